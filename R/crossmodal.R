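#' Bisquare kernel configuration for cross-modal smoothing
#'
#' @param d_max maximal distance in micrometres (default 75); the weight
#'   `w(d) = (1 - (d/d_max)^2)^2` is maximal (1) at distance 0 and zero at
#'   and beyond `d_max`.
#' @param include_self include a cell itself among its same-modality donors
#'   (default TRUE; cross-modality transfer has no self by construction).
#' @return A `kernel_config` list.
#' @export
kernel_config <- function(d_max = 75, include_self = TRUE) {
  stopifnot(d_max > 0)
  structure(list(d_max = d_max, include_self = include_self),
            class = "kernel_config")
}

#' Bisquare weight function
#' @param d distances (µm).
#' @param d_max cutoff (µm).
#' @return Weights in `[0, 1]`, zero at and beyond `d_max`.
#' @export
bisquare_weight <- function(d, d_max = 75) {
  ifelse(d < d_max, (1 - (d / d_max)^2)^2, 0)
}

#' Kernel-weighted cross-modal smoothing and transfer
#'
#' Places spatial-transcriptomics cells (carrying gene expression values:
#' measured panel genes and imputed ones) and EM cells (carrying structural
#' features) in a common registered frame and computes, for every cell of
#' both modalities and every column, the bisquare-kernel distance-weighted
#' average over the donors of that column's source modality within `d_max`.
#' After smoothing every cell carries values for every gene and every
#' structural feature, which is what makes gene-structure correlation across
#' modalities possible.
#'
#' ST cells are restricted to the area surrounding the available EM data,
#' operationalized as: within `d_max` of the nearest EM cell (disable with
#' `restrict = FALSE`).
#'
#' @param st_cells tibble of ST cells (`cell_id`, `x`, `y`) in the common
#'   frame.
#' @param st_values numeric matrix, ST cells x gene columns (rows in the
#'   order of `st_cells`).
#' @param em_cells tibble of EM cells (`cell_id`, `x`, `y`) in the common
#'   frame.
#' @param em_values numeric matrix, EM cells x feature columns.
#' @param cfg a [kernel_config()].
#' @param restrict restrict ST cells to the EM neighbourhood (default TRUE).
#' @param provenance optional per-gene-column provenance tags (e.g.
#'   "measured"/"imputed") carried through to the result.
#' @return A `smoothed_matrix`: tibble with `cell_id`, `modality`, `x`, `y`
#'   and one column per gene/feature; attributes `provenance` and
#'   `n_missing` (cells without any donor in range, per column group).
#' @export
kernel_smooth_transfer <- function(st_cells, st_values, em_cells, em_values,
                                   cfg = kernel_config(), restrict = TRUE,
                                   provenance = NULL) {
  st_values <- as.matrix(st_values); em_values <- as.matrix(em_values)
  stopifnot(nrow(st_values) == nrow(st_cells),
            nrow(em_values) == nrow(em_cells))
  if (nrow(em_cells) == 0) rlang::abort("no EM donor cells")
  if (nrow(st_cells) == 0) rlang::abort("no ST donor cells")

  st_xy <- cbind(st_cells$x, st_cells$y)
  em_xy <- cbind(em_cells$x, em_cells$y)
  if (restrict) {
    nnd <- cpp_knn(em_xy, st_xy, 1, FALSE)$dist[, 1]
    keep <- nnd <= cfg$d_max
    st_cells <- st_cells[keep, , drop = FALSE]
    st_values <- st_values[keep, , drop = FALSE]
    st_xy <- st_xy[keep, , drop = FALSE]
    if (nrow(st_cells) == 0) rlang::abort("no ST cells within d_max of the EM data")
  }

  all_xy <- rbind(st_xy, em_xy)
  modality <- rep(c("ST", "EM"), c(nrow(st_xy), nrow(em_xy)))

  # gene columns: donors are ST cells. Self-exclusion only applies to the
  # same-modality (ST target) rows when include_self = FALSE.
  sm_genes_st <- cpp_kernel_smooth(st_xy, st_xy, st_values, cfg$d_max,
                                   !cfg$include_self)
  sm_genes_em <- cpp_kernel_smooth(em_xy, st_xy, st_values, cfg$d_max, FALSE)
  sm_genes <- rbind(sm_genes_st, sm_genes_em)
  colnames(sm_genes) <- colnames(st_values)

  # feature columns: donors are EM cells
  sm_feat_st <- cpp_kernel_smooth(st_xy, em_xy, em_values, cfg$d_max, FALSE)
  sm_feat_em <- cpp_kernel_smooth(em_xy, em_xy, em_values, cfg$d_max,
                                  !cfg$include_self)
  sm_feat <- rbind(sm_feat_st, sm_feat_em)
  colnames(sm_feat) <- colnames(em_values)

  out <- dplyr::bind_cols(
    tibble::tibble(
      cell_id = c(st_cells$cell_id, em_cells$cell_id),
      modality = modality,
      x = all_xy[, 1], y = all_xy[, 2]
    ),
    tibble::as_tibble(sm_genes),
    tibble::as_tibble(sm_feat)
  )
  prov <- c(
    if (is.null(provenance)) setNames(rep("measured", ncol(st_values)),
                                      colnames(st_values)) else provenance,
    setNames(rep("structural", ncol(em_values)), colnames(em_values))
  )
  attr(out, "provenance") <- prov
  attr(out, "n_missing") <- c(
    genes = sum(is.na(sm_genes[, 1])),
    features = sum(is.na(sm_feat[, 1]))
  )
  attr(out, "gene_cols") <- colnames(st_values)
  attr(out, "feature_cols") <- colnames(em_values)
  class(out) <- c("smoothed_matrix", class(out))
  out
}

#' Gene-structure Spearman correlation
#'
#' Spearman rank correlation (average ranks for ties, pairwise-complete
#' cells) between every smoothed gene column and every smoothed structural
#' feature column.
#'
#' @param sm a `smoothed_matrix` from [kernel_smooth_transfer()], or a data
#'   frame plus explicit `genes`/`features` column names.
#' @param genes,features column names; default taken from the
#'   `smoothed_matrix` attributes.
#' @return Tibble with `gene`, `feature`, `rho` (`NA` for constant columns,
#'   reported with a warning).
#' @export
gene_structure_correlation <- function(sm, genes = NULL, features = NULL) {
  genes <- genes %||% attr(sm, "gene_cols")
  features <- features %||% attr(sm, "feature_cols")
  if (is.null(genes) || is.null(features)) {
    rlang::abort("supply `genes` and `features` column names")
  }
  G <- as.matrix(sm[, genes, drop = FALSE])
  F <- as.matrix(sm[, features, drop = FALSE])
  rho <- suppressWarnings(
    stats::cor(G, F, method = "spearman", use = "pairwise.complete.obs")
  )
  if (anyNA(rho)) rlang::warn("constant column(s): correlation undefined (NA)")
  tibble::as_tibble(as.table(rho), .name_repair = "minimal") |>
    stats::setNames(c("gene", "feature", "rho")) |>
    dplyr::mutate(gene = as.character(.data$gene),
                  feature = as.character(.data$feature))
}

#' Over-representation of gene sets among the top feature correlates
#'
#' One-sided hypergeometric test of each gene set's overlap with the
#' `n_top` most positively (or negatively) correlated genes for a feature,
#' against the analyzed gene universe, with Benjamini-Hochberg adjustment.
#'
#' @param corr_tbl output of [gene_structure_correlation()].
#' @param feature feature name to rank genes by.
#' @param gene_sets named list of gene vectors (e.g. from [read_gmt()]).
#' @param universe gene universe; defaults to all genes in `corr_tbl`.
#' @param n_top number of top correlates (default 200).
#' @param direction `"positive"` or `"negative"`.
#' @return Tibble with `term`, `n_set`, `overlap`, `p`, `adj_p`, sorted by
#'   `p`; sets with no gene in the universe are skipped.
#' @export
top_gene_enrichment <- function(corr_tbl, feature, gene_sets, universe = NULL,
                                n_top = 200, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  sub <- corr_tbl |>
    dplyr::filter(.data$feature == !!feature, !is.na(.data$rho))
  if (nrow(sub) == 0) rlang::abort("feature not found in correlation table")
  universe <- universe %||% unique(sub$gene)
  sub <- sub |> dplyr::filter(.data$gene %in% universe)
  ord <- if (direction == "positive") -sub$rho else sub$rho
  top <- sub$gene[order(ord)][seq_len(min(n_top, nrow(sub)))]

  N <- length(universe); n <- length(top)
  rows <- purrr::imap(gene_sets, function(set, term) {
    set_u <- intersect(set, universe)
    if (length(set_u) == 0) return(NULL)
    K <- length(set_u)
    ov <- length(intersect(set_u, top))
    p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term = term, n_set = K, overlap = ov, p = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) rlang::abort("no gene set intersects the universe")
  out |>
    dplyr::mutate(adj_p = stats::p.adjust(.data$p, method = "BH")) |>
    dplyr::arrange(.data$p)
}
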