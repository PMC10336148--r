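#' Build metacells by k-nearest-neighbor aggregation
#'
#' Samples seed cells and groups each with its `k - 1` nearest neighbors in
#' PCA space; candidate metacells sharing more than `max_shared` members with
#' an already accepted one are rejected. Gene expression is averaged on the
#' normalized scale; the lipid stain is log10-transformed before averaging.
#'
#' @param counts a normalized [counts_matrix()].
#' @param bodipy per-cell positive lipid-stain values, in cell order.
#' @param k cells per metacell (default 20; `k = 1` returns single cells).
#' @param n_seeds seed cells sampled (default `n_cells / 5`, at least 1).
#' @param max_shared maximal member overlap with accepted metacells
#'   (default `k / 2`).
#' @param n_pcs PCA dimensions for the neighbor search (default 15).
#' @param seed integer seed.
#' @return A `metacell_table`: list with `expr` (metacells x genes mean
#'   normalized expression), `bodipy` (mean log10 stain), `members` (list of
#'   cell ids), `k`.
#' @export
build_metacells <- function(counts, bodipy, k = 20, n_seeds = NULL,
                            max_shared = NULL, n_pcs = 15, seed = 0L) {
  stopifnot(inherits(counts, "counts_matrix"))
  if (is.null(counts$norm)) rlang::abort("run normalize_counts() first")
  n <- length(counts$cells)
  if (k > n) rlang::abort("k exceeds the number of cells")
  stopifnot(length(bodipy) == n, all(bodipy > 0))
  n_seeds <- n_seeds %||% max(1L, floor(n / 5))
  max_shared <- max_shared %||% floor(k / 2)

  norm <- as.matrix(counts$norm)
  withr::local_seed(seed)
  seeds <- sample.int(n, min(n_seeds, n))
  if (k > 1) {
    pcs <- stats::prcomp(norm, center = TRUE, scale. = FALSE,
                         rank. = min(n_pcs, dim(norm) - 1L))$x
    nn <- cpp_knn(pcs, pcs[seeds, , drop = FALSE], k, FALSE)$index
  } else {
    nn <- matrix(seeds, ncol = 1)
  }

  accepted <- list()
  for (s in seq_along(seeds)) {
    members <- nn[s, ]
    ok <- TRUE
    for (acc in accepted) {
      if (length(intersect(acc, members)) > max_shared) { ok <- FALSE; break }
    }
    if (ok) accepted[[length(accepted) + 1]] <- members
  }
  if (!length(accepted)) rlang::abort("no metacell accepted; lower max_shared")

  expr <- do.call(rbind, lapply(accepted, function(m) colMeans(norm[m, , drop = FALSE])))
  rownames(expr) <- sprintf("mc-%03d", seq_along(accepted))
  lb <- log10(bodipy)
  structure(
    list(
      expr = expr,
      bodipy = vapply(accepted, function(m) mean(lb[m]), numeric(1)),
      members = lapply(accepted, function(m) counts$cells[m]),
      k = k
    ),
    class = "metacell_table"
  )
}

#' @export
print.metacell_table <- function(x, ...) {
  cat(sprintf("<metacell_table> %d metacells of k = %d cells, %d genes\n",
              nrow(x$expr), x$k, ncol(x$expr)))
  invisible(x)
}

#' Gene-stain correlation over metacells
#'
#' Pearson correlation between every gene's mean normalized expression and
#' the mean log10 lipid stain across metacells; genes are ranked by r.
#'
#' @param mc a `metacell_table`.
#' @return Tibble with `gene`, `r`, `rank` (1 = most positively correlated);
#'   constant genes get `NA`.
#' @export
stain_correlation <- function(mc) {
  stopifnot(inherits(mc, "metacell_table"))
  if (nrow(mc$expr) < 3) rlang::abort("need at least 3 metacells")
  r <- suppressWarnings(as.numeric(stats::cor(mc$expr, mc$bodipy)))
  tibble::tibble(gene = colnames(mc$expr), r = r) |>
    dplyr::mutate(rank = rank(-.data$r, ties.method = "first", na.last = "keep"))
}

# weighted Kolmogorov-Smirnov running-sum enrichment score
gsea_es <- function(in_set, stat, weight = 1) {
  hit_w <- abs(stat)^weight * in_set
  if (sum(hit_w) == 0) hit_w <- in_set / sum(in_set)
  else hit_w <- hit_w / sum(hit_w)
  miss_w <- (!in_set) / sum(!in_set)
  run <- cumsum(hit_w - miss_w)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum GSEA on a ranking statistic
#' (e.g. gene-stain Pearson correlations): genes are ordered by decreasing
#' statistic (ties broken by gene name for determinism), the enrichment
#' score is the signed maximal deviation of the running sum (hit increments
#' proportional to `|stat|^weight`, uniform miss decrements), the p-value
#' comes from a gene-permutation null and NES divides ES by the mean
#' same-sign permutation magnitude.
#'
#' @param stats named numeric vector, gene -> ranking statistic.
#' @param gene_sets named list of gene vectors.
#' @param weight running-sum weight exponent (default 1; 0 gives the classic
#'   unweighted statistic).
#' @param n_perm gene permutations (default 1000).
#' @param min_size sets smaller than this after restriction to the ranked
#'   universe are skipped (default 5).
#' @param seed integer seed.
#' @return Tibble with `term`, `size`, `ES`, `NES`, `p`, `adj_p`,
#'   `leading_edge` (list of genes driving the score).
#' @export
preranked_gsea <- function(stats, gene_sets, weight = 1, n_perm = 1000,
                           min_size = 5, seed = 0L) {
  stats <- stats[!is.na(stats)]
  ord <- order(-stats, names(stats))        # deterministic tie-break
  stat <- as.numeric(stats[ord])
  genes <- names(stats)[ord]
  n <- length(genes)

  withr::local_seed(seed)
  rows <- purrr::imap(gene_sets, function(set, term) {
    in_set <- genes %in% set
    size <- sum(in_set)
    if (size < min_size || size == n) return(NULL)
    es <- gsea_es(in_set, stat, weight)

    perm_es <- vapply(seq_len(n_perm), function(i) {
      gsea_es(sample(in_set), stat, weight)
    }, numeric(1))
    same <- perm_es[sign(perm_es) == sign(es)]
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_

    # leading edge: set genes at or before (after, for negative ES) the peak
    hit_w <- abs(stat)^weight * in_set
    hit_w <- if (sum(hit_w) == 0) in_set / size else hit_w / sum(hit_w)
    run <- cumsum(hit_w - (!in_set) / sum(!in_set))
    peak <- which.max(abs(run))
    le <- if (es >= 0) genes[seq_len(peak)][in_set[seq_len(peak)]]
          else genes[peak:n][in_set[peak:n]]
    tibble::tibble(term = term, size = size, ES = es, NES = nes, p = p,
                   leading_edge = list(le))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) rlang::abort("no gene set passes the size filter")
  out |>
    dplyr::mutate(adj_p = stats::p.adjust(.data$p, method = "BH")) |>
    dplyr::select("term", "size", "ES", "NES", "p", "adj_p", "leading_edge") |>
    dplyr::arrange(.data$p)
}
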