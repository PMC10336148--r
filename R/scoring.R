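#' Gene signature
#'
#' @param name signature name.
#' @param genes character vector of gene names (duplicates are dropped).
#' @return A `gene_signature` list.
#' @export
gene_signature <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) rlang::abort("a signature needs at least one gene")
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' Binned-control module score
#'
#' Scores a gene signature in every cell as the mean normalized expression of
#' the signature genes minus the mean over control genes. Controls are drawn
#' per signature gene from the same average-expression bin (genes are binned
#' into `n_bins` by their mean normalized expression), which corrects for the
#' tendency of highly expressed genes to score high everywhere.
#'
#' @param counts a normalized [counts_matrix()].
#' @param signature a [gene_signature()] or character vector of genes.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl controls sampled per signature gene (default 100, without
#'   replacement within the gene's bin, capped at the bin size).
#' @param seed integer seed making the control draw reproducible.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(counts, signature, n_bins = 24, n_ctrl = 100,
                         seed = 0L) {
  stopifnot(inherits(counts, "counts_matrix"))
  if (is.null(counts$norm)) rlang::abort("run normalize_counts() first")
  if (is.character(signature)) signature <- gene_signature("signature", signature)
  norm <- counts$norm
  genes <- colnames(norm)

  sig <- unique(signature$genes)
  missing <- setdiff(sig, genes)
  if (length(missing) == length(sig)) {
    rlang::abort("none of the signature genes are measured")
  }
  if (length(missing)) {
    rlang::warn(sprintf("dropping %d signature gene(s) not measured: %s",
                        length(missing), paste(head(missing, 5), collapse = ", ")))
    sig <- setdiff(sig, missing)
  }

  avg <- Matrix::colMeans(norm)
  n_bins <- min(n_bins, length(avg))
  bins <- as.integer(cut(rank(avg, ties.method = "first"), breaks = n_bins,
                         labels = FALSE, include.lowest = TRUE))
  names(bins) <- genes

  withr::local_seed(seed)
  ctrl <- unlist(lapply(sig, function(g) {
    pool <- genes[bins == bins[[g]]]
    sample(pool, size = min(n_ctrl, length(pool)), replace = FALSE)
  }))

  score <- Matrix::rowMeans(norm[, sig, drop = FALSE]) -
    Matrix::rowMeans(norm[, ctrl, drop = FALSE])
  setNames(as.numeric(score), counts$cells)
}

#' Regress signature scores out of the normalized layer
#'
#' Fits, per gene, an ordinary least-squares model of the normalized
#' expression on the supplied per-cell score covariates (with intercept) and
#' replaces the working layer by the residuals plus the gene mean. Used to
#' remove contamination signatures before PCA and clustering. When no
#' informative covariates are supplied (all constant), the input is returned
#' unchanged so the operation is a no-op without scores.
#'
#' @param counts a normalized [counts_matrix()].
#' @param scores data frame or matrix of per-cell covariates (cells in rows,
#'   in the order of `counts$cells`).
#' @return The counts object with an `adjusted` dense layer.
#' @export
regress_signatures <- function(counts, scores) {
  stopifnot(inherits(counts, "counts_matrix"))
  if (is.null(counts$norm)) rlang::abort("run normalize_counts() first")
  X <- as.matrix(scores)
  if (nrow(X) != length(counts$cells)) {
    rlang::abort("scores must have one row per cell")
  }
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    rlang::warn(sprintf("dropping %d constant covariate(s)", sum(!keep)))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) == 0) {
    counts$adjusted <- as.matrix(counts$norm)
    return(counts)
  }
  Xi <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    rlang::warn("collinear covariates dropped (rank-deficient fit)")
    Xi <- Xi[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(Xi)
  }
  Y <- as.matrix(counts$norm)
  res <- qr.resid(qrX, Y)
  dimnames(res) <- dimnames(counts$norm)
  counts$adjusted <- res
  counts
}

#' Wilcoxon rank-sum marker test
#'
#' Two-sided rank-sum test per (non-blank) gene between one group and all
#' other cells (or a named reference group), with Benjamini-Hochberg
#' adjustment. Genes constant across the compared cells get `p = 1` by
#' convention. The log fold change is computed on de-logged normalized means.
#'
#' @param counts a normalized [counts_matrix()].
#' @param labels per-cell group labels in the order of `counts$cells`.
#' @param group label of the group of interest.
#' @param reference optional label to compare against (default: all others).
#' @return Tibble with `gene`, `log_fc` (log2), `statistic` (rank-sum U),
#'   `p`, `adj_p`, sorted by `p`.
#' @export
rank_sum_markers <- function(counts, labels, group, reference = NULL) {
  stopifnot(inherits(counts, "counts_matrix"))
  if (is.null(counts$norm)) rlang::abort("run normalize_counts() first")
  labels <- as.character(labels)
  stopifnot(length(labels) == length(counts$cells))
  in_grp <- labels == group
  in_ref <- if (is.null(reference)) !in_grp else labels == reference
  if (sum(in_grp) < 2 || sum(in_ref) < 2) {
    rlang::abort("both compared groups need at least 2 cells")
  }
  norm <- counts$norm
  genes <- colnames(norm)
  x <- as.matrix(norm[in_grp, , drop = FALSE])
  y <- as.matrix(norm[in_ref, , drop = FALSE])

  res <- vapply(seq_along(genes), function(j) {
    xj <- x[, j]; yj <- y[, j]
    if (stats::sd(c(xj, yj)) == 0) {
      return(c(stat = length(xj) * length(yj) / 2, p = 1))
    }
    w <- suppressWarnings(stats::wilcox.test(xj, yj, exact = FALSE))
    c(stat = unname(w$statistic), p = w$p.value)
  }, numeric(2))

  mean_g <- colMeans(expm1(x))
  mean_r <- colMeans(expm1(y))
  eps <- 1e-9
  tibble::tibble(
    gene = genes,
    log_fc = log2((mean_g + eps) / (mean_r + eps)),
    statistic = res["stat", ],
    p = pmin(res["p", ], 1),
    adj_p = stats::p.adjust(pmin(res["p", ], 1), method = "BH")
  ) |>
    dplyr::arrange(.data$p)
}
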