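#' Cells-by-genes counts container
#'
#' Light S3 wrapper around a sparse raw count matrix (cells in rows, genes in
#' columns) that tracks blank (negative-control) probes and, after
#' [normalize_counts()], a log-normalized layer over the non-blank genes.
#'
#' @param raw integer-valued matrix or `Matrix::dgCMatrix`, cells x genes,
#'   with unique row (cell) and column (gene) names.
#' @param is_blank logical per-gene flag marking blank probes. Defaults to
#'   genes whose name starts with `"Blank-"`, the usual MERFISH convention.
#' @return An object of class `counts_matrix` with elements `raw`, `cells`,
#'   `genes`, `is_blank` and (once computed) `norm`.
#' @export
counts_matrix <- function(raw, is_blank = NULL) {
  raw <- methods::as(methods::as(methods::as(Matrix::Matrix(raw, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(raw)) || is.null(colnames(raw))) {
    rlang::abort("counts need cell (row) and gene (column) names")
  }
  if (anyDuplicated(rownames(raw)) || anyDuplicated(colnames(raw))) {
    rlang::abort("cell and gene names must be unique")
  }
  if (any(raw@x < 0)) rlang::abort("counts must be non-negative")
  if (is.null(is_blank)) is_blank <- grepl("^Blank-", colnames(raw))
  stopifnot(length(is_blank) == ncol(raw))
  structure(
    list(raw = raw, cells = rownames(raw), genes = colnames(raw),
         is_blank = is_blank, norm = NULL),
    class = "counts_matrix"
  )
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat(sprintf(
    "<counts_matrix> %d cells x %d genes (%d blank probes)%s\n",
    length(x$cells), length(x$genes), sum(x$is_blank),
    if (is.null(x$norm)) "" else ", normalized layer present"
  ))
  invisible(x)
}

#' @export
dim.counts_matrix <- function(x) dim(x$raw)

# raw counts restricted to real (non-blank) genes
real_counts <- function(counts) counts$raw[, !counts$is_blank, drop = FALSE]

# per-cell totals over non-blank genes only (blanks never enter totals)
cell_totals <- function(counts) Matrix::rowSums(real_counts(counts))

#' Per-cell QC summary of a counts matrix
#'
#' Computes, over non-blank genes, the total transcript count and the number
#' of detected genes per cell, plus the mean count over blank probes.
#'
#' @param counts a [counts_matrix()].
#' @return A tibble with `cell_id`, `total_counts`, `n_genes`, `blank_mean`.
#' @export
cell_qc_stats <- function(counts) {
  stopifnot(inherits(counts, "counts_matrix"))
  rc <- real_counts(counts)
  bl <- counts$raw[, counts$is_blank, drop = FALSE]
  tibble::tibble(
    cell_id = counts$cells,
    total_counts = Matrix::rowSums(rc),
    n_genes = Matrix::rowSums(rc > 0),
    blank_mean = if (ncol(bl)) Matrix::rowSums(bl) / ncol(bl) else 0
  )
}

# subset a counts_matrix by cell ids (keeps layer consistency)
subset_cells <- function(counts, cell_ids) {
  keep <- match(cell_ids, counts$cells)
  stopifnot(!anyNA(keep))
  counts$raw <- counts$raw[keep, , drop = FALSE]
  counts$cells <- counts$cells[keep]
  if (!is.null(counts$norm)) counts$norm <- counts$norm[keep, , drop = FALSE]
  counts
}
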