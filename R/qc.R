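#' Quality-control thresholds for imaging-based single-cell data
#'
#' Defaults follow common MERFISH practice: cells are excluded when the total
#' (non-blank) transcript count is below 30 or above 2500, fewer than 5
#' distinct genes are detected, the segmented volume is below 40 or above
#' 2500 cubic micrometres, or the mean count over blank probes exceeds 1.
#' All bounds are inclusive for retention: a cell at exactly 30 counts,
#' 5 genes or 40 um^3 is kept (exclusion is strict, `< min` / `> max`).
#'
#' @param min_counts,max_counts retention bounds on total transcripts.
#' @param min_genes minimum number of detected genes.
#' @param min_volume,max_volume retention bounds on cell volume (um^3).
#' @param max_blank_mean maximum mean blank-probe count per cell.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_counts = 30, max_counts = 2500, min_genes = 5,
                          min_volume = 40, max_volume = 2500,
                          max_blank_mean = 1) {
  stopifnot(min_counts < max_counts, min_volume < max_volume, min_genes >= 0)
  structure(
    list(min_counts = min_counts, max_counts = max_counts,
         min_genes = min_genes, min_volume = min_volume,
         max_volume = max_volume, max_blank_mean = max_blank_mean),
    class = "qc_thresholds"
  )
}

#' Filter cells on transcript count, gene count, volume and blank signal
#'
#' Recomputes per-cell QC statistics from the counts (totals over non-blank
#' genes only) and retains cells passing every criterion. The report counts
#' removals per criterion non-exclusively, so a cell failing two criteria
#' appears in both rows.
#'
#' @param cells tibble with at least `cell_id` and `volume`; rows match
#'   `counts` cells.
#' @param counts a [counts_matrix()] with the raw layer present.
#' @param thresholds a [qc_thresholds()].
#' @return A list with `cells`, `counts` (both filtered, QC columns
#'   refreshed) and `report` (tibble of per-criterion removal counts).
#' @examples
#' b <- simulate_bundle(synth_config(seed = 1, n_cells_st = 300))
#' qc <- qc_filter(b$st_cells, b$st_counts)
#' qc$report
#' @export
qc_filter <- function(cells, counts, thresholds = qc_thresholds()) {
  stopifnot(inherits(counts, "counts_matrix"), is.data.frame(cells))
  if (!all(cells$cell_id %in% counts$cells)) {
    rlang::abort("every cell in `cells` must be present in `counts`")
  }
  counts <- subset_cells(counts, cells$cell_id)
  qc <- cell_qc_stats(counts)
  cells <- cells |>
    dplyr::select(-dplyr::any_of(c("total_counts", "n_genes", "blank_mean"))) |>
    dplyr::left_join(qc, by = "cell_id")

  thr <- thresholds
  fail <- list(
    low_counts  = cells$total_counts < thr$min_counts,
    high_counts = cells$total_counts > thr$max_counts,
    low_genes   = cells$n_genes < thr$min_genes,
    low_volume  = cells$volume < thr$min_volume,
    high_volume = cells$volume > thr$max_volume,
    high_blank  = cells$blank_mean > thr$max_blank_mean
  )
  any_fail <- Reduce(`|`, fail)
  if (all(any_fail)) rlang::abort("empty after QC: all cells fail at least one criterion")

  report <- tibble::tibble(
    criterion = names(fail),
    n_removed = vapply(fail, sum, numeric(1))
  ) |>
    dplyr::bind_rows(tibble::tibble(criterion = "total", n_removed = sum(any_fail)))

  keep_ids <- cells$cell_id[!any_fail]
  list(
    cells = cells[!any_fail, , drop = FALSE],
    counts = subset_cells(counts, keep_ids),
    report = report
  )
}

#' Log-normalize counts
#'
#' For each cell the non-blank counts are divided by the cell's total
#' (non-blank) count, multiplied by `scale_factor` and log-transformed with a
#' pseudocount of one: `norm = log(1 + scale_factor * raw / total)`. Blank
#' probes are excluded from both the totals and the normalized layer.
#'
#' @param counts a [counts_matrix()].
#' @param scale_factor library-size scale, default 10000.
#' @return The counts object with a `norm` layer (cells x non-blank genes).
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  stopifnot(inherits(counts, "counts_matrix"))
  rc <- real_counts(counts)
  tot <- Matrix::rowSums(rc)
  if (any(tot == 0)) {
    rlang::abort("cells with zero total counts cannot be normalized (run qc_filter first)")
  }
  norm <- Matrix::Diagonal(x = scale_factor / tot) %*% rc
  norm@x <- log1p(norm@x)
  norm <- methods::as(norm, "CsparseMatrix")
  dimnames(norm) <- dimnames(rc)
  counts$norm <- norm
  counts
}
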