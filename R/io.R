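#' Write / read a counts matrix as an MTX triplet
#'
#' MatrixMarket sparse matrix plus `genes.tsv` (gene name, blank flag) and
#' `cells.tsv` (cell id), the common exchange layout for single-cell counts.
#'
#' @param counts a [counts_matrix()].
#' @param dir directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  stopifnot(inherits(counts, "counts_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts$raw, file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(gene = counts$genes, is_blank = as.integer(counts$is_blank)),
    file.path(dir, "genes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(cell_id = counts$cells),
    file.path(dir, "cells.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- utils::read.table(file.path(dir, "genes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  cells <- utils::read.table(file.path(dir, "cells.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  dimnames(m) <- list(cells$cell_id, genes$gene)
  counts_matrix(m, is_blank = as.logical(genes$is_blank))
}

#' Read a GMT gene-set collection
#'
#' Tab-delimited: term, description, then member genes.
#'
#' @param path file path.
#' @return Named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene vectors.
#' @param description optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write landmark pairs as TSV
#'
#' Columns `x_src`, `y_src`, `x_dst`, `y_dst` in micrometres.
#'
#' @param path file path.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  landmark_set(cbind(d$x_src, d$y_src), cbind(d$x_dst, d$y_dst))
}

#' @rdname read_landmarks
#' @param lm a [landmark_set()] or a tibble with the four columns.
#' @export
write_landmarks <- function(lm, path) {
  if (inherits(lm, "landmark_set")) {
    lm <- data.frame(x_src = lm$source[, 1], y_src = lm$source[, 2],
                     x_dst = lm$target[, 1], y_dst = lm$target[, 2])
  }
  utils::write.table(lm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write polygons as a GeoJSON-like file
#'
#' @param polys named list of polygon matrices.
#' @param path output path.
#' @export
write_regions_json <- function(polys, path) {
  features <- purrr::imap(polys, function(p, nm) {
    p <- as_polygon(p)
    ring <- rbind(p, p[1, ])
    list(
      type = "Feature",
      properties = list(name = nm),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ])))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = unname(features)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_regions_json
#' @export
read_regions_json <- function(path) {
  j <- jsonlite::read_json(path)
  polys <- lapply(j$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    as_polygon(ring)
  })
  names(polys) <- vapply(j$features, function(f) f$properties$name, character(1))
  polys
}

# deterministic TSV writer used by the pipeline (fixed number formatting so
# identical inputs give byte-identical files)
write_tsv_deterministic <- function(df, path, digits = 10) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- formatC(df[[nm]], digits = digits, format = "g")
    }
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(x) paste(x, collapse = ","),
                         character(1))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Write a synthetic bundle to disk
#'
#' Cell tables and landmarks as TSV, counts as MTX triplets, the truth
#' record as JSON.
#'
#' @param bundle a [simulate_bundle()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_deterministic(bundle$st_cells, file.path(dir, "st_cells.tsv"))
  write_tsv_deterministic(bundle$em_cells, file.path(dir, "em_cells.tsv"))
  write_tsv_deterministic(bundle$em_features, file.path(dir, "em_features.tsv"))
  write_landmarks(bundle$landmarks, file.path(dir, "landmarks.tsv"))
  write_counts_mtx(bundle$st_counts, file.path(dir, "st_counts"))
  write_counts_mtx(bundle$sc_counts, file.path(dir, "sc_counts"))
  write_tsv_deterministic(
    tibble::tibble(cell_id = names(bundle$bodipy), bodipy = bundle$bodipy),
    file.path(dir, "bodipy.tsv")
  )
  truth <- bundle$truth
  truth$st$violators <- as.data.frame(truth$st$violators)
  jsonlite::write_json(
    list(
      st_class = as.list(truth$st$class_label),
      violators = truth$st$violators,
      similarity = truth$em$similarity,
      rho = truth$em$rho
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
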