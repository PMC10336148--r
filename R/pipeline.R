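#' Run the full integration pipeline on a synthetic bundle
#'
#' End-to-end chain used for integration testing and as the engine behind
#' the command-line wrapper: simulate (or accept) a bundle, QC-filter and
#' normalize the spatial counts, segment the lesion and expand the edge
#' rings, assign regions, run neighborhood enrichment and cross-type
#' Ripley's L inside the lesion, register the EM frame onto the ST frame
#' from the landmarks, compute the multiscale EMD class matrix in the common
#' frame, smooth both modalities with the bisquare kernel and correlate
#' genes with structural features, and correlate metacell expression with
#' the lipid stain. All outputs are written as deterministic TSV/JSON, so a
#' fixed-seed run is byte-identical across repetitions.
#'
#' Permutation counts and grid sizes default to reduced, desk-scale values
#' here; the statistical functions themselves default to the full settings.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory.
#' @param bundle optionally a pre-built [simulate_bundle()] result.
#' @param n_perm_neigh,n_perm_ripley permutation counts.
#' @param emd_grid_size EMD density grid edge.
#' @param emd_sigmas EMD smoothing scales (µm).
#' @return Named list of the main result tables (invisibly written to
#'   `out_dir`).
#' @export
run_pipeline <- function(config = synth_config(), out_dir,
                         bundle = NULL,
                         n_perm_neigh = 1000, n_perm_ripley = 100,
                         emd_grid_size = 32, emd_sigmas = c(25, 50, 75, 100)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  b <- bundle %||% simulate_bundle(config)

  qc <- qc_filter(b$st_cells, b$st_counts)
  counts <- normalize_counts(qc$counts)
  cells <- qc$cells

  core <- estimate_lesion_core(cells, pos_class = "dam",
                               neg_class = "homeostatic")
  regions <- expand_rings(core, step = 50, n = 2)
  cells <- assign_regions(cells, regions)

  lesion_cells <- cells |>
    dplyr::filter(.data$region_label %in%
                    c("lesion_core", "lesion_inner_edge", "lesion_outer_edge"))
  neigh <- knn_enrichment(lesion_cells, k = 5, n_perm = n_perm_neigh,
                          seed = config$seed)

  window <- rect_window(range(lesion_cells$x), range(lesion_cells$y))
  ripley <- cross_ripley_l(lesion_cells, "tcell", "ifn", window = window,
                           n_perm = n_perm_ripley, seed = config$seed)

  lm <- landmark_set(cbind(b$landmarks$x_src, b$landmarks$y_src),
                     cbind(b$landmarks$x_dst, b$landmarks$y_dst))
  chain <- fit_transform_chain(lm)
  em_cells <- b$em_cells
  em_reg <- apply_chain(chain, cbind(em_cells$x, em_cells$y))
  em_cells$x <- em_reg[, 1]; em_cells$y <- em_reg[, 2]

  emd <- emd_class_matrix(cells, em_cells, sigmas = emd_sigmas,
                          grid_size = emd_grid_size)

  st_vals <- as.matrix(counts$norm)
  feat_cols <- setdiff(names(b$em_features), c("cell_id", "x", "y"))
  sm <- kernel_smooth_transfer(
    cells, st_vals[cells$cell_id, , drop = FALSE],
    em_cells, as.matrix(b$em_features[, feat_cols])
  )
  corr <- gene_structure_correlation(sm)

  sc_norm <- normalize_counts(b$sc_counts)
  mc <- build_metacells(sc_norm, b$bodipy, k = 20, seed = config$seed)
  stain <- stain_correlation(mc)

  write_tsv_deterministic(qc$report, file.path(out_dir, "qc_report.tsv"))
  write_tsv_deterministic(cells, file.path(out_dir, "st_cells.tsv"))
  write_tsv_deterministic(neigh, file.path(out_dir, "neighborhood.tsv"))
  write_tsv_deterministic(tibble::as_tibble(ripley),
                          file.path(out_dir, "ripley_tcell_ifn.tsv"))
  write_tsv_deterministic(tidy(chain), file.path(out_dir, "registration.tsv"))
  write_tsv_deterministic(
    tibble::as_tibble(as.data.frame(unclass(emd)), rownames = "st_class"),
    file.path(out_dir, "emd_matrix.tsv")
  )
  write_tsv_deterministic(corr, file.path(out_dir, "gene_structure_corr.tsv"))
  write_tsv_deterministic(stain, file.path(out_dir, "stain_correlation.tsv"))
  write_regions_json(
    c(list(lesion_core = regions$core),
      setNames(Filter(Negate(is.null), regions$rings),
               paste0("ring_", seq_along(regions$rings))[!vapply(regions$rings, is.null, logical(1))])),
    file.path(out_dir, "regions.json")
  )

  invisible(list(cells = cells, qc_report = qc$report, neighborhood = neigh,
                 ripley = ripley, chain = chain, emd = emd,
                 correlation = corr, stain = stain, regions = regions))
}

#' Spatial scatter of cells colored by a label
#'
#' @param cells tibble with `x`, `y` and the color column.
#' @param colour column name to color by (default `class_label`).
#' @return A ggplot.
#' @export
plot_spatial <- function(cells, colour = "class_label") {
  ggplot2::ggplot(cells, ggplot2::aes(.data$x, .data$y,
                                      colour = .data[[colour]])) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = colour) +
    ggplot2::theme_minimal()
}
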