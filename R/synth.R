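#' Configuration for the coupled synthetic datasets
#'
#' Parameterizes a lesion-centered tissue emulation: five cell classes
#' (homeostatic, DAM-like, foamy, IFN-responsive, T-cell) laid out around a
#' circular demyelinated lesion, negative-binomial marker programs with blank
#' probes, an adjacent-section "EM" point set related to the spatial
#' transcriptomics frame by a known similarity transform plus a smooth
#' deformation, per-cell organelle features with a planted latent correlation
#' to the foamy gene program, and a full-transcriptome single-cell set with a
#' lipid-stain (BODIPY-like) readout driven by the same program.
#'
#' Defaults describe the emulated study conditions: a 400 um lesion radius
#' centered in a 2200 um frame (of the order of the imaged block face), foamy cells clustered at the core (Thomas process),
#' IFN-responsive cells and T-cells sharing Thomas-process parents (planted
#' co-clustering in niches of `niche_sd` spread), 10 um adjacent-section
#' jitter of 5 um sd, and a 10 degree / 1.05x / (30, -20) um similarity
#' between frames with 20 um smooth deformation.
#'
#' @param seed integer seed; every derived dataset is a deterministic
#'   function of the configuration.
#' @param n_cells_st,n_cells_em,n_cells_sc cell numbers per modality.
#' @param n_genes_panel measured panel size (real genes, excluding blanks).
#' @param n_genes_full full-transcriptome gene count for the scRNA-seq set.
#' @param frame_size,lesion_center,lesion_radius geometry in micrometres.
#' @param class_proportions named fractions over the five classes (sum to 1).
#' @param nb_dispersion negative-binomial size parameter of counts.
#' @param marker_logfc log2 fold change of class markers over baseline.
#' @param niche_parent_rate intensity (parents per um^2 of lesion) of the
#'   Thomas parent process for niche-forming classes.
#' @param niche_sd Gaussian daughter spread around niche parents (um).
#' @param blank_rate mean total blank-probe counts per cell, split over
#'   `n_blanks` blank pseudo-genes.
#' @param n_blanks number of appended `Blank-` pseudo-genes.
#' @param em_similarity list with `rotation` (radians), `scale`,
#'   `translation` (um) mapping the ST frame into the EM frame.
#' @param em_jitter_sd adjacent-section positional jitter sd (um).
#' @param em_deform_amp,em_deform_sd,n_deform_bumps amplitude (um), spread
#'   (um) and count of the Gaussian deformation bumps added to the EM frame.
#' @param latent_gene_feature_rho planted correlation between the foamy
#'   program latent and the lipid-droplet area feature.
#' @param bodipy_noise_sd Gaussian noise sd on the log lipid-stain values.
#' @param qc_violator_frac fraction of ST cells planted as QC violators.
#' @param n_landmarks number of landmark pairs (>= 8; default 16, a 4 x 4 grid).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_cells_st = 2000L,
                         n_cells_em = 800L,
                         n_cells_sc = 1000L,
                         n_genes_panel = 150L,
                         n_genes_full = 2000L,
                         frame_size = c(2200, 2200),
                         lesion_center = c(1100, 1100),
                         lesion_radius = 400,
                         class_proportions = c(homeostatic = 0.40, dam = 0.25,
                                               foamy = 0.15, ifn = 0.12,
                                               tcell = 0.08),
                         nb_dispersion = 2,
                         marker_logfc = 2,
                         niche_parent_rate = 1e-5,
                         niche_sd = 30,
                         blank_rate = 0.3,
                         n_blanks = 10L,
                         em_similarity = list(rotation = 10 * pi / 180,
                                              scale = 1.05,
                                              translation = c(30, -20)),
                         em_jitter_sd = 5,
                         em_deform_amp = 20,
                         em_deform_sd = 250,
                         n_deform_bumps = 3L,
                         latent_gene_feature_rho = 0.6,
                         bodipy_noise_sd = 0.3,
                         qc_violator_frac = 0.02,
                         n_landmarks = 16L) {
  cfg <- as.list(environment())
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    rlang::abort("class_proportions must sum to 1")
  }
  if (any(class_proportions < 0)) rlang::abort("class_proportions must be >= 0")
  if (n_cells_st <= 0 || n_cells_em <= 0 || n_cells_sc <= 0) {
    rlang::abort("cell numbers must be positive")
  }
  if (abs(latent_gene_feature_rho) > 1) {
    rlang::abort("latent_gene_feature_rho must lie in [-1, 1]")
  }
  if (n_cells_em > n_cells_st) {
    rlang::abort("n_cells_em cannot exceed n_cells_st (EM cells subsample ST cells)")
  }
  # injectivity guard: the deformation must stay a diffeomorphism so that the
  # landmark map is invertible (max gradient of summed bumps well below 1)
  if (n_deform_bumps * em_deform_amp * exp(-0.5) / em_deform_sd >= 0.9) {
    rlang::abort("em_deform_amp too large relative to em_deform_sd: deformation may fold")
  }
  if (n_landmarks < 8) rlang::abort("need at least 8 landmark pairs")
  structure(cfg, class = "synth_config")
}

synth_classes <- function(cfg) names(cfg$class_proportions)

# gene catalogue shared by the panel and the full transcriptome: 12 markers
# per class plus extra full-transcriptome-only program genes used to test
# imputation
synth_gene_catalog <- function(cfg) {
  classes <- synth_classes(cfg)
  markers <- lapply(classes, function(cl) sprintf("%s-m%02d", cl, 1:12))
  names(markers) <- classes
  n_marker <- sum(lengths(markers))
  n_null <- cfg$n_genes_panel - n_marker
  stopifnot(n_null > 0)
  panel <- c(unlist(markers), sprintf("null-%03d", seq_len(n_null)))
  extra_markers <- lapply(classes, function(cl) sprintf("%s-x%02d", cl, 1:8))
  names(extra_markers) <- classes
  n_extra_null <- cfg$n_genes_full - length(panel) - sum(lengths(extra_markers))
  stopifnot(n_extra_null > 0)
  full <- c(panel, unlist(extra_markers), sprintf("nullx-%04d", seq_len(n_extra_null)))
  list(panel = panel, full = full, markers = markers,
       extra_markers = extra_markers)
}

# Thomas process: Poisson parents, Gaussian daughters, n points total
rthomas_n <- function(n, parents, sd, clamp) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  pick <- sample.int(nrow(parents), n, replace = TRUE)
  xy <- parents[pick, , drop = FALSE] + matrix(rnorm(2 * n, sd = sd), ncol = 2)
  xy[, 1] <- pmin(pmax(xy[, 1], clamp[1]), clamp[2])
  xy[, 2] <- pmin(pmax(xy[, 2], clamp[3]), clamp[4])
  colnames(xy) <- c("x", "y")
  xy
}

runif_disk <- function(n, center, radius) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

# per-cell foamy program latent: class effect + unit noise; drives the foamy
# marker program, the lipid-droplet feature and the lipid stain
foamy_latent <- function(class_label) {
  2 * (class_label == "foamy") + rnorm(length(class_label))
}

# negative-binomial counts for a set of cells given class labels and latents
synth_counts <- function(cfg, genes, markers, class_label, latent,
                         extra_markers = NULL) {
  n <- length(class_label)
  g <- length(genes)
  base <- rlnorm(g, meanlog = log(0.5), sdlog = 0.6)
  names(base) <- genes
  size_f <- rlnorm(n, 0, 0.25)
  logmu <- outer(rep(0, n), log(base), `+`)
  fc <- cfg$marker_logfc * log(2)
  all_markers <- markers
  if (!is.null(extra_markers)) {
    for (cl in names(extra_markers)) {
      all_markers[[cl]] <- c(all_markers[[cl]], extra_markers[[cl]])
    }
  }
  for (cl in names(all_markers)) {
    cols <- match(intersect(all_markers[[cl]], genes), genes)
    rows <- class_label == cl
    logmu[rows, cols] <- logmu[rows, cols] + fc
  }
  # foamy program additionally scales smoothly with the latent
  foamy_cols <- match(intersect(all_markers[["foamy"]], genes), genes)
  logmu[, foamy_cols] <- logmu[, foamy_cols] +
    0.4 * (latent - mean(latent))
  mu <- exp(logmu) * size_f
  counts <- matrix(
    rnbinom(n * g, mu = as.vector(mu), size = cfg$nb_dispersion),
    nrow = n, ncol = g
  )
  colnames(counts) <- genes
  counts
}

#' Generate the spatial-transcriptomics dataset
#'
#' Lays out cells around the lesion (homeostatic outside, DAM-like inside,
#' foamy from a Thomas cluster process at the core, IFN-responsive and
#' T-cells sharing Thomas parents so they co-cluster in niches), then draws
#' negative-binomial counts with class marker programs, appends blank
#' pseudo-genes, assigns lognormal volumes inside the QC window and plants a
#' configurable fraction of QC violators (recorded in the truth).
#'
#' @param cfg a [synth_config()].
#' @return List with `cells` (tibble), `counts` ([counts_matrix()]) and
#'   `truth` (class labels, foamy latents, planted violators, marker sets).
#' @export
generate_st <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::local_seed(cfg$seed)
  classes <- synth_classes(cfg)
  n <- cfg$n_cells_st
  n_class <- floor(cfg$class_proportions * n)
  rem <- n - sum(n_class)
  if (rem > 0) {
    top <- order(cfg$class_proportions, decreasing = TRUE)[seq_len(rem)]
    n_class[top] <- n_class[top] + 1L
  }
  ctr <- cfg$lesion_center; rad <- cfg$lesion_radius
  clamp <- c(0, cfg$frame_size[1], 0, cfg$frame_size[2])

  # homeostatic: uniform outside the lesion disk
  xy_h <- matrix(numeric(0), ncol = 2)
  while (nrow(xy_h) < n_class[["homeostatic"]]) {
    cand <- cbind(runif(n, 0, cfg$frame_size[1]), runif(n, 0, cfg$frame_size[2]))
    keep <- sqrt((cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2) > rad
    xy_h <- rbind(xy_h, cand[keep, , drop = FALSE])
  }
  xy_h <- xy_h[seq_len(n_class[["homeostatic"]]), , drop = FALSE]

  xy_d <- runif_disk(n_class[["dam"]], ctr, rad)

  # foamy: Thomas process concentrated at the core
  n_par_f <- max(1L, rpois(1, cfg$niche_parent_rate * pi * (rad / 2)^2))
  par_f <- runif_disk(n_par_f, ctr, rad / 3)
  xy_f <- rthomas_n(n_class[["foamy"]], par_f, cfg$niche_sd, clamp)

  # IFN-responsive and T-cells: shared niche parents anywhere in the lesion.
  # T-cells occupy a subset of the IFN niches, so the two classes co-cluster
  # while keeping distinguishable global densities.
  n_par_n <- max(2L, rpois(1, cfg$niche_parent_rate * pi * rad^2))
  par_n <- runif_disk(n_par_n, ctr, rad * 0.9)
  par_t <- par_n[seq_len(max(1L, ceiling(0.6 * n_par_n))), , drop = FALSE]
  xy_i <- rthomas_n(n_class[["ifn"]], par_n, cfg$niche_sd, clamp)
  xy_t <- rthomas_n(n_class[["tcell"]], par_t, cfg$niche_sd, clamp)

  xy <- rbind(xy_h, xy_d, xy_f, xy_i, xy_t)
  class_label <- rep(classes, c(nrow(xy_h), nrow(xy_d), nrow(xy_f),
                                nrow(xy_i), nrow(xy_t)))
  ord <- sample.int(nrow(xy))
  xy <- xy[ord, , drop = FALSE]
  class_label <- class_label[ord]
  cell_id <- sprintf("st-%04d", seq_len(n))

  latent <- foamy_latent(class_label)
  cat <- synth_gene_catalog(cfg)
  counts <- synth_counts(cfg, cat$panel, cat$markers, class_label, latent)

  blanks <- matrix(
    rpois(n * cfg$n_blanks, cfg$blank_rate / cfg$n_blanks),
    nrow = n, ncol = cfg$n_blanks,
    dimnames = list(NULL, sprintf("Blank-%02d", seq_len(cfg$n_blanks)))
  )

  volume <- rlnorm(n, meanlog = log(300), sdlog = 0.35)
  volume <- pmin(pmax(volume, 45), 2200)

  # guard band: keep honest cells safely inside every QC bound
  tot <- rowSums(counts)
  low <- which(tot < 35)
  for (i in low) {
    add <- 35 - tot[i]
    cols <- sample.int(ncol(counts), add, replace = TRUE)
    for (cc in cols) counts[i, cc] <- counts[i, cc] + 1L
  }
  ngene <- rowSums(counts > 0)
  few <- which(ngene < 6)
  for (i in few) {
    cols <- sample(which(counts[i, ] == 0), 6 - ngene[i])
    counts[i, cols] <- 1L
  }

  # planted QC violators, one unambiguous violation each
  n_viol <- round(cfg$qc_violator_frac * n)
  violators <- tibble::tibble(cell_id = character(0), type = character(0))
  if (n_viol > 0) {
    types <- rep(c("low_counts", "high_counts", "low_genes", "low_volume",
                   "high_volume", "high_blank"), length.out = n_viol)
    vi <- sample.int(n, n_viol)
    for (s in seq_len(n_viol)) {
      i <- vi[s]
      switch(types[s],
        low_counts = {
          counts[i, ] <- 0L
          cols <- sample.int(ncol(counts), 10, replace = TRUE)
          for (cc in cols) counts[i, cc] <- counts[i, cc] + 1L
        },
        high_counts = {
          cols <- sample.int(ncol(counts), 40, replace = TRUE)
          for (cc in cols) counts[i, cc] <- counts[i, cc] + 100L
        },
        low_genes = {
          counts[i, ] <- 0L
          counts[i, sample.int(ncol(counts), 3)] <- 20L
        },
        low_volume = volume[i] <- runif(1, 10, 39),
        high_volume = volume[i] <- runif(1, 2600, 4000),
        high_blank = blanks[i, ] <- blanks[i, ] + 2L
      )
    }
    violators <- tibble::tibble(cell_id = cell_id[vi], type = types)
  }

  raw <- cbind(counts, blanks)
  rownames(raw) <- cell_id
  cm <- counts_matrix(raw)
  qc <- cell_qc_stats(cm)

  cells <- tibble::tibble(
    cell_id = cell_id,
    x = xy[, 1], y = xy[, 2],
    volume = volume,
    total_counts = qc$total_counts,
    n_genes = qc$n_genes,
    blank_mean = qc$blank_mean,
    class_label = class_label,
    region_label = NA_character_,
    modality = "ST"
  )
  truth <- list(
    class_label = setNames(class_label, cell_id),
    foamy_latent = setNames(latent, cell_id),
    violators = violators,
    markers = cat$markers,
    niche_parents = par_n
  )
  list(cells = cells, counts = cm, truth = truth)
}

# similarity transform helpers (ST frame -> EM frame)
similarity_apply <- function(sim, pts) {
  R <- matrix(c(cos(sim$rotation), sin(sim$rotation),
                -sin(sim$rotation), cos(sim$rotation)), 2, 2)
  sweep(sim$scale * (as.matrix(pts) %*% t(R)), 2, sim$translation, `+`)
}

deform_field <- function(bumps, pts) {
  pts <- as.matrix(pts)
  out <- pts
  for (b in seq_len(nrow(bumps$center))) {
    d2 <- (pts[, 1] - bumps$center[b, 1])^2 + (pts[, 2] - bumps$center[b, 2])^2
    g <- exp(-d2 / (2 * bumps$sd^2))
    out[, 1] <- out[, 1] + bumps$amp[b, 1] * g
    out[, 2] <- out[, 2] + bumps$amp[b, 2] * g
  }
  out
}

st_to_em_frame <- function(cfg, bumps, pts) {
  deform_field(bumps, similarity_apply(cfg$em_similarity, pts))
}

#' Generate the EM dataset coupled to an ST dataset
#'
#' EM cells are a subsample of the ST cells with adjacent-section jitter,
#' mapped into the EM image frame by the configured similarity transform plus
#' a smooth low-frequency deformation (sum of Gaussian bumps). Per-cell
#' organelle features are drawn with class-specific structure: foamy cells
#' have large lipid-droplet areas (tied to the foamy program latent with the
#' planted correlation), T-cells a high nucleus-to-cell ratio with near-zero
#' organelles, IFN-responsive cells a high mitochondria share and empty
#' cytoplasm. Landmark pairs mapping the EM frame back to the ST frame are
#' returned and map exactly under the true transform chain.
#'
#' @param cfg a [synth_config()].
#' @param st the result of [generate_st()].
#' @return List with `cells`, `features`, `landmarks`, `truth`.
#' @export
generate_em <- function(cfg, st) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::local_seed(cfg$seed + 1L)
  n <- cfg$n_cells_em
  pick <- sort(sample.int(nrow(st$cells), n))
  parent <- st$cells[pick, ]

  bumps <- list(
    center = cbind(runif(cfg$n_deform_bumps, 0, cfg$frame_size[1]),
                   runif(cfg$n_deform_bumps, 0, cfg$frame_size[2])),
    amp = matrix(rnorm(2 * cfg$n_deform_bumps, sd = cfg$em_deform_amp / sqrt(2)),
                 ncol = 2),
    sd = cfg$em_deform_sd
  )

  jitter <- matrix(rnorm(2 * n, sd = cfg$em_jitter_sd), ncol = 2)
  st_xy <- cbind(parent$x, parent$y) + jitter
  em_xy <- st_to_em_frame(cfg, bumps, st_xy)

  cell_id <- sprintf("em-%04d", seq_len(n))
  class_label <- parent$class_label
  latent <- st$truth$foamy_latent[parent$cell_id]

  rho <- cfg$latent_gene_feature_rho
  z <- as.numeric(scale(latent))
  lipid_mix <- rho * z + sqrt(1 - rho^2) * rnorm(n)

  base <- function(mu, sd) pmax(rlnorm(n, log(mu), sd), 0.01)
  whole <- base(80, 0.25)
  nucleus_frac <- dplyr::case_when(
    class_label == "tcell" ~ pmin(rbeta_shift(n, 0.70, 0.05), 0.9),
    TRUE ~ pmin(rbeta_shift(n, 0.35, 0.06), 0.7)
  )
  nucleus <- nucleus_frac * whole
  hetero <- pmin(rbeta_shift(n, 0.4, 0.08), 0.8) * nucleus
  # linear in the mixed latent so the truth-latent correlation is exactly rho
  # in expectation; foamy cells are high-lipid through their latent offset
  lipid <- pmax(20 + 6 * lipid_mix, 0.05)
  lyso <- dplyr::case_when(
    class_label == "tcell" ~ base(0.3, 0.3),
    class_label == "dam" ~ base(6, 0.3),
    TRUE ~ base(3, 0.3)
  )
  mito <- dplyr::case_when(
    class_label == "tcell" ~ base(0.4, 0.3),
    class_label == "ifn" ~ base(9, 0.25),
    TRUE ~ base(3, 0.3)
  )
  er_len <- dplyr::case_when(
    class_label == "ifn" ~ base(30, 0.3),
    class_label == "tcell" ~ base(4, 0.3),
    TRUE ~ base(15, 0.3)
  )
  organellar <- pmax(whole - nucleus - lipid - lyso - mito, 1) *
    rbeta_shift(n, 0.5, 0.1)
  organellar[class_label == "ifn"] <- organellar[class_label == "ifn"] * 0.4
  empty <- pmax(whole - nucleus - lipid - lyso - mito - organellar, 0.5)

  features <- tibble::tibble(
    cell_id = cell_id,
    x = em_xy[, 1], y = em_xy[, 2],
    whole_cell_area = whole,
    nucleus_area = nucleus,
    heterochromatin_area = hetero,
    lysosome_area = lyso,
    lipid_droplet_area = lipid,
    mitochondria_area = mito,
    er_length = er_len,
    organellar_cytoplasm_area = organellar,
    empty_cytoplasm_area = empty
  )

  cells <- tibble::tibble(
    cell_id = cell_id,
    x = em_xy[, 1], y = em_xy[, 2],
    volume = NA_real_,
    total_counts = NA_real_,
    n_genes = NA_real_,
    blank_mean = NA_real_,
    class_label = class_label,
    region_label = NA_character_,
    modality = "EM"
  )

  # landmarks: anatomical-landmark stand-ins spread over the frame; source
  # (EM frame) = true forward map of target (ST frame)
  g <- ceiling(sqrt(cfg$n_landmarks))
  gx <- seq(0.08 * cfg$frame_size[1], 0.92 * cfg$frame_size[1], length.out = g)
  gy <- seq(0.08 * cfg$frame_size[2], 0.92 * cfg$frame_size[2], length.out = g)
  lm_st <- cbind(rep(gx, each = g), rep(gy, g))[seq_len(cfg$n_landmarks), ]
  lm_em <- st_to_em_frame(cfg, bumps, lm_st)
  landmarks <- tibble::tibble(
    x_src = lm_em[, 1], y_src = lm_em[, 2],
    x_dst = lm_st[, 1], y_dst = lm_st[, 2]
  )

  truth <- list(
    parent_cell = setNames(parent$cell_id, cell_id),
    class_label = setNames(class_label, cell_id),
    st_xy = st_xy,
    similarity = cfg$em_similarity,
    deformation = bumps,
    foamy_latent = setNames(as.numeric(z), cell_id),
    rho = rho
  )
  list(cells = cells, features = features, landmarks = landmarks, truth = truth)
}

rbeta_shift <- function(n, mean, sd) pmax(rnorm(n, mean, sd), 0.01)

#' Generate the full-transcriptome scRNA-seq dataset with lipid stain values
#'
#' Draws cells with the same class programs over the full gene catalogue
#' (panel genes plus non-panel program genes and nulls) and a strictly
#' positive lipid-stain (BODIPY-like) intensity that increases monotonically
#' with the foamy program latent, with Gaussian noise of sd
#' `bodipy_noise_sd` on the log scale.
#'
#' @param cfg a [synth_config()].
#' @return List with `counts` ([counts_matrix()], no blanks), `bodipy`
#'   (named positive vector) and `truth`.
#' @export
generate_sc <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::local_seed(cfg$seed + 2L)
  n <- cfg$n_cells_sc
  classes <- synth_classes(cfg)
  class_label <- sample(classes, n, replace = TRUE,
                        prob = cfg$class_proportions)
  latent <- foamy_latent(class_label)
  cat <- synth_gene_catalog(cfg)
  counts <- synth_counts(cfg, cat$full, cat$markers, class_label, latent,
                         extra_markers = cat$extra_markers)
  cell_id <- sprintf("sc-%04d", seq_len(n))
  rownames(counts) <- cell_id
  bodipy <- 100 * exp(0.5 * latent + rnorm(n, sd = cfg$bodipy_noise_sd))
  cm <- counts_matrix(counts, is_blank = rep(FALSE, ncol(counts)))
  truth <- list(
    class_label = setNames(class_label, cell_id),
    foamy_latent = setNames(latent, cell_id),
    markers = cat$markers,
    extra_markers = cat$extra_markers
  )
  list(counts = cm, bodipy = setNames(bodipy, cell_id), truth = truth)
}

#' Generate the full coupled bundle
#'
#' Runs [generate_st()], [generate_em()] and [generate_sc()] under the
#' configuration seed and collects their truth records; the bundle is a
#' deterministic function of the configuration.
#'
#' @param cfg a [synth_config()].
#' @return A `synth_bundle` list with `st_cells`, `st_counts`, `em_cells`,
#'   `em_features`, `landmarks`, `sc_counts`, `bodipy`, `truth`, `config`.
#' @export
simulate_bundle <- function(cfg = synth_config()) {
  st <- generate_st(cfg)
  em <- generate_em(cfg, st)
  sc <- generate_sc(cfg)
  structure(
    list(
      st_cells = st$cells, st_counts = st$counts,
      em_cells = em$cells, em_features = em$features,
      landmarks = em$landmarks,
      sc_counts = sc$counts, bodipy = sc$bodipy,
      truth = list(st = st$truth, em = em$truth, sc = sc$truth),
      config = cfg
    ),
    class = "synth_bundle"
  )
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf(
    "<synth_bundle> %d ST cells, %d EM cells, %d scRNA-seq cells (seed %d)\n",
    nrow(x$st_cells), nrow(x$em_cells), length(x$bodipy), x$config$seed
  ))
  invisible(x)
}
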