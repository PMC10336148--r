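lesion_subset <- function(bundle) {
  core <- estimate_lesion_core(bundle$st_cells, "dam", "homeostatic")
  cells <- assign_regions(bundle$st_cells, expand_rings(core))
  dplyr::filter(cells, .data$region_label %in%
                  c("lesion_core", "lesion_inner_edge", "lesion_outer_edge"))
}

test_that("neighborhood fractions are proper and trivial cases check out", {
  b <- small_bundle()
  cells <- lesion_subset(b)
  res <- knn_enrichment(cells, k = 5, n_perm = 200, seed = 1)
  sums <- res |>
    dplyr::summarise(s = sum(.data$observed_fraction), .by = "query_class")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_true(all(res$empirical_p >= 1 / 201))

  # k = 1 with two isolated same-class pairs: each cell's neighbor is its
  # partner, so the same-class fraction is 1
  toy <- tibble::tibble(
    cell_id = paste0("t", 1:4),
    x = c(0, 1, 100, 101), y = 0,
    class_label = c("a", "a", "b", "b")
  )
  rt <- knn_enrichment(toy, k = 1, n_perm = 50, seed = 1)
  expect_equal(
    rt$observed_fraction[rt$query_class == "a" & rt$target_class == "a"], 1
  )
})

test_that("planted T-cell/IFN niches are enriched; random labels are not", {
  b <- default_bundle()
  cells <- lesion_subset(b)
  res <- knn_enrichment(cells, k = 5, n_perm = 2000, seed = 2)
  hit <- res |>
    dplyr::filter(.data$query_class == "tcell", .data$target_class == "ifn")
  expect_gt(hit$fold_enrichment, 1)
  expect_lt(hit$empirical_p, 0.01)

  # random labels: mean fold near 1
  folds <- c()
  for (sd in 1:5) {
    set.seed(sd)
    shuffled <- cells
    shuffled$class_label <- sample(shuffled$class_label)
    rs <- knn_enrichment(shuffled, k = 5, n_perm = 500, seed = sd)
    folds <- c(folds, rs$fold_enrichment)
  }
  expect_gt(mean(folds, na.rm = TRUE), 0.9)
  expect_lt(mean(folds, na.rm = TRUE), 1.1)
})

test_that("cross-K matches the O(n^2) pair-count oracle without edge correction", {
  pts <- tibble::tibble(
    x = c(10, 20, 35, 50, 60, 80, 15, 25, 45, 55, 70, 90),
    y = c(15, 80, 40, 20, 70, 50, 60, 30, 85, 45, 25, 65),
    class_label = rep(c("a", "b"), each = 6)
  )
  win <- rect_window(c(0, 100), c(0, 100))
  radii <- seq(5, 60, by = 5)
  out <- cross_ripley_l(pts, "a", "b", window = win, radii = radii,
                        n_perm = 10, correction = "none", seed = 1)
  # oracle: K_ab(r) = |W| / (n_a n_b) * #{pairs (i in a, j in b): d_ij <= r}
  a <- pts[pts$class_label == "a", ]; bb <- pts[pts$class_label == "b", ]
  K_oracle <- vapply(radii, function(r) {
    cnt <- 0
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(bb))) {
      d <- sqrt((a$x[i] - bb$x[j])^2 + (a$y[i] - bb$y[j])^2)
      if (d <= r) cnt <- cnt + 1
    }
    1e4 / (6 * 6) * cnt
  }, numeric(1))
  expect_equal(out$K_obs, K_oracle, tolerance = 1e-12)
  expect_true(all(diff(out$K_obs) >= 0))      # monotone in r
})

test_that("the cross-L estimator is symmetric and detects maximal attraction", {
  b <- small_bundle()
  cells <- lesion_subset(b)
  win <- rect_window(range(cells$x), range(cells$y))
  ab <- cross_ripley_l(cells, "tcell", "ifn", window = win, n_perm = 20,
                       radii = seq(10, 100, 10), seed = 3)
  ba <- cross_ripley_l(cells, "ifn", "tcell", window = win, n_perm = 20,
                       radii = seq(10, 100, 10), seed = 3)
  expect_lt(max(abs(ab$L_obs - ba$L_obs)), 1e-9)

  # class_b placed exactly on class_a positions: centered L far above the
  # envelope at small r
  pts_a <- dplyr::filter(cells, .data$class_label == "tcell")
  dup <- dplyr::mutate(pts_a, class_label = "dup",
                       cell_id = paste0(.data$cell_id, "-d"))
  both <- dplyr::bind_rows(pts_a, dup)
  rc <- cross_ripley_l(both, "tcell", "dup", window = win,
                       radii = c(5, 10, 20), n_perm = 50, seed = 1)
  expect_gt(rc$centered[1], rc$envelope_hi[1] - rc$L_perm_mean[1])

  # radius grid beyond the window diameter is truncated with a warning
  expect_warning(
    cross_ripley_l(cells, "tcell", "ifn", window = win,
                   radii = c(10, 1e5), n_perm = 5, seed = 1),
    "truncated"
  )
})

test_that("under CSR the centered curve stays inside the envelopes", {
  cover <- c()
  for (sd in 1:3) {
    set.seed(sd)
    n <- 120
    cells <- tibble::tibble(
      cell_id = as.character(seq_len(n)),
      x = runif(n, 0, 500), y = runif(n, 0, 500),
      class_label = sample(rep(c("a", "b"), each = n / 2))
    )
    rc <- cross_ripley_l(cells, "a", "b",
                         window = rect_window(c(0, 500), c(0, 500)),
                         radii = seq(5, 150, 10), n_perm = 100, seed = sd)
    cover <- c(cover, mean(rc$L_obs >= rc$envelope_lo &
                             rc$L_obs <= rc$envelope_hi))
  }
  expect_gte(mean(cover), 0.85)
})
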