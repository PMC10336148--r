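square_mask <- function(dim, r0, r1, c0, c1) {
  m <- matrix(FALSE, dim, dim)
  m[r0:r1, c0:c1] <- TRUE
  m
}

test_that("areas, empty cytoplasm, and position follow pixel arithmetic", {
  cell <- square_mask(20, 5, 14, 5, 14)       # 10x10 = 100 px
  nuc <- square_mask(20, 7, 10, 7, 10)        # 4x4 = 16 px
  stack <- label_mask_stack(list(whole_cell = cell, nucleus = nuc),
                            px_size_nm = 1000, origin = c(0, 0))
  row <- extract_features(stack)
  expect_equal(row$whole_cell_px, 100)
  expect_equal(row$nucleus_px, 16)
  expect_equal(row$empty_cytoplasm_px, 84)
  expect_equal(row$whole_cell_px + 0, row$nucleus_px + row$empty_cytoplasm_px)
  expect_equal(row$ratio_nucleus_whole_cell, 0.16)
  # bounding-box center (1-based pixel indices 5..14 -> center 9.5 px = 9.5 um)
  expect_equal(row$x, 9.5)

  # masks beyond the whole cell violate the invariants
  bad <- square_mask(20, 1, 16, 1, 16)
  expect_error(label_mask_stack(list(whole_cell = cell, nucleus = bad)),
               "beyond")
  # empty organelle masks: empty cytoplasm equals the whole cell
  stack2 <- label_mask_stack(list(whole_cell = cell,
                                  lysosome = cell & FALSE))
  expect_equal(extract_features(stack2)$empty_cytoplasm_px, 100)
})

test_that("pixel conservation holds exactly for disjoint compartments", {
  set.seed(2)
  cell <- square_mask(40, 3, 38, 3, 38)
  nuc <- square_mask(40, 5, 14, 5, 14)
  lyso <- square_mask(40, 20, 24, 20, 24)
  lipid <- square_mask(40, 28, 33, 8, 13)
  stack <- label_mask_stack(list(whole_cell = cell, nucleus = nuc,
                                 lysosome = lyso, lipid_droplet = lipid))
  row <- extract_features(stack)
  expect_identical(
    row$nucleus_px + row$lysosome_px + row$lipid_droplet_px +
      row$empty_cytoplasm_px,
    row$whole_cell_px
  )

  # translation invariance of everything but the position
  sh <- 2
  shift <- function(m) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + sh):nrow(m), (1 + sh):ncol(m)] <-
      m[1:(nrow(m) - sh), 1:(ncol(m) - sh)]
    out
  }
  row2 <- extract_features(label_mask_stack(lapply(
    list(whole_cell = cell, nucleus = nuc, lysosome = lyso,
         lipid_droplet = lipid), shift)))
  keep <- setdiff(names(row), c("x", "y"))
  expect_equal(row2[keep], row[keep], tolerance = 1e-12)
})

test_that("ER arc length matches the straight-segment oracle; stray pixels drop", {
  cell <- square_mask(60, 1, 60, 1, 60)
  er <- matrix(FALSE, 60, 60)
  er[6:55, 30] <- TRUE                       # 1-px straight segment, 50 px
  stack <- label_mask_stack(list(whole_cell = cell, er = er),
                            px_size_nm = 20)
  row <- extract_features(stack)
  px_um <- 0.02
  expect_lt(abs(row$er_length - 49 * px_um), 1 * px_um)

  # a diagonal segment uses sqrt(2) steps
  er2 <- matrix(FALSE, 60, 60)
  for (i in 1:30) er2[10 + i, 10 + i] <- TRUE
  row2 <- extract_features(label_mask_stack(list(whole_cell = cell, er = er2),
                                            px_size_nm = 20))
  expect_lt(abs(row2$er_length - 29 * sqrt(2) * px_um), 2 * px_um)

  # stray specks below 5 px are cleaned before measuring
  lyso <- matrix(FALSE, 60, 60)
  lyso[2, 2] <- TRUE; lyso[50, 50] <- TRUE   # two 1-px specks
  lyso[20:24, 20:24] <- TRUE                 # one real 25-px lysosome
  row3 <- extract_features(label_mask_stack(list(whole_cell = cell,
                                                 lysosome = lyso)))
  expect_equal(row3$lysosome_px, 25)
})

test_that("structural clustering separates planted morphology classes", {
  set.seed(6)
  n <- 90
  cls <- rep(c("foamy-like", "t-like", "reactive-like"), each = n / 3)
  feats <- tibble::tibble(
    cell_id = as.character(1:n),
    lipid = rnorm(n, ifelse(cls == "foamy-like", 20, 2), 1.5),
    nuc_ratio = rnorm(n, ifelse(cls == "t-like", 0.8, 0.3), 0.05),
    mito = rnorm(n, ifelse(cls == "reactive-like", 10, 3), 1),
    er = rnorm(n, 5, 1),
    junk_ratio = NA_real_
  )
  lab <- cluster_structural(feats, n_pcs = 4, resolution = 0.3, seed = 2)
  expect_gte(ari(lab, cls), 0.8)

  # duplicated rows co-cluster; resolution -> 0 collapses to one cluster
  lab2 <- cluster_structural(dplyr::bind_rows(feats, feats), n_pcs = 4,
                             resolution = 0.3, seed = 2)
  expect_true(all(lab2[1:n] == lab2[n + 1:n]))
  lab0 <- cluster_structural(feats, n_pcs = 4, resolution = 0, seed = 2)
  expect_equal(nlevels(droplevels(lab0)), 1)
})

test_that("expert labels map to the nearest featured cell with flags", {
  set.seed(9)
  grid <- expand.grid(x = seq(0, 200, 20), y = seq(0, 200, 20))
  featured <- tibble::tibble(cell_id = sprintf("f%02d", seq_len(nrow(grid))),
                             x = grid$x, y = grid$y)
  # identical coordinates: identity mapping with zero distances
  expert0 <- featured |> dplyr::rename(expert_id = "cell_id") |>
    dplyr::mutate(cell_id = .data$expert_id)
  m0 <- match_expert_labels(expert0, featured)
  expect_identical(m0$matched_id, featured$cell_id)
  expect_true(all(m0$distance == 0))

  # jitter 2 um with 20 um spacing: always the right partner
  for (sd in 1:5) {
    set.seed(sd)
    expert <- featured
    expert$x <- expert$x + rnorm(nrow(expert), sd = 2)
    expert$y <- expert$y + rnorm(nrow(expert), sd = 2)
    m <- match_expert_labels(expert, featured)
    expect_identical(m$matched_id, featured$cell_id)
  }

  # two experts nearest to one featured cell: both mapped, flagged
  expert2 <- tibble::tibble(cell_id = c("e1", "e2"), x = c(0, 1), y = 0)
  expect_warning(m2 <- match_expert_labels(expert2, featured[1, ]),
                 "many-to-one")
  expect_true(all(m2$shared))
  expect_error(match_expert_labels(expert2[0, ], featured), "nonempty")
})

test_that("label-overlap Fisher test equals exact hypergeometric enumeration", {
  # perfectly aligned balanced labels
  a <- rep(c("x", "y"), each = 20)
  res <- overlap_test(a, a)
  row <- res[res$class_a == "x" & res$class_b == "x", ]
  # oracle: one-sided tail of the hypergeometric
  p_oracle <- phyper(19, 20, 20, 20, lower.tail = FALSE)
  expect_equal(row$p, p_oracle, tolerance = 1e-12)
  expect_lt(row$p, 1e-5)

  # random tables up to n = 60 match fisher's one-sided tail exactly
  set.seed(14)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    la <- sample(c("a", "b"), n, replace = TRUE)
    lb <- sample(c("u", "v"), n, replace = TRUE)
    if (length(unique(la)) < 2 || length(unique(lb)) < 2) next
    res <- overlap_test(la, lb)
    x11 <- sum(la == "a" & lb == "u")
    K <- sum(la == "a"); nn <- sum(lb == "u")
    p_or <- phyper(x11 - 1, K, n - K, nn, lower.tail = FALSE)
    expect_equal(res$p[res$class_a == "a" & res$class_b == "u"], p_or,
                 tolerance = 1e-12)
  }

  # a pairing that never occurs: count 0 and p = 1
  la <- c(rep("a", 10), rep("b", 10))
  lb <- c(rep("u", 10), rep("v", 10))
  res <- overlap_test(la, lb)
  expect_equal(res$count[res$class_a == "a" & res$class_b == "v"], 0L)
  expect_equal(res$p[res$class_a == "a" & res$class_b == "v"], 1)
  expect_error(overlap_test(rep("a", 5), lb[1:5]), "2 classes")
})

test_that("independent labels give calibrated Fisher p-values", {
  set.seed(15)
  ps <- vapply(1:200, function(i) {
    la <- sample(c("a", "b"), 40, replace = TRUE)
    lb <- sample(c("u", "v"), 40, replace = TRUE)
    if (length(unique(la)) < 2 || length(unique(lb)) < 2) return(NA_real_)
    res <- overlap_test(la, lb)
    res$p[res$class_a == "a" & res$class_b == "u"]
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  # conservative discrete test: small p-values are not over-produced
  expect_lt(mean(ps < 0.05), 0.08)
  expect_gt(mean(ps > 0.3), 0.5)
})
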