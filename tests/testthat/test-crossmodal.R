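test_that("bisquare weights and the smoothing arithmetic match closed forms", {
  expect_equal(bisquare_weight(0, 75), 1)
  expect_equal(bisquare_weight(75, 75), 0)
  expect_equal(bisquare_weight(76, 75), 0)
  expect_equal(bisquare_weight(30, 75), (1 - (30 / 75)^2)^2)

  # one target, two ST donors with values 0 and 10 at 10 and 70 um
  st <- tibble::tibble(cell_id = c("s1", "s2"), x = c(10, 70), y = 0)
  em <- tibble::tibble(cell_id = "e1", x = 0, y = 0)
  sm <- kernel_smooth_transfer(
    st, cbind(g = c(0, 10)), em, cbind(f = 1),
    cfg = kernel_config(d_max = 75), restrict = FALSE
  )
  w10 <- bisquare_weight(10, 75); w70 <- bisquare_weight(70, 75)
  expect_equal(sm$g[sm$cell_id == "e1"], 10 * w70 / (w10 + w70))

  # a donor exactly at d_max has zero weight -> no donors -> missing
  st2 <- tibble::tibble(cell_id = "s1", x = 75, y = 0)
  sm2 <- kernel_smooth_transfer(st2, cbind(g = 5), em, cbind(f = 1),
                                restrict = FALSE)
  expect_true(is.na(sm2$g[sm2$cell_id == "e1"]))
  # a single donor at distance 0 transfers its value with weight 1
  st3 <- tibble::tibble(cell_id = "s1", x = 0, y = 0)
  sm3 <- kernel_smooth_transfer(st3, cbind(g = 5), em, cbind(f = 1),
                                restrict = FALSE)
  expect_equal(sm3$g, c(5, 5))
})

test_that("smoothing is a convex combination and restriction rule applies", {
  b <- small_bundle()
  set.seed(2)
  st <- b$st_cells[1:150, ]
  vals <- cbind(v = runif(150, -3, 7))
  em <- b$em_cells[1:60, c("cell_id", "x", "y")]
  em$x <- st$x[1:60]; em$y <- st$y[1:60]    # co-located frames
  feats <- cbind(f = rnorm(60))
  sm <- kernel_smooth_transfer(st, vals, em, feats, restrict = FALSE)
  expect_true(all(sm$v >= min(vals) - 1e-12 & sm$v <= max(vals) + 1e-12,
                  na.rm = TRUE))

  # restrict = TRUE keeps only ST cells within d_max of an EM cell
  smr <- kernel_smooth_transfer(st, vals, em, feats, restrict = TRUE)
  kept <- smr$cell_id[smr$modality == "ST"]
  d_nn <- nn_dist(cbind(em$x, em$y), cbind(st$x, st$y))
  expect_setequal(kept, st$cell_id[d_nn <= 75])
})

test_that("gene-structure Spearman correlation is rank-based and monotone-invariant", {
  set.seed(4)
  n <- 80
  sm <- tibble::tibble(
    cell_id = as.character(1:n), modality = "ST",
    x = runif(n), y = runif(n),
    g1 = rnorm(n), g2 = rnorm(n)
  )
  sm$f1 <- exp(sm$g1)                      # monotone transform: rho = 1
  sm$f2 <- rnorm(n)
  tbl <- gene_structure_correlation(sm, genes = c("g1", "g2"),
                                    features = c("f1", "f2"))
  expect_equal(tbl$rho[tbl$gene == "g1" & tbl$feature == "f1"], 1)
  # invariance of the full table under monotone transform of a gene
  sm2 <- sm; sm2$g2 <- qexp(pnorm(sm2$g2))
  tbl2 <- gene_structure_correlation(sm2, genes = c("g1", "g2"),
                                     features = c("f1", "f2"))
  expect_equal(tbl$rho, tbl2$rho, tolerance = 1e-12)

  sm$g2 <- 1                               # constant -> NA with warning
  expect_warning(
    tbl3 <- gene_structure_correlation(sm, genes = c("g1", "g2"),
                                       features = c("f1", "f2")),
    "constant"
  )
  expect_true(all(is.na(tbl3$rho[tbl3$gene == "g2"])))
})

test_that("planted gene-feature correlation is recovered through the full chain", {
  b <- default_bundle()
  qc <- qc_filter(b$st_cells, b$st_counts)
  counts <- normalize_counts(qc$counts)
  chain <- fit_transform_chain(landmarks_of(b))
  em <- b$em_cells
  reg <- apply_chain(chain, cbind(em$x, em$y))
  em$x <- reg[, 1]; em$y <- reg[, 2]

  genes <- c(b$truth$st$markers$foamy[1:6], paste0("null-", sprintf("%03d", 1:20)))
  sm <- kernel_smooth_transfer(
    qc$cells, as.matrix(counts$norm[, genes]),
    em, as.matrix(b$em_features[, "lipid_droplet_area", drop = FALSE])
  )
  tbl <- gene_structure_correlation(sm)
  foamy_rho <- mean(tbl$rho[tbl$gene %in% b$truth$st$markers$foamy])
  null_rho <- mean(tbl$rho[grepl("^null-", tbl$gene)], na.rm = TRUE)
  expect_gt(foamy_rho, 0.3)
  expect_lt(abs(null_rho), 0.15)
})

test_that("top-correlate enrichment equals the hypergeometric tail", {
  genes <- sprintf("g%03d", 1:100)
  corr <- tibble::tibble(gene = genes, feature = "f",
                         rho = seq(1, -1, length.out = 100))
  # a 10-gene set with exactly 5 members in the top 20
  set <- c(genes[c(1, 5, 10, 15, 20)], genes[c(50, 60, 70, 80, 90)])
  res <- top_gene_enrichment(corr, "f", list(myset = set), n_top = 20)
  expect_equal(res$overlap, 5L)
  expect_equal(res$p, phyper(4, 10, 90, 20, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$p, sum(dhyper(5:10, 10, 90, 20)), tolerance = 1e-12)

  # the exact top-n as a set achieves the minimal possible p
  sets <- list(top = genes[1:20], mid = genes[41:60])
  res2 <- top_gene_enrichment(corr, "f", sets, n_top = 20)
  expect_equal(res2$term[1], "top")
  expect_equal(res2$p[res2$term == "top"],
               phyper(19, 20, 80, 20, lower.tail = FALSE), tolerance = 1e-12)
  # sets disjoint from the universe are skipped
  res3 <- top_gene_enrichment(corr, "f", list(top = genes[1:20], alien = "zz"),
                              n_top = 20)
  expect_equal(res3$term, "top")
})

test_that("random gene sets give calibrated enrichment p-values", {
  genes <- sprintf("g%03d", 1:200)
  corr <- tibble::tibble(gene = genes, feature = "f", rho = seq_along(genes))
  set.seed(12)
  ps <- vapply(1:400, function(i) {
    top_gene_enrichment(corr, "f", list(s = sample(genes, 20)), n_top = 50)$p
  }, numeric(1))
  # discrete p-values: compare the empirical cdf loosely to uniform
  expect_gt(mean(ps > 0.5), 0.3)
  expect_lt(mean(ps < 0.05), 0.12)
})
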