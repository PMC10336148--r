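# small hand-built counts fixture: 4 cells x (4 genes + 2 blanks)
make_toy_counts <- function() {
  raw <- rbind(
    c(10, 10, 5, 0, 0, 0),    # total 25 -> below the count floor
    c(10, 10, 5, 5, 0, 0),    # total 30, 4 genes
    c(1000, 800, 500, 200, 0, 0),
    c(10, 10, 5, 5, 2, 3)     # blank mean 2.5 -> too noisy
  )
  dimnames(raw) <- list(paste0("c", 1:4),
                        c("g1", "g2", "g3", "g4", "Blank-01", "Blank-02"))
  counts_matrix(raw)
}

test_that("qc_filter applies the documented inclusive bounds per criterion", {
  counts <- make_toy_counts()
  cells <- tibble::tibble(cell_id = paste0("c", 1:4),
                          volume = c(100, 41, 100, 100))
  thr <- qc_thresholds(min_genes = 4)
  res <- qc_filter(cells, counts, thr)
  # c1: 25 transcripts -> excluded; c2: exactly 30 counts, 4 genes, volume 41
  # -> retained; c4: blank mean > 1 -> excluded
  expect_setequal(res$cells$cell_id, c("c2", "c3"))
  rep <- tibble::deframe(res$report)
  expect_equal(unname(rep["low_counts"]), 1)
  expect_equal(unname(rep["high_blank"]), 1)
  expect_equal(unname(rep["total"]), 2)

  # idempotent
  res2 <- qc_filter(res$cells, res$counts, thr)
  expect_identical(res2$cells$cell_id, res$cells$cell_id)
  expect_equal(tibble::deframe(res2$report)[["total"]], 0)

  # all removed -> explicit error
  expect_error(
    qc_filter(cells, counts, qc_thresholds(min_counts = 1e6 - 1, max_counts = 1e6)),
    "empty after QC"
  )
})

test_that("qc_filter removes exactly the planted violators on synthetic data", {
  b <- small_bundle()
  res <- qc_filter(b$st_cells, b$st_counts)
  planted <- b$truth$st$violators$cell_id
  removed <- setdiff(b$st_cells$cell_id, res$cells$cell_id)
  expect_setequal(removed, planted)
})

test_that("normalization matches its closed form and preserves structure", {
  raw <- rbind(c(1, 9999), c(5000, 5000))
  dimnames(raw) <- list(c("a", "b"), c("g1", "g2"))
  counts <- normalize_counts(counts_matrix(raw))
  # a gene with count 1 in a cell of total 10000: ln(1 + 1e4 * 1 / 1e4) = ln 2
  expect_equal(unname(counts$norm["a", "g1"]), log(2), tolerance = 1e-12)
  # raw zero stays zero
  raw0 <- rbind(c(5, 0), c(3, 2))
  dimnames(raw0) <- list(c("u", "v"), c("g1", "g2"))
  expect_equal(unname(normalize_counts(counts_matrix(raw0))$norm["u", "g2"]), 0)

  b <- small_bundle()
  qc <- qc_filter(b$st_cells, b$st_counts)
  nc <- normalize_counts(qc$counts)
  rc <- spatem:::real_counts(nc)
  tot <- Matrix::rowSums(rc)
  expected <- log1p(as.matrix(rc) * 1e4 / tot)
  expect_equal(as.matrix(nc$norm), expected, tolerance = 1e-12)
  # zero pattern and ordering preserved
  expect_identical(as.matrix(nc$norm) == 0, as.matrix(rc) == 0)
  expect_identical(rownames(nc$norm), qc$cells$cell_id)
  expect_error(normalize_counts(counts_matrix(
    matrix(0, 1, 2, dimnames = list("z", c("g1", "g2"))))), "zero total")
})

test_that("module scores separate planted programs and respect set semantics", {
  b <- small_bundle()
  counts <- normalize_counts(qc_filter(b$st_cells, b$st_counts)$counts)
  cls <- qc_filter(b$st_cells, b$st_counts)$cells$class_label
  sig <- b$truth$st$markers$foamy
  sc <- module_score(counts, sig, seed = 1)
  expect_gt(mean(sc[cls == "foamy"]), mean(sc[cls == "homeostatic"]))

  # duplicate listing of a gene changes nothing (set semantics, same seed)
  sc_dup <- module_score(counts, c(sig, sig[1]), seed = 1)
  expect_identical(sc, sc_dup)

  expect_warning(module_score(counts, c(sig, "not-a-gene"), seed = 1),
                 "not measured")
  expect_error(module_score(counts, c("nope-1", "nope-2"), seed = 1),
               "none of the signature genes")
})

test_that("signature regression is a guarded no-op and yields orthogonal residuals", {
  b <- small_bundle()
  counts <- normalize_counts(qc_filter(b$st_cells, b$st_counts)$counts)
  n <- length(counts$cells)

  # all-zero scores: unchanged
  expect_warning(out <- regress_signatures(counts, matrix(0, n, 1)),
                 "constant")
  expect_equal(out$adjusted, as.matrix(counts$norm), tolerance = 1e-12)

  # a gene exactly proportional to a score has ~zero residuals
  score <- as.numeric(counts$norm[, 1])
  out2 <- regress_signatures(counts, cbind(s1 = score))
  expect_lt(sqrt(sum(out2$adjusted[, 1]^2)), 1e-8)

  # residuals orthogonal to the covariate for every gene
  cors <- suppressWarnings(abs(cor(out2$adjusted, score)))
  expect_true(all(cors < 1e-10 | is.na(cors)))
})

test_that("rank-sum markers find planted markers and are calibrated", {
  b <- small_bundle()
  counts <- normalize_counts(qc_filter(b$st_cells, b$st_counts)$counts)
  cls <- qc_filter(b$st_cells, b$st_counts)$cells$class_label
  mk <- rank_sum_markers(counts, cls, "foamy")
  planted <- b$truth$st$markers$foamy
  expect_lt(max(mk$adj_p[mk$gene %in% planted]), 0.01)
  expect_true(all(mk$log_fc[mk$gene %in% planted] > 0))

  # constant gene convention
  raw <- cbind(g1 = rep(5L, 20), g2 = rpois(20, 5))
  rownames(raw) <- paste0("c", 1:20)
  cm <- normalize_counts(counts_matrix(raw, is_blank = c(FALSE, FALSE)))
  # g1 is constant in raw but normalization divides by cell totals; build a
  # truly constant normalized gene instead
  cm$norm[, "g1"] <- 1
  mk2 <- rank_sum_markers(cm, rep(c("a", "b"), each = 10), "a")
  expect_equal(mk2$p[mk2$gene == "g1"], 1)

  # permuted labels: p-values uniform (KS)
  set.seed(11)
  perm <- sample(cls)
  mk3 <- rank_sum_markers(counts, perm, "foamy")
  ks <- suppressWarnings(ks.test(mk3$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("graph clustering recovers separated blobs and degenerate limits", {
  set.seed(3)
  x <- rbind(matrix(rnorm(200, 0), ncol = 2),
             matrix(rnorm(200, 8), ncol = 2),
             cbind(rnorm(100, 16), rnorm(100, 0)))
  truth <- rep(1:3, each = 100)
  cl <- expect_warning(cluster_graph(x, n_pcs = 2, k_snn = 15,
                                     resolution = 0.2, seed = 1), NA)
  expect_gte(ari(cl, truth), 0.95)

  # duplicates co-cluster
  xd <- rbind(x, x)
  cld <- cluster_graph(xd, n_pcs = 2, k_snn = 15, seed = 1)
  expect_true(all(cld[seq_len(nrow(x))] == cld[nrow(x) + seq_len(nrow(x))]))

  # resolution -> 0 merges everything (on a connected neighbor graph)
  set.seed(5)
  xc <- matrix(rnorm(400), ncol = 2)
  cl0 <- cluster_graph(xc, n_pcs = 2, k_snn = 15, resolution = 0, seed = 1)
  expect_equal(nlevels(droplevels(cl0)), 1)
  cl1 <- cluster_graph(xc, n_pcs = 2, k_snn = 15, resolution = 1, seed = 1)
  expect_gt(nlevels(droplevels(cl1)), 1)

  expect_warning(cluster_graph(x[1:10, ], n_pcs = 50, k_snn = 3, seed = 1),
                 "clamped")
})

test_that("label transfer reproduces identity and recovers synthetic classes", {
  b <- default_bundle()
  counts <- normalize_counts(qc_filter(b$st_cells, b$st_counts)$counts)
  cls <- qc_filter(b$st_cells, b$st_counts)$cells$class_label

  self <- transfer_labels(counts, cls, counts, n_dims = 10, k = 10)
  expect_identical(self$label, cls)
  expect_true(all(self$confidence == 1))

  # scRNA-seq -> spatial panel transfer on shared genes
  sc_norm <- normalize_counts(b$sc_counts)
  tr <- transfer_labels(sc_norm, b$truth$sc$class_label, counts,
                        n_dims = 15, k = 20)
  expect_gte(mean(tr$label == cls), 0.9)

  # uniform-noise query is less confident than the matched query
  set.seed(4)
  noise <- matrix(rpois(200 * ncol(counts$raw), 2), 200,
                  dimnames = list(paste0("n", 1:200), colnames(counts$raw)))
  nq <- normalize_counts(counts_matrix(noise, is_blank = counts$is_blank))
  trn <- transfer_labels(sc_norm, b$truth$sc$class_label, nq)
  expect_lt(median(trn$confidence), median(tr$confidence))
})

test_that("gene imputation filters, passes panel genes through, and recovers programs", {
  b <- small_bundle()
  counts <- normalize_counts(qc_filter(b$st_cells, b$st_counts)$counts)
  cls <- qc_filter(b$st_cells, b$st_counts)$cells$class_label
  sc_norm <- normalize_counts(b$sc_counts)

  # plant a low-expression reference gene: < 10 total counts
  sc_low <- sc_norm
  low_gene <- colnames(sc_low$raw)[ncol(sc_low$raw)]
  sc_low$raw[, low_gene] <- 0
  sc_low$raw[1:9, low_gene] <- 1
  sc_low <- normalize_counts(sc_low)
  imp <- impute_genes(sc_low, counts)
  expect_false(low_gene %in% colnames(imp$norm))

  # measured genes pass through exactly
  measured <- colnames(counts$norm)
  expect_equal(imp$norm[, measured], as.matrix(counts$norm), tolerance = 1e-12)

  # planted non-panel foamy markers impute higher in foamy-labelled cells
  extra <- b$truth$sc$extra_markers$foamy
  extra <- intersect(extra, colnames(imp$norm))
  expect_gt(length(extra), 0)
  vals <- rowMeans(imp$norm[, extra, drop = FALSE])
  wt <- wilcox.test(vals[cls == "foamy"], vals[cls == "homeostatic"],
                    alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})
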