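# shared fixtures: one small and one default-size bundle, built once per run

.fixture_env <- new.env(parent = emptyenv())

small_config <- function(...) {
  defaults <- list(seed = 1L, n_cells_st = 500L, n_cells_em = 250L,
                   n_cells_sc = 400L, n_genes_panel = 90L,
                   n_genes_full = 400L)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

small_bundle <- function(seed = 1L) {
  key <- paste0("small_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_bundle(small_config(seed))
  }
  .fixture_env[[key]]
}

default_bundle <- function(seed = 1L) {
  key <- paste0("default_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_bundle(synth_config(seed = seed))
  }
  .fixture_env[[key]]
}

# adjusted Rand index (pair-counting form)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

landmarks_of <- function(bundle) {
  landmark_set(bundle$landmarks[, c("x_src", "y_src")],
               bundle$landmarks[, c("x_dst", "y_dst")])
}

# density_map constructor from a raw histogram (test doubles for emd2d)
raw_map <- function(z, xc = seq_len(nrow(z)), yc = seq_len(ncol(z))) {
  structure(list(z = z / sum(z), xc = xc, yc = yc, sigma = 1),
            class = "density_map")
}

# exact transportation LP oracle (boot::simplex) for small problems
emd_lp_oracle <- function(wa, wb, cost) {
  m <- length(wa); n <- length(wb)
  A3 <- matrix(0, m + n, m * n)
  for (i in seq_len(m)) A3[i, (seq_len(n) - 1) * m + i] <- 1
  for (j in seq_len(n)) A3[m + j, (j - 1) * m + seq_len(m)] <- 1
  A3 <- A3[-(m + n), , drop = FALSE]          # drop redundant row
  b3 <- c(wa, wb)[-(m + n)]
  unname(boot::simplex(a = as.vector(cost), A3 = A3, b3 = b3, maxi = FALSE)$value)
}

# brute-force GSEA running-sum oracle
gsea_oracle <- function(ranks, set, weight = 1) {
  ord <- order(-ranks, names(ranks))
  r <- ranks[ord]
  hit <- names(r) %in% set
  inc <- abs(r)^weight * hit
  inc <- if (sum(inc) == 0) hit / sum(hit) else inc / sum(inc)
  dec <- (!hit) / sum(!hit)
  run <- cumsum(inc - dec)
  unname(run[which.max(abs(run))])
}

# nearest-neighbour distances from each row of `from` to the point set `to`
nn_dist <- function(to, from) {
  spatem:::cpp_knn(as.matrix(to), as.matrix(from), 1, FALSE)$dist[, 1]
}
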