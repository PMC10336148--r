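#' PCA + shared-nearest-neighbor graph clustering
#'
#' Standard single-cell community detection: principal components of the
#' (already scaled) feature matrix, a k-nearest-neighbor graph in PC space,
#' Jaccard-weighted shared-nearest-neighbor (SNN) edges, and Louvain
#' community detection. Deterministic under `seed`.
#'
#' @param features numeric matrix, observations in rows (cells) and scaled
#'   variables in columns.
#' @param n_pcs number of principal components (clamped with a warning when
#'   it exceeds what the data support; default 20).
#' @param k_snn neighbors used to build the SNN graph (default 20).
#' @param resolution Louvain resolution; smaller values merge communities and
#'   `resolution = 0` yields a single cluster.
#' @param seed integer seed for the (randomized) Louvain pass.
#' @return Integer factor of cluster labels, one per row of `features`.
#' @examples
#' x <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 8), 50))
#' table(cluster_graph(x, n_pcs = 2, k_snn = 10))
#' @export
cluster_graph <- function(features, n_pcs = 20, k_snn = 20, resolution = 1,
                          seed = 0L) {
  features <- as.matrix(features)
  n <- nrow(features)
  max_pcs <- min(nrow(features) - 1L, ncol(features))
  if (n_pcs > max_pcs) {
    rlang::warn(sprintf("n_pcs clamped from %d to %d", n_pcs, max_pcs))
    n_pcs <- max(1L, max_pcs)
  }
  pcs <- stats::prcomp(features, center = TRUE, scale. = FALSE,
                       rank. = n_pcs)$x
  k_snn <- min(k_snn, n - 1L)
  nn <- cpp_knn(pcs, pcs, k_snn, TRUE)$index
  # neighbor sets include the cell itself (standard SNN convention)
  sets <- cbind(seq_len(n), nn)

  edges <- snn_edges(sets)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$i, to = edges$j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  withr::local_seed(seed)
  cl <- igraph::cluster_louvain(g, weights = edges$w, resolution = resolution)
  labels <- igraph::membership(cl)
  factor(as.integer(labels[as.character(seq_len(n))]))
}

# Jaccard weights between neighbor sets, over candidate pairs (i, j) where j
# is a neighbor of i.
snn_edges <- function(sets) {
  n <- nrow(sets); k <- ncol(sets)
  memb <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k), j = as.vector(sets),
    x = 1, dims = c(n, n)
  )
  shared <- memb %*% Matrix::t(memb)          # |A n B|
  shared <- methods::as(shared, "TsparseMatrix")
  i <- shared@i + 1L; j <- shared@j + 1L; s <- shared@x
  keep <- i < j
  i <- i[keep]; j <- j[keep]; s <- s[keep]
  w <- s / (2 * k - s)                        # Jaccard: |A n B| / |A u B|
  pos <- w > 0
  list(i = i[pos], j = j[pos], w = w[pos])
}

#' Transfer labels from a reference to a query dataset
#'
#' Projects both datasets into a reduced space fitted on the shared non-blank
#' genes of the (normalized, scaled) reference, then gives each query cell
#' the distance-weighted vote of its `k` nearest reference cells. Confidence
#' is the winning vote share. A query cell sitting exactly on a reference
#' cell adopts that cell's label with confidence 1.
#'
#' @param ref_counts,query_counts normalized [counts_matrix()] objects.
#' @param ref_labels per-cell labels of the reference, in order.
#' @param n_dims dimensions of the shared reduction (default 15).
#' @param k reference neighbors voting per query cell (default 20).
#' @return Tibble with `cell_id`, `label`, `confidence`.
#' @export
transfer_labels <- function(ref_counts, ref_labels, query_counts,
                            n_dims = 15, k = 20) {
  proj <- joint_projection(ref_counts, query_counts, n_dims)
  ref_labels <- as.character(ref_labels)
  stopifnot(length(ref_labels) == nrow(proj$ref))

  k <- min(k, nrow(proj$ref))
  nn <- cpp_knn(proj$ref, proj$query, k, FALSE)
  votes <- vote_labels(nn, ref_labels)
  tibble::tibble(
    cell_id = query_counts$cells,
    label = votes$label,
    confidence = votes$confidence
  )
}

vote_labels <- function(nn, ref_labels) {
  n <- nrow(nn$index)
  label <- character(n); confidence <- numeric(n)
  for (i in seq_len(n)) {
    idx <- nn$index[i, ]; d <- nn$dist[i, ]
    ok <- !is.na(idx)
    idx <- idx[ok]; d <- d[ok]
    if (any(d == 0)) {
      w <- as.numeric(d == 0)
    } else {
      w <- 1 / d
    }
    tab <- tapply(w, ref_labels[idx], sum)
    tab <- tab / sum(tab)
    label[i] <- names(tab)[which.max(tab)]
    confidence[i] <- max(tab)
  }
  list(label = label, confidence = confidence)
}

# Fit a PCA on the scaled reference over shared genes and project both sets
# with the reference's centering/scaling.
joint_projection <- function(ref_counts, query_counts, n_dims) {
  stopifnot(inherits(ref_counts, "counts_matrix"),
            inherits(query_counts, "counts_matrix"))
  if (is.null(ref_counts$norm) || is.null(query_counts$norm)) {
    rlang::abort("run normalize_counts() on both datasets first")
  }
  shared <- intersect(colnames(ref_counts$norm), colnames(query_counts$norm))
  if (length(shared) < 10) rlang::abort("fewer than 10 shared genes")
  R <- as.matrix(ref_counts$norm[, shared, drop = FALSE])
  Q <- as.matrix(query_counts$norm[, shared, drop = FALSE])
  mu <- colMeans(R)
  sg <- apply(R, 2, stats::sd)
  sg[sg == 0] <- 1
  Rs <- sweep(sweep(R, 2, mu), 2, sg, `/`)
  Qs <- sweep(sweep(Q, 2, mu), 2, sg, `/`)
  n_dims <- min(n_dims, dim(Rs) - 1L)
  pca <- stats::prcomp(Rs, center = FALSE, scale. = FALSE, rank. = n_dims)
  list(ref = pca$x, query = Qs %*% pca$rotation)
}

#' Impute unmeasured genes in a panel dataset from a full-transcriptome reference
#'
#' Reference genes failing the expression filter (fewer than `min_counts`
#' total raw counts or detected in fewer than `min_cells` cells) are dropped.
#' Remaining genes absent from the query panel are imputed per query cell as
#' the distance-weighted average of its `k` reference neighbors in the shared
#' reduced space (same neighbor structure as [transfer_labels()]). Measured
#' panel genes pass through unchanged.
#'
#' @inheritParams transfer_labels
#' @param min_counts,min_cells reference expression filter (defaults 10, 20).
#' @return A list: `norm` (cells x genes matrix of measured + imputed
#'   normalized expression), `provenance` (per gene: "measured"/"imputed"),
#'   `n_dropped` (reference genes failing the filter).
#' @export
impute_genes <- function(ref_counts, query_counts, min_counts = 10,
                         min_cells = 20, n_dims = 15, k = 20) {
  stopifnot(inherits(ref_counts, "counts_matrix"))
  raw <- real_counts(ref_counts)
  tot <- Matrix::colSums(raw)
  det <- Matrix::colSums(raw > 0)
  eligible <- colnames(raw)[tot >= min_counts & det >= min_cells]
  if (length(eligible) == 0) rlang::abort("no reference genes pass the filter")

  measured <- colnames(query_counts$norm)
  if (!length(intersect(measured, colnames(ref_counts$norm)))) {
    rlang::abort("no overlap between query panel and reference genes")
  }
  to_impute <- setdiff(eligible, measured)

  proj <- joint_projection(ref_counts, query_counts, n_dims)
  k <- min(k, nrow(proj$ref))
  nn <- cpp_knn(proj$ref, proj$query, k, FALSE)

  refX <- as.matrix(ref_counts$norm[, to_impute, drop = FALSE])
  nq <- nrow(proj$query)
  imputed <- matrix(0, nq, length(to_impute),
                    dimnames = list(query_counts$cells, to_impute))
  for (i in seq_len(nq)) {
    idx <- nn$index[i, ]; d <- nn$dist[i, ]
    ok <- !is.na(idx); idx <- idx[ok]; d <- d[ok]
    w <- if (any(d == 0)) as.numeric(d == 0) else 1 / d
    w <- w / sum(w)
    imputed[i, ] <- w %*% refX[idx, , drop = FALSE]
  }
  out <- cbind(as.matrix(query_counts$norm), imputed)
  prov <- setNames(
    rep(c("measured", "imputed"), c(length(measured), length(to_impute))),
    c(measured, to_impute)
  )
  list(norm = out, provenance = prov,
       n_dropped = sum(!(colnames(raw) %in% eligible)))
}
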