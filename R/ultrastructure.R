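#' Per-cell organelle label-mask stack
#'
#' Binary masks (logical or 0/1 matrices, identical dimensions) for one cell:
#' `whole_cell` plus any of `nucleus`, `heterochromatin`, `lysosome`,
#' `lipid_droplet`, `mitochondria`, `er` (curvilinear), and
#' `organellar_cytoplasm`. Organelle masks must lie within the whole-cell
#' mask and heterochromatin within the nucleus.
#'
#' @param masks named list of binary matrices; `whole_cell` required.
#' @param px_size_nm pixel edge length in nanometres.
#' @param origin global position (µm) of the mask's (0, 0) corner.
#' @return A `label_mask_stack`.
#' @export
label_mask_stack <- function(masks, px_size_nm = 20, origin = c(0, 0)) {
  stopifnot(is.list(masks), "whole_cell" %in% names(masks))
  masks <- lapply(masks, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "logical"
    m
  })
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    rlang::abort("all masks must share dimensions")
  }
  if ("nucleus" %in% names(masks) &&
      any(masks$nucleus & !masks$whole_cell)) {
    rlang::abort("nucleus mask extends beyond the whole-cell mask")
  }
  if (all(c("heterochromatin", "nucleus") %in% names(masks)) &&
      any(masks$heterochromatin & !masks$nucleus)) {
    rlang::abort("heterochromatin mask extends beyond the nucleus")
  }
  structure(list(masks = masks, px_size_nm = px_size_nm, origin = origin),
            class = "label_mask_stack")
}

# remove connected components smaller than min_px (stray pixels)
clean_stray_pixels <- function(mask, min_px = 5) {
  if (!any(mask)) return(mask)
  lab <- label_components(mask, connectivity = 8)
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes < min_px)
  if (length(drop)) mask[lab %in% drop] <- FALSE
  mask
}

# Zhang-Suen thinning, vectorized over the image
zhang_suen_thin <- function(mask, max_iter = 200) {
  img <- mask
  pad <- function(m) {
    out <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
    out[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    out
  }
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (phase in 1:2) {
      p <- pad(img)
      nr <- nrow(img); nc <- ncol(img)
      ctr <- p[2:(nr + 1), 2:(nc + 1)]
      # 8-neighbourhood, clockwise from north (matrix rows = x, cols = y):
      p2 <- p[2:(nr + 1), 1:nc]        # N
      p3 <- p[3:(nr + 2), 1:nc]        # NE
      p4 <- p[3:(nr + 2), 2:(nc + 1)]  # E
      p5 <- p[3:(nr + 2), 3:(nc + 2)]  # SE
      p6 <- p[2:(nr + 1), 3:(nc + 2)]  # S
      p7 <- p[1:nr,       3:(nc + 2)]  # SW
      p8 <- p[1:nr,       2:(nc + 1)]  # W
      p9 <- p[1:nr,       1:nc]        # NW
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (phase == 1) {
        cond <- ctr & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- ctr & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { img[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  img
}

# arc length of a (thin) curve mask: minimum spanning forest over the
# 8-neighbour adjacency of skeleton pixels, edge weights 1 or sqrt(2) px
skeleton_arc_length <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  n <- nrow(px)
  if (n <= 1) return(0)
  idx <- matrix(0L, nrow(mask), ncol(mask))
  idx[px] <- seq_len(n)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  shifts <- list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)), c(1L, -1L, sqrt(2)))
  for (s in shifts) {
    ii <- px[, 1] + s[1]; jj <- px[, 2] + s[2]
    ok <- ii >= 1 & ii <= nrow(mask) & jj >= 1 & jj <= ncol(mask)
    nb <- rep(0L, n)
    nb[ok] <- idx[cbind(ii[ok], jj[ok])]
    hit <- nb > 0
    from <- c(from, which(hit)); to <- c(to, nb[hit]); w <- c(w, rep(s[3], sum(hit)))
  }
  if (!length(from)) return(0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = FALSE, vertices = data.frame(name = seq_len(n))
  )
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  sum(igraph::E(mst)$weight)
}

#' Extract structural features from a label-mask stack
#'
#' Areas as pixel counts (and µm²), endoplasmic-reticulum length as the arc
#' length of the skeletonized ER mask, empty cytoplasm as the whole-cell area
#' minus the union of all other segmentations, the cell position as the
#' whole-cell bounding-box center in global coordinates, and a manifest of
#' non-redundant ratios (0/0 reported as missing). Connected components
#' below `min_px` pixels are removed as stray pixels first.
#'
#' @param stack a [label_mask_stack()].
#' @param min_px stray-pixel threshold (default 5).
#' @param ratios ratio manifest, see [structural_ratio_manifest()].
#' @return One-row tibble of features.
#' @export
extract_features <- function(stack, min_px = 5,
                             ratios = structural_ratio_manifest()) {
  stopifnot(inherits(stack, "label_mask_stack"))
  masks <- lapply(stack$masks, clean_stray_pixels, min_px = min_px)
  px_um <- stack$px_size_nm / 1000          # µm per pixel edge
  organelles <- setdiff(names(masks), "whole_cell")

  area_px <- vapply(masks, sum, numeric(1))
  # union of all non-whole-cell masks (heterochromatin lies inside nucleus,
  # union avoids double counting)
  if (length(organelles)) {
    un <- Reduce(`|`, masks[organelles])
  } else {
    un <- masks$whole_cell & FALSE
  }
  empty_px <- sum(masks$whole_cell & !un)

  bb <- which(masks$whole_cell, arr.ind = TRUE)
  if (nrow(bb) == 0) rlang::abort("empty whole-cell mask")
  center <- c(mean(range(bb[, 1])), mean(range(bb[, 2]))) * px_um + stack$origin

  er_len <- if ("er" %in% names(masks) && any(masks$er)) {
    skeleton_arc_length(zhang_suen_thin(masks$er)) * px_um
  } else 0

  vals <- c(
    setNames(as.list(area_px), paste0(names(area_px), "_px")),
    setNames(as.list(area_px * px_um^2), paste0(names(area_px), "_area")),
    empty_cytoplasm_px = empty_px,
    empty_cytoplasm_area = empty_px * px_um^2,
    er_length = er_len,
    x = center[1], y = center[2]
  )
  row <- tibble::as_tibble(vals)
  for (r in ratios) {
    num <- paste0(r[1], "_px"); den <- paste0(r[2], "_px")
    if (!num %in% names(row) || !den %in% names(row)) next
    nm <- paste0("ratio_", r[1], "_", r[2])
    row[[nm]] <- ifelse(row[[den]] > 0, row[[num]] / row[[den]], NA_real_)
  }
  row
}

#' Canonical ratio manifest for structural metrics
#'
#' The default manifest yields, together with the base area/length measures,
#' a 32-metric feature set: every organelle area relative to the whole cell,
#' compartment-internal shares (heterochromatin within the nucleus, each
#' organelle within the cytoplasm), and the nucleus-to-cytoplasm balance.
#'
#' @return List of `c(numerator, denominator)` pairs (mask names;
#'   `empty_cytoplasm` is a derived measure).
#' @export
structural_ratio_manifest <- function() {
  list(
    c("nucleus", "whole_cell"),
    c("heterochromatin", "whole_cell"),
    c("lysosome", "whole_cell"),
    c("lipid_droplet", "whole_cell"),
    c("mitochondria", "whole_cell"),
    c("er", "whole_cell"),
    c("organellar_cytoplasm", "whole_cell"),
    c("empty_cytoplasm", "whole_cell"),
    c("heterochromatin", "nucleus"),
    c("lysosome", "nucleus"),
    c("lipid_droplet", "nucleus"),
    c("mitochondria", "nucleus"),
    c("lipid_droplet", "lysosome"),
    c("mitochondria", "lysosome"),
    c("er", "organellar_cytoplasm"),
    c("empty_cytoplasm", "organellar_cytoplasm")
  )
}

#' Cluster cells on structural features
#'
#' Z-scales the feature columns (missing ratio values are imputed as 0 with a
#' companion missingness indicator) and delegates to [cluster_graph()].
#'
#' @param features tibble of per-cell features (non-feature columns
#'   `cell_id`, `x`, `y` are ignored).
#' @param n_pcs,resolution,seed see [cluster_graph()].
#' @return Factor of cluster labels.
#' @export
cluster_structural <- function(features, n_pcs = 20, resolution = 1,
                               seed = 0L) {
  X <- features |>
    dplyr::select(-dplyr::any_of(c("cell_id", "x", "y"))) |>
    as.matrix()
  miss <- is.na(X)
  ind <- NULL
  if (any(miss)) {
    ind <- 1 * miss[, colSums(miss) > 0, drop = FALSE]
    colnames(ind) <- paste0(colnames(ind), "_missing")
    X[miss] <- 0
  }
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  X <- scale(X)
  if (!is.null(ind)) X <- cbind(X, ind)
  cluster_graph(X, n_pcs = n_pcs, k_snn = 20, resolution = resolution,
                seed = seed)
}

#' Match expert-annotated cells to feature-table cells by position
#'
#' Each expert cell is assigned the nearest featured cell (Euclidean);
#' many-to-one matches are allowed but flagged.
#'
#' @param expert,featured tibbles with `cell_id`, `x`, `y` in a common frame.
#' @return Tibble with `expert_id`, `matched_id`, `distance`, `shared`
#'   (TRUE when the featured cell is matched by several expert cells).
#' @export
match_expert_labels <- function(expert, featured) {
  if (nrow(expert) == 0 || nrow(featured) == 0) {
    rlang::abort("both cell tables must be nonempty")
  }
  nn <- cpp_knn(cbind(featured$x, featured$y), cbind(expert$x, expert$y),
                1, FALSE)
  matched <- featured$cell_id[nn$index[, 1]]
  dup <- duplicated(matched) | duplicated(matched, fromLast = TRUE)
  if (any(dup)) rlang::warn("many-to-one match(es) flagged in `shared`")
  tibble::tibble(
    expert_id = expert$cell_id,
    matched_id = matched,
    distance = nn$dist[, 1],
    shared = dup
  )
}

#' One-sided Fisher overlap test between two labelings
#'
#' For every class pair, builds the 2x2 table (in class a x in class b vs
#' rest) over the matched cells and tests over-representation with a
#' one-sided (greater) Fisher exact test.
#'
#' @param labels_a,labels_b paired label vectors (same cells, same order).
#' @return Tibble with `class_a`, `class_b`, `count`, `p`; plus the full
#'   contingency matrix as attribute `"contingency"`.
#' @export
overlap_test <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  labels_a <- as.character(labels_a); labels_b <- as.character(labels_b)
  if (length(unique(labels_a)) < 2 || length(unique(labels_b)) < 2) {
    rlang::abort("need >= 2 classes on each side")
  }
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  grid <- expand.grid(a = rownames(tab), b = colnames(tab),
                      stringsAsFactors = FALSE)
  res <- purrr::map2(grid$a, grid$b, function(ca, cb) {
    x11 <- tab[ca, cb]
    x12 <- sum(tab[ca, ]) - x11
    x21 <- sum(tab[, cb]) - x11
    x22 <- n - x11 - x12 - x21
    p <- stats::fisher.test(matrix(c(x11, x21, x12, x22), 2),
                            alternative = "greater")$p.value
    tibble::tibble(class_a = ca, class_b = cb, count = as.integer(x11), p = p)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "contingency") <- tab
  out
}
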