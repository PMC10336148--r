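#' Normalized 2D density map of a point set
#'
#' Gaussian kernel density with bandwidth `sigma`, evaluated at the centers
#' of a regular `grid_size` x `grid_size` grid spanning the window's bounding
#' box, set to zero outside a polygonal window (clip-then-renormalize) and
#' normalized to total mass 1.
#'
#' @param points matrix or data frame of points (`x`, `y`, micrometres).
#' @param window polygon matrix, or a list with `xlim`/`ylim`; defines the
#'   grid extent (and the clip region when a polygon).
#' @param sigma KDE bandwidth in micrometres.
#' @param grid_size pixels per axis (default 50).
#' @return A `density_map`: list with `z` (grid matrix, sums to 1), `xc`,
#'   `yc` (bin centers), `sigma`.
#' @export
density_map <- function(points, window, sigma, grid_size = 50) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  points <- as.matrix(points)
  if (nrow(points) == 0) rlang::abort("density_map needs at least one point")
  stopifnot(sigma > 0)
  if (is.list(window) && !is.data.frame(window)) {
    xlim <- window$xlim; ylim <- window$ylim; poly <- NULL
  } else {
    poly <- as_polygon(window)
    xlim <- range(poly[, 1]); ylim <- range(poly[, 2])
  }
  xc <- seq(xlim[1], xlim[2], length.out = grid_size + 1)
  xc <- (xc[-1] + xc[-length(xc)]) / 2
  yc <- seq(ylim[1], ylim[2], length.out = grid_size + 1)
  yc <- (yc[-1] + yc[-length(yc)]) / 2
  z <- kde_grid(points, xc, yc, sigma)
  if (!is.null(poly)) {
    grid <- cbind(rep(xc, times = grid_size), rep(yc, each = grid_size))
    inside <- matrix(points_in_polygon(grid, poly), grid_size, grid_size)
    z[!inside] <- 0
  }
  if (sum(z) == 0) rlang::abort("all density mass clipped away")
  z <- z / sum(z)
  structure(list(z = z, xc = xc, yc = yc, sigma = sigma),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %dx%d grid, sigma = %g µm\n",
              nrow(x$z), ncol(x$z), x$sigma))
  invisible(x)
}

#' @method autoplot density_map
#' @export
autoplot.density_map <- function(object, ...) {
  df <- expand.grid(x = object$xc, y = object$yc)
  df$density <- as.vector(object$z)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("Density map (sigma = %g µm)", object$sigma)) +
    ggplot2::theme_minimal()
}

#' Exact Earth Mover's Distance between two density maps
#'
#' Solves the discrete optimal-transport problem between the two normalized
#' histograms with Euclidean ground distance between bin centers, by a dense
#' transportation (network) simplex; the result is the minimal transport cost
#' in micrometres. Bins carrying negligible mass (< 1e-12 of the total) are
#' pruned before the solve. For grids above `exact_max` x `exact_max` an
#' entropic (Sinkhorn) approximation is used with a warning.
#'
#' @param a,b `density_map` objects on the same grid geometry.
#' @param exact_max largest grid edge solved exactly (default 64).
#' @return Nonnegative scalar, micrometres.
#' @export
emd2d <- function(a, b, exact_max = 64) {
  stopifnot(inherits(a, "density_map"), inherits(b, "density_map"))
  if (!isTRUE(all.equal(a$xc, b$xc)) || !isTRUE(all.equal(a$yc, b$yc))) {
    rlang::abort("density maps must share the same grid geometry")
  }
  ma <- sum(a$z); mb <- sum(b$z)
  if (abs(ma - mb) > 1e-6) rlang::abort("mass mismatch exceeds 1e-6")

  gx <- rep(a$xc, times = ncol(a$z))
  gy <- rep(a$yc, each = nrow(a$z))
  wa <- as.vector(a$z) / ma
  wb <- as.vector(b$z) / mb
  ia <- which(wa > 1e-12); ib <- which(wb > 1e-12)
  wa <- wa[ia] / sum(wa[ia])
  wb <- wb[ib] / sum(wb[ib])
  cost <- sqrt(outer(gx[ia]^2 + gy[ia]^2, gx[ib]^2 + gy[ib]^2, `+`) -
                 2 * (outer(gx[ia], gx[ib]) + outer(gy[ia], gy[ib])))
  cost[cost < 0 | is.nan(cost)] <- 0
  if (max(dim(a$z)) > exact_max) {
    rlang::warn("grid larger than exact_max: using entropic approximation")
    reg <- 1e-3 * stats::median(cost)
    return(cpp_sinkhorn(wa, wb, cost, reg, 2000L, 1e-10)$cost)
  }
  res <- cpp_emd(wa, wb, cost, max_iter = 200000L)
  if (!res$converged) rlang::warn("transport solve hit the iteration cap")
  max(res$cost, 0)
}

#' Multiscale Earth Mover's Distance between two point patterns
#'
#' Mean of [emd2d()] over density maps of the two point sets computed at each
#' smoothing scale; the default scales are 25/50/75/100 micrometres.
#'
#' @param points_a,points_b point sets (matrix or data frame, `x`, `y`).
#' @param window shared window (see [density_map()]).
#' @param sigmas KDE bandwidths in micrometres.
#' @param grid_size pixels per axis.
#' @return Nonnegative scalar, micrometres.
#' @export
multiscale_emd <- function(points_a, points_b, window,
                           sigmas = c(25, 50, 75, 100), grid_size = 50) {
  per <- vapply(sigmas, function(s) {
    emd2d(density_map(points_a, window, s, grid_size),
          density_map(points_b, window, s, grid_size))
  }, numeric(1))
  mean(per)
}

#' Pairwise multiscale EMD matrix between the classes of two cell tables
#'
#' Computes, in a common coordinate frame, the multiscale EMD between every
#' class of `cells_a` and every class of `cells_b`.
#'
#' @param cells_a,cells_b tibbles with `x`, `y`, `class_label` (already
#'   registered into a common frame).
#' @param window shared window; defaults to the joint bounding box.
#' @param sigmas,grid_size see [multiscale_emd()].
#' @return An `emd_matrix`: numeric matrix (classes of a x classes of b) with
#'   attribute `per_sigma` (3D array) and the settings.
#' @export
emd_class_matrix <- function(cells_a, cells_b, window = NULL,
                             sigmas = c(25, 50, 75, 100), grid_size = 50) {
  if (is.null(window)) {
    window <- rect_window(range(c(cells_a$x, cells_b$x)),
                          range(c(cells_a$y, cells_b$y)))
  }
  ca <- sort(unique(cells_a$class_label))
  cb <- sort(unique(cells_b$class_label))
  maps_a <- lapply(ca, function(cl) lapply(sigmas, function(s) {
    density_map(dplyr::filter(cells_a, .data$class_label == cl), window, s, grid_size)
  }))
  maps_b <- lapply(cb, function(cl) lapply(sigmas, function(s) {
    density_map(dplyr::filter(cells_b, .data$class_label == cl), window, s, grid_size)
  }))
  per <- array(NA_real_, c(length(ca), length(cb), length(sigmas)),
               dimnames = list(ca, cb, paste0("sigma_", sigmas)))
  for (i in seq_along(ca)) {
    for (j in seq_along(cb)) {
      for (s in seq_along(sigmas)) {
        per[i, j, s] <- emd2d(maps_a[[i]][[s]], maps_b[[j]][[s]])
      }
    }
  }
  m <- apply(per, c(1, 2), mean)
  structure(m, per_sigma = per, sigmas = sigmas, grid_size = grid_size,
            class = c("emd_matrix", class(m)))
}

#' Row- or column-standardize a comparison matrix
#'
#' @param m numeric matrix (e.g. an `emd_matrix`).
#' @param axis `"row"` or `"col"`.
#' @return Matrix of z-scores; zero-variance lines become zeros with a
#'   warning.
#' @export
zscore_matrix <- function(m, axis = c("row", "col")) {
  axis <- match.arg(axis)
  m <- unclass(m); attr(m, "per_sigma") <- NULL
  if (axis == "col") return(t(zscore_matrix(t(m), "row")))
  if (ncol(m) < 2) rlang::abort("need >= 2 entries per scored line")
  out <- t(apply(m, 1, function(r) {
    s <- stats::sd(r)
    if (s == 0) return(rep(0, length(r)))
    (r - mean(r)) / s
  }))
  if (any(apply(m, 1, stats::sd) == 0)) {
    rlang::warn("zero-variance line(s) set to 0")
  }
  dimnames(out) <- dimnames(m)
  out
}

#' @method autoplot emd_matrix
#' @export
autoplot.emd_matrix <- function(object, zscore = NULL, ...) {
  m <- unclass(object); attr(m, "per_sigma") <- NULL; attr(m, "sigmas") <- NULL
  attr(m, "grid_size") <- NULL
  if (!is.null(zscore)) m <- zscore_matrix(m, zscore)
  df <- as.data.frame(as.table(m))
  names(df) <- c("class_a", "class_b", "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$class_b, .data$class_a,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = if (is.null(zscore)) "EMD (µm)" else "z",
                  title = "Multiscale EMD between class density maps") +
    ggplot2::theme_minimal()
}
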