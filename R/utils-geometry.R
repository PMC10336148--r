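# Plain-matrix 2D geometry helpers. Polygons are closed implicitly: a matrix
# (or data frame) with columns x, y listing vertices once, in order.

as_polygon <- function(p) {
  if (is.data.frame(p)) p <- cbind(p$x, p$y)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2 || nrow(p) < 3) {
    rlang::abort("a polygon needs >= 3 vertices with columns x, y")
  }
  colnames(p) <- c("x", "y")
  # drop a repeated closing vertex
  if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  p
}

#' Area of a simple polygon (shoelace formula)
#'
#' @param poly matrix or data frame of vertices with columns `x`, `y`
#'   (micrometres), listed once in order.
#' @return Area in square micrometres (always positive).
#' @export
polygon_area <- function(poly) {
  p <- as_polygon(poly)
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

# Boundary-inclusive point-in-polygon: mgcv::in.out for the interior plus a
# distance-to-boundary tolerance so points exactly on an edge count as inside.
points_in_polygon <- function(pts, poly, tol = 1e-9) {
  p <- as_polygon(poly)
  pts <- as.matrix(pts)
  bnd <- rbind(p, p[1, ])
  inside <- mgcv::in.out(bnd, pts)
  on_edge <- dist_to_polygon(pts, p) <= tol
  inside | on_edge
}

# Minimum Euclidean distance from each point to the polygon boundary.
dist_to_polygon <- function(pts, poly) {
  p <- as_polygon(poly)
  pts <- as.matrix(pts)
  n <- nrow(p)
  dmin <- rep(Inf, nrow(pts))
  for (s in seq_len(n)) {
    a <- p[s, ]; b <- p[if (s == n) 1 else s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- (pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (pts[, 1] - (a[1] + t * ab[1]))^2 + (pts[, 2] - (a[2] + t * ab[2]))^2
    }
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

# Signed distance convention used for ring assignment: 0 inside or on the
# polygon, positive Euclidean distance outside.
outside_distance <- function(pts, poly, tol = 1e-9) {
  d <- dist_to_polygon(pts, poly)
  d[points_in_polygon(pts, poly, tol = tol)] <- 0
  d
}

# Rectangular window helper -------------------------------------------------

#' Rectangular window polygon
#'
#' @param xlim,ylim numeric length-2 ranges in micrometres.
#' @return A 4-vertex polygon matrix.
#' @export
rect_window <- function(xlim, ylim) {
  as_polygon(cbind(
    x = c(xlim[1], xlim[2], xlim[2], xlim[1]),
    y = c(ylim[1], ylim[1], ylim[2], ylim[2])
  ))
}

# Raster a polygon onto a logical grid of pixel centers. Returns the mask and
# grid geometry; used for edge-correction lookups and ring contouring.
rasterize_polygon <- function(poly, resolution, pad = 0) {
  p <- as_polygon(poly)
  x0 <- min(p[, 1]) - pad; x1 <- max(p[, 1]) + pad
  y0 <- min(p[, 2]) - pad; y1 <- max(p[, 2]) + pad
  nx <- max(8L, ceiling((x1 - x0) / resolution))
  ny <- max(8L, ceiling((y1 - y0) / resolution))
  xc <- x0 + (seq_len(nx) - 0.5) * resolution
  yc <- y0 + (seq_len(ny) - 0.5) * resolution
  grid <- cbind(rep(xc, times = ny), rep(yc, each = nx))
  m <- matrix(points_in_polygon(grid, p), nrow = nx, ncol = ny)
  list(mask = m, x0 = x0, y0 = y0, resolution = resolution, xc = xc, yc = yc)
}

# Extract the longest contour ring of a scalar field z (nx x ny, on grid
# xc/yc) at the given level, as a polygon matrix.
longest_contour <- function(xc, yc, z, level) {
  cl <- grDevices::contourLines(xc, yc, z, levels = level)
  if (length(cl) == 0) return(NULL)
  lens <- vapply(cl, function(c) length(c$x), numeric(1))
  c1 <- cl[[which.max(lens)]]
  as_polygon(cbind(x = c1$x, y = c1$y))
}

# Connected-component labelling of a logical matrix (4- or 8-connectivity).
label_components <- function(mask, connectivity = 4) {
  nbrs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8) {
    nbrs <- c(nbrs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  idx <- which(mask)
  stack <- integer(length(idx))
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- cur
    while (top > 0L) {
      v <- stack[top]
      top <- top - 1L
      i <- ((v - 1L) %% nx) + 1L
      j <- ((v - 1L) %/% nx) + 1L
      for (d in nbrs) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii < 1L || ii > nx || jj < 1L || jj > ny) next
        w <- (jj - 1L) * nx + ii
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- cur
          top <- top + 1L
          stack[top] <- w
        }
      }
    }
  }
  lab
}

# Gaussian kernel density on a fixed grid; returns nx x ny matrix of the
# density evaluated at pixel centers (sum not normalised here).
kde_grid <- function(pts, xc, yc, sigma) {
  nx <- length(xc); ny <- length(yc)
  z <- matrix(0, nx, ny)
  gx <- outer(xc, pts[, 1], function(a, b) dnorm(a - b, sd = sigma))
  gy <- outer(yc, pts[, 2], function(a, b) dnorm(a - b, sd = sigma))
  # sum_k gx[, k] %o% gy[, k]  ==  gx %*% t(gy)
  z <- gx %*% t(gy)
  z
}
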