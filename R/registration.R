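#' Landmark set
#'
#' @param source,target matrices (or data frames with `x`, `y`) of paired
#'   points in micrometres; `source` is mapped onto `target`.
#' @return A `landmark_set` with elements `source` and `target`.
#' @export
landmark_set <- function(source, target) {
  to_mat <- function(p) {
    if (is.data.frame(p)) {
      p <- if (all(c("x", "y") %in% names(p))) cbind(p$x, p$y) else as.matrix(p)
    }
    p <- as.matrix(p); storage.mode(p) <- "double"
    if (ncol(p) != 2) rlang::abort("landmarks must be 2D (two columns)")
    colnames(p) <- c("x", "y"); p
  }
  source <- to_mat(source); target <- to_mat(target)
  if (nrow(source) != nrow(target)) rlang::abort("landmark lists must pair up")
  if (nrow(source) < 3) rlang::abort("need at least 3 landmark pairs")
  if (anyDuplicated(source)) rlang::abort("duplicate source landmarks")
  structure(list(source = source, target = target), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d paired 2D landmarks\n", nrow(x$source)))
  invisible(x)
}

rmse <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Closed-form orthogonal Procrustes (Kabsch/Umeyama), det(R) = +1 enforced;
# with_scale adds the isotropic scale factor.
solve_procrustes <- function(src, dst, with_scale = FALSE) {
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  S <- sweep(src, 2, mu_s); D <- sweep(dst, 2, mu_d)
  H <- crossprod(S, D)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  C <- diag(c(1, d))
  R <- sv$v %*% C %*% t(sv$u)
  s <- if (with_scale) sum(diag(C) * sv$d) / sum(S^2) else 1
  t_vec <- unname(mu_d - s * as.vector(R %*% mu_s))
  list(R = R, s = s, t = t_vec)
}

stage_obj <- function(.type, ...) {
  structure(c(list(type = .type), list(...)), class = "transform_stage")
}

apply_stage <- function(stage, pts) {
  pts <- as.matrix(pts)
  switch(stage$type,
    rigid = ,
    similarity = sweep(stage$s * (pts %*% t(stage$R)), 2, stage$t, `+`),
    tps = tps_predict(stage, pts),
    rlang::abort(sprintf("unknown stage type '%s'", stage$type))
  )
}

tps_u <- function(r2) ifelse(r2 == 0, 0, 0.5 * r2 * log(r2)) # r^2 log r

tps_kernel <- function(a, b) {
  r2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  tps_u(pmax(r2, 0))
}

tps_predict <- function(stage, pts) {
  ptsn <- sweep(pts, 2, stage$center) / stage$scale
  K <- tps_kernel(ptsn, stage$control)
  P <- cbind(1, ptsn)
  K %*% stage$w + P %*% stage$affine
}

#' Fit one registration stage on a landmark set
#'
#' Stage types: `"rigid"` (rotation + translation), `"similarity"` (adds an
#' isotropic scale), both solved in closed form by orthogonal Procrustes when
#' the given pairing is trusted (`correspondence = TRUE`), or by iterative
#' closest point (nearest-neighbor pairing, worst-decile rejection, repeat
#' until the rmse change drops below `tol`) otherwise; and `"tps"`, the
#' interpolating thin-plate spline with kernel U(r) = r^2 log r and affine
#' part (exact at the landmarks when `lambda = 0`).
#'
#' @param lm a [landmark_set()]; `source` should already carry any previously
#'   fitted stages.
#' @param stage `"rigid"`, `"similarity"` or `"tps"`.
#' @param correspondence trust the given pairing (closed form) or re-estimate
#'   it by ICP.
#' @param max_iter,tol ICP controls.
#' @param lambda TPS smoothing (0 = exact interpolation).
#' @return A `transform_stage` with a `rmse` field (fitted residual).
#' @export
fit_stage <- function(lm, stage = c("rigid", "similarity", "tps"),
                      correspondence = TRUE, max_iter = 50, tol = 1e-10,
                      lambda = 0) {
  stage <- match.arg(stage)
  stopifnot(inherits(lm, "landmark_set"))
  src <- lm$source; dst <- lm$target
  if (stage %in% c("rigid", "similarity")) {
    with_scale <- stage == "similarity"
    if (correspondence) {
      p <- solve_procrustes(src, dst, with_scale)
    } else {
      p <- icp_fit(src, dst, with_scale, max_iter, tol)
    }
    fitted <- sweep(p$s * (src %*% t(p$R)), 2, p$t, `+`)
    return(stage_obj(stage, R = p$R, s = p$s, t = p$t,
                     rmse = rmse(fitted, dst),
                     converged = p$converged %||% TRUE))
  }
  # thin-plate spline; source coordinates are normalized to unit scale for
  # conditioning (r^2 log r spans many orders of magnitude at um scale)
  n <- nrow(src)
  if (n < 3 || qr(cbind(1, src))$rank < 3) {
    rlang::abort("TPS needs >= 3 non-collinear landmarks")
  }
  ctr <- colMeans(src)
  scl <- max(stats::sd(src[, 1]), stats::sd(src[, 2]), 1e-12)
  srcn <- sweep(src, 2, ctr) / scl
  K <- tps_kernel(srcn, srcn) + diag(lambda, n)
  P <- cbind(1, srcn)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  sol <- solve(L, rhs)
  st <- stage_obj("tps", control = srcn, center = ctr, scale = scl,
                  w = sol[seq_len(n), , drop = FALSE],
                  affine = sol[n + 1:3, , drop = FALSE], lambda = lambda)
  st$rmse <- rmse(tps_predict(st, src), dst)
  st
}

icp_fit <- function(src, dst, with_scale, max_iter, tol) {
  cur <- list(R = diag(2), s = 1, t = c(0, 0))
  prev_rmse <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    moved <- sweep(cur$s * (src %*% t(cur$R)), 2, cur$t, `+`)
    nn <- cpp_knn(dst, moved, 1, FALSE)
    res <- nn$dist[, 1]
    keep <- res <= stats::quantile(res, 0.9)    # reject worst decile
    if (sum(keep) < 3) keep <- rep(TRUE, length(res))
    cur <- solve_procrustes(src[keep, , drop = FALSE],
                            dst[nn$index[keep, 1], , drop = FALSE], with_scale)
    moved <- sweep(cur$s * (src %*% t(cur$R)), 2, cur$t, `+`)
    r <- rmse(moved, dst[cpp_knn(dst, moved, 1, FALSE)$index[, 1], , drop = FALSE])
    if (abs(prev_rmse - r) < tol) { converged <- TRUE; break }
    prev_rmse <- r
  }
  if (!converged) rlang::warn("ICP did not converge; returning best fit")
  c(cur, list(converged = converged))
}

#' Fit an ordered registration chain on landmarks
#'
#' Fits the stages in order, each on the source points as mapped by the
#' stages before it, mirroring the common rigid -> similarity -> thin-plate
#' spline alignment of EM to spatial-transcriptomics coordinates. The fitted
#' rmse is non-increasing across stages.
#'
#' @param lm a [landmark_set()].
#' @param stages character vector, in order, from
#'   `c("rigid", "similarity", "tps")`.
#' @param correspondence trust the landmark pairing (see [fit_stage()]).
#' @param lambda TPS smoothing.
#' @return A `transform_chain`; apply it with [apply_chain()] or
#'   `predict()`, inspect with [tidy()]/[glance()].
#' @examples
#' b <- simulate_bundle(synth_config(seed = 2, n_cells_st = 400, n_cells_em = 200))
#' lm <- landmark_set(b$landmarks[, c("x_src", "y_src")],
#'                    b$landmarks[, c("x_dst", "y_dst")])
#' chain <- fit_transform_chain(lm)
#' glance(chain)
#' @export
fit_transform_chain <- function(lm, stages = c("rigid", "similarity", "tps"),
                                correspondence = TRUE, lambda = 0) {
  stopifnot(inherits(lm, "landmark_set"))
  src <- lm$source
  fitted <- list()
  for (st in stages) {
    stage <- fit_stage(landmark_set(src, lm$target), st,
                       correspondence = correspondence, lambda = lambda)
    src <- apply_stage(stage, src)
    fitted[[length(fitted) + 1]] <- stage
  }
  structure(list(stages = fitted, landmarks = lm,
                 rmse = vapply(fitted, `[[`, numeric(1), "rmse")),
            class = "transform_chain")
}

#' Apply a transform chain to points
#'
#' @param chain a `transform_chain` (an empty chain is the identity).
#' @param pts matrix or data frame of points with columns `x`, `y`.
#' @return Matrix of mapped points.
#' @export
apply_chain <- function(chain, pts) {
  if (is.data.frame(pts)) pts <- cbind(pts$x, pts$y)
  pts <- as.matrix(pts)
  for (st in chain$stages) pts <- apply_stage(st, pts)
  colnames(pts) <- c("x", "y")
  pts
}

#' @export
predict.transform_chain <- function(object, newdata, ...) {
  apply_chain(object, newdata)
}

#' @export
print.transform_chain <- function(x, ...) {
  cat(sprintf("<transform_chain> %s; rmse: %s µm\n",
              paste(vapply(x$stages, `[[`, character(1), "type"), collapse = " -> "),
              paste(signif(x$rmse, 4), collapse = " -> ")))
  invisible(x)
}

#' @method tidy transform_chain
#' @export
tidy.transform_chain <- function(x, ...) {
  tibble::tibble(
    stage = vapply(x$stages, `[[`, character(1), "type"),
    rmse = x$rmse,
    scale = vapply(x$stages, function(s) s[["s"]] %||% NA_real_, numeric(1)),
    rotation_deg = vapply(x$stages, function(s) {
      if (is.null(s[["R"]])) NA_real_ else atan2(s[["R"]][2, 1], s[["R"]][1, 1]) * 180 / pi
    }, numeric(1)),
    tx = vapply(x$stages, function(s) if (is.null(s[["t"]])) NA_real_ else s[["t"]][1], numeric(1)),
    ty = vapply(x$stages, function(s) if (is.null(s[["t"]])) NA_real_ else s[["t"]][2], numeric(1))
  )
}

#' @method glance transform_chain
#' @export
glance.transform_chain <- function(x, ...) {
  tibble::tibble(
    n_landmarks = nrow(x$landmarks$source),
    n_stages = length(x$stages),
    final_rmse = x$rmse[length(x$rmse)]
  )
}

#' Report fold-over (negative Jacobian) locations of a chain
#'
#' The thin-plate stage is not guaranteed invertible; this evaluates the
#' numeric Jacobian determinant of the composed map on a grid over the given
#' points and reports locations where it is negative.
#'
#' @param chain a `transform_chain`.
#' @param pts points delimiting the region of interest.
#' @param n grid resolution per axis.
#' @param h finite-difference step (µm).
#' @return Tibble of grid locations with `jacobian`; rows with
#'   `jacobian < 0` indicate local fold-over.
#' @export
diagnose_foldover <- function(chain, pts, n = 20, h = 1e-3) {
  if (is.data.frame(pts)) pts <- cbind(pts$x, pts$y)
  gx <- seq(min(pts[, 1]), max(pts[, 1]), length.out = n)
  gy <- seq(min(pts[, 2]), max(pts[, 2]), length.out = n)
  g <- cbind(rep(gx, each = n), rep(gy, n))
  f0 <- apply_chain(chain, g)
  fx <- apply_chain(chain, cbind(g[, 1] + h, g[, 2]))
  fy <- apply_chain(chain, cbind(g[, 1], g[, 2] + h))
  j11 <- (fx[, 1] - f0[, 1]) / h; j21 <- (fx[, 2] - f0[, 2]) / h
  j12 <- (fy[, 1] - f0[, 1]) / h; j22 <- (fy[, 2] - f0[, 2]) / h
  tibble::tibble(x = g[, 1], y = g[, 2], jacobian = j11 * j22 - j12 * j21)
}
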