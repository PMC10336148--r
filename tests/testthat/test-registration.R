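similarity_of <- function(theta, s, t) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  function(p) sweep(s * (p %*% t(R)), 2, t, `+`)
}

test_that("a known similarity transform is recovered to 1e-6", {
  set.seed(21)
  src <- matrix(runif(16, 0, 1000), 8)
  theta <- 10 * pi / 180
  fwd <- similarity_of(theta, 1.05, c(30, -20))
  st <- fit_stage(landmark_set(src, fwd(src)), "similarity")
  expect_lt(abs(st$s - 1.05), 1e-6)
  expect_lt(abs(atan2(st$R[2, 1], st$R[1, 1]) - theta), 1e-6)
  expect_lt(max(abs(st$t - c(30, -20))), 1e-6)
  expect_lt(st$rmse, 1e-8)

  # aligned landmarks give the identity stage with zero rmse
  id <- fit_stage(landmark_set(src, src), "similarity")
  expect_equal(id$R, diag(2), tolerance = 1e-10)
  expect_equal(id$s, 1, tolerance = 1e-10)
  expect_equal(id$t, c(0, 0), tolerance = 1e-8)
  expect_lt(id$rmse, 1e-10)

  # rigid equals similarity when the true scale is 1
  fwd1 <- similarity_of(theta, 1, c(5, 9))
  r <- fit_stage(landmark_set(src, fwd1(src)), "rigid")
  s2 <- fit_stage(landmark_set(src, fwd1(src)), "similarity")
  expect_equal(r$R, s2$R, tolerance = 1e-9)
  expect_equal(s2$s, 1, tolerance = 1e-9)
})

test_that("closed-form rigid fit agrees with vegan procrustes", {
  set.seed(8)
  src <- matrix(runif(20, 0, 100), 10)
  fwd <- similarity_of(0.4, 1, c(12, -7))
  dst <- fwd(src) + matrix(rnorm(20, sd = 0.5), 10)
  ours <- fit_stage(landmark_set(src, dst), "rigid")
  vg <- vegan::procrustes(dst, src, scale = FALSE, symmetric = FALSE)
  # vegan maps src onto dst via Y %*% rotation + translation
  expect_equal(abs(det(vg$rotation)), 1, tolerance = 1e-8)
  fitted_vg <- src %*% vg$rotation
  fitted_vg <- sweep(fitted_vg, 2, as.numeric(vg$translation), `+`)
  fitted_ours <- spatem:::apply_stage(ours, src)
  expect_equal(fitted_ours, unname(fitted_vg), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("unsmoothed TPS interpolates landmarks exactly and degrades to affine", {
  set.seed(5)
  src <- matrix(runif(24, 0, 800), 12)
  dst <- src + 10 * matrix(sin(src / 150), 12)
  st <- fit_stage(landmark_set(src, dst), "tps")
  pred <- spatem:::apply_stage(st, src)
  expect_lt(max(sqrt(rowSums((pred - dst)^2))), 1e-8)

  # three non-collinear landmarks: affine map, zero bending (weights ~ 0)
  src3 <- rbind(c(0, 0), c(100, 0), c(0, 100))
  dst3 <- rbind(c(10, 5), c(115, 2), c(12, 108))
  st3 <- fit_stage(landmark_set(src3, dst3), "tps")
  expect_lt(max(abs(st3$w)), 1e-8)
  # collinear landmarks error out
  expect_error(
    fit_stage(landmark_set(rbind(c(0, 0), c(1, 1), c(2, 2)),
                           rbind(c(0, 0), c(1, 1), c(2, 3))), "tps"),
    "non-collinear"
  )
})

test_that("ICP without trusted correspondences still recovers the motion", {
  set.seed(13)
  src <- matrix(runif(60, 0, 500), 30)
  fwd <- similarity_of(8 * pi / 180, 1, c(15, -10))
  dst <- fwd(src)
  # shuffle the target rows so the given pairing is useless
  st <- fit_stage(landmark_set(src, dst[sample(30), ]), "rigid",
                  correspondence = FALSE)
  moved <- spatem:::apply_stage(st, src)
  nn <- spatem:::cpp_knn(dst, moved, 1, FALSE)
  expect_lt(median(nn$dist[, 1]), 1e-6)
})

test_that("chain application composes, rmse decreases, and trivia hold", {
  b <- default_bundle(2)
  lm <- landmarks_of(b)
  chain <- fit_transform_chain(lm)
  expect_true(all(diff(chain$rmse) <= 1e-9))
  expect_lt(chain$rmse[3], 1e-8)            # TPS interpolates landmarks

  td <- tidy(chain)
  expect_equal(td$stage, c("rigid", "similarity", "tps"))
  expect_equal(glance(chain)$n_landmarks, nrow(b$landmarks))

  # empty chain = identity; pure translation shifts x
  empty <- structure(list(stages = list()), class = "transform_chain")
  pts <- cbind(x = 1:5, y = 5:1)
  expect_equal(apply_chain(empty, pts), pts, ignore_attr = TRUE)
  trans <- structure(list(stages = list(
    spatem:::stage_obj("rigid", R = diag(2), s = 1, t = c(10, 0))
  )), class = "transform_chain")
  moved <- apply_chain(trans, pts)
  expect_equal(moved[, 1], pts[, 1] + 10, ignore_attr = TRUE)
  expect_equal(moved[, 2], pts[, 2], ignore_attr = TRUE)

  # full 3-stage chain brings EM cells within jitter sd + 2 um of their
  # matched ST source cells
  em_reg <- apply_chain(chain, cbind(b$em_cells$x, b$em_cells$y))
  parent_xy <- as.matrix(
    b$st_cells[match(b$truth$em$parent_cell, b$st_cells$cell_id), c("x", "y")]
  )
  expect_lt(median(sqrt(rowSums((em_reg - parent_xy)^2))),
            b$config$em_jitter_sd + 2)

  # smooth synthetic deformations do not fold the plane
  fo <- diagnose_foldover(chain, cbind(b$em_cells$x, b$em_cells$y))
  expect_true(all(fo$jacobian > 0))
})
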