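test_that("marker extraction localizes 3 mm fiducials on a fine grid", {
  # 12 spheres on a separated grid at 0.5 mm spacing
  centers <- as.matrix(expand.grid(x = c(10, 25, 40), y = c(12, 32),
                                   z = c(11, 33)))
  centers <- centers + 0.213  # off-lattice
  arr <- array(-1000, c(100, 90, 90))
  coords <- lapply(c(100, 90, 90), function(n) (0:(n - 1)) * 0.5)
  for (i in seq_len(nrow(centers))) {
    arr <- limbalign:::paint_solid(arr, coords,
                                   limbalign:::solid_sphere(centers[i, ], 1.5),
                                   3000)
  }
  vol <- ct_volume(arr, rep(0.5, 3), c(0, 0, 0))
  ms <- marker_centers_from_volume(vol, 2000, 3)
  expect_equal(nrow(ms$centers), 12)
  d <- as.matrix(dist(rbind(ms$centers, centers)))
  err <- apply(d[1:12, 13:24, drop = FALSE], 2, min)
  expect_lt(max(err), 0.5 * 0.5)

  # a 10 mm blob is rejected by the diameter gate
  arr2 <- limbalign:::paint_solid(arr, coords,
                                  limbalign:::solid_sphere(c(44, 39, 39), 5),
                                  3000)
  ms2 <- marker_centers_from_volume(ct_volume(arr2, rep(0.5, 3), c(0, 0, 0)),
                                    2000, 3)
  expect_equal(nrow(ms2$centers), 12)

  expect_error(marker_centers_from_volume(vol, 5000, 3), "threshold")
})

test_that("labeled 2D marker projections triangulate back to their 3D centers", {
  g <- eos_geometry()
  set.seed(15)
  pts <- cbind(runif(8, -80, 80), runif(8, -80, 80), runif(8, 50, 350))
  labels <- paste0("m", 1:8)
  fr <- as.data.frame(project_point(pts, g, "frontal"))
  la <- as.data.frame(project_point(pts, g, "lateral"))
  fr$label <- labels
  la$label <- labels
  ms <- triangulate_markers(fr, la, g)
  expect_equal(ms$frame, "EOS")
  expect_lt(max(abs(ms$centers - pts)), 1e-9)
  # vertical coordinate follows the printed averaging formula exactly
  expect_equal(unname(ms$centers[, 3]),
               unname(g$z0 - g$lambda_z * (fr$v + la$v) / 2))

  la_bad <- la
  la_bad$label[2] <- "mX"
  expect_error(triangulate_markers(fr, la_bad, g), "m2.*mX|mX.*m2")
})

test_that("rigid point-set fitting recovers exact and noisy transforms", {
  set.seed(17)
  src <- matrix(runif(36, -60, 60), 12, 3)
  s <- marker_set(src, paste0("m", 1:12), "CT")

  fit0 <- rigid_fit_points(s, s)
  expect_transform_equal(fit0$transform, diag(4), tol = 1e-9)
  expect_lt(fit0$rmsd, 1e-9)

  truth <- random_rigid(max_deg = 90, max_mm = 100)
  tgt <- marker_set(transform_points(truth, src), paste0("m", 1:12), "EOS")
  fit <- rigid_fit_points(s, tgt)
  expect_transform_equal(fit$transform, truth, tol = 1e-9)

  sigma <- 0.1
  reps <- vapply(1:20, function(i) {
    noisy <- marker_set(transform_points(truth, src) +
                          matrix(rnorm(36, 0, sigma), 12, 3),
                        paste0("m", 1:12), "EOS")
    fitn <- rigid_fit_points(s, noisy)
    err <- registration_error(fitn$transform, truth)
    c(max(abs(err$translation)), max(abs(err$rotation)), fitn$rmsd)
  }, numeric(3))
  expect_lt(max(reps[1, ]), 0.15)
  expect_lt(max(reps[2, ]), 0.15)
  expect_lt(mean(reps[1, ]), 3 * sigma / sqrt(12))
  expect_lt(mean(reps[2, ]), 3 * sigma / sqrt(12) * 2)
  expect_equal(mean(reps[3, ]), sigma * sqrt(2 / 3) * sqrt(3), tolerance = 0.3)

  expect_error(rigid_fit_points(src[1:2, ], src[1:2, ]), "at least 3")
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(rigid_fit_points(line, line), "collinear")
})

test_that("rigid fit matches a dense rotation-grid brute-force search on toy sets", {
  set.seed(19)
  src <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 0), c(2, 3, 7))
  truth <- rigid_transform(euler_to_rotmat(c(20, -40, 65)), c(4, -2, 6))
  tgt <- transform_points(truth, src) + matrix(rnorm(12, 0, 0.3), 4, 3)
  fit <- rigid_fit_points(src, tgt)
  sse <- function(r) {
    tr <- colMeans(tgt) - r %*% colMeans(src)
    sum((t(r %*% t(src)) + rep(tr, each = 4) - tgt)^2)
  }
  best <- Inf
  for (a in seq(-180, 170, by = 10)) {
    for (b in seq(-80, 80, by = 10)) {
      for (c in seq(-180, 170, by = 10)) {
        best <- min(best, sse(euler_to_rotmat(c(a, b, c))))
      }
    }
  }
  sse_fit <- sum((transform_points(fit$transform, src) - tgt)^2)
  expect_lte(sse_fit, best + 1e-9)
})

test_that("error matrices decompose into printed per-axis components and norms", {
  gt <- random_rigid(max_deg = 40, max_mm = 60)
  # tibia: printed translation error components (0.0, 0.5, -0.4) -> norm 0.6
  e_tib <- rigid_transform(euler_to_rotmat(c(0.0, -0.2, 1.1)), c(0.0, 0.5, -0.4))
  t_tib <- gt %*% transform_invert(e_tib)
  err <- registration_error(t_tib, gt)
  expect_equal(round(err$translation_norm, 1), 0.6)
  expect_equal(err$translation, c(0.0, 0.5, -0.4), tolerance = 1e-9)
  expect_equal(err$rotation, c(0.0, -0.2, 1.1), tolerance = 1e-9)
  # femur: (1.1, 0.3, -0.1) -> norm 1.1
  e_fem <- rigid_transform(diag(3), c(1.1, 0.3, -0.1))
  err_f <- registration_error(gt %*% transform_invert(e_fem), gt)
  expect_equal(round(err_f$translation_norm, 1), 1.1)

  expect_equal(registration_error(gt, gt)$translation, c(0, 0, 0),
               tolerance = 1e-9)
  expect_equal(registration_error(gt, gt)$rotation, c(0, 0, 0),
               tolerance = 1e-7)
})

test_that("Euler decomposition of small error rotations recomposes exactly", {
  set.seed(23)
  for (i in 1:20) {
    ang <- runif(3, -1.5, 1.5)
    e <- euler_to_rotmat(ang)
    expect_lt(max(abs(euler_to_rotmat(rotmat_to_euler(e)) - e)), 1e-12)
  }
})
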