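sphere_points <- function(n, center, r, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  t(center + t(r * u))
}

test_that("sphere fitting is exact on noiseless data and rejects coplanar sets", {
  p <- sphere_points(20, c(1, 2, 3), 24)
  fit <- fit_sphere(p)
  expect_equal(fit$center, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(fit$radius, 24, tolerance = 1e-9)
  expect_lt(fit$rms, 1e-9)

  set.seed(2)
  noisy <- sphere_points(200, c(-5, 8, 11), 22, seed = 3) +
    matrix(rnorm(600, 0, 0.1), 200, 3)
  fitn <- fit_sphere(noisy)
  expect_lt(sqrt(sum((fitn$center - c(-5, 8, 11))^2)), 0.05)

  coplanar <- cbind(runif(6), runif(6), 2)
  expect_error(fit_sphere(coplanar), "coplanar|degenerate")
  expect_error(fit_sphere(p[1:3, ]), "at least 4")
})

test_that("plane fitting matches an independent eigen-decomposition oracle", {
  set.seed(4)
  pts <- cbind(runif(8, -20, 20), runif(8, -20, 20), 0)
  tilt <- euler_to_rotmat(c(12, -7, 30))
  tilted <- pts %*% t(tilt) + rep(c(3, -2, 9), each = 8)
  fit <- fit_plane(tilted, orient = tilt[, 3])
  expect_lt(fit$rms, 1e-9)
  expect_equal(abs(sum(fit$normal * tilt[, 3])), 1, tolerance = 1e-9)

  # oracle: smallest eigenvector of the covariance matrix
  noisy <- tilted + matrix(rnorm(24, 0, 0.1), 8, 3)
  fitn <- fit_plane(noisy, orient = tilt[, 3])
  ev <- eigen(stats::cov(noisy))$vectors[, 3]
  expect_equal(abs(sum(fitn$normal * ev)), 1, tolerance = 1e-9)
  expect_lt(acos(min(1, abs(sum(fitn$normal * tilt[, 3])))) * 180 / pi, 0.5)

  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_plane(line), "collinear")
})

test_that("knee joint center is the symmetric eminence midpoint and rigid-equivariant", {
  expect_equal(compute_kjc(c(0, 0, 0), c(10, 0, 0)), c(5, 0, 0))
  a <- c(3, -4, 9)
  b <- c(-1, 2, 5)
  expect_equal(compute_kjc(a, b), compute_kjc(b, a))
  set.seed(6)
  t <- random_rigid()
  expect_equal(drop(transform_points(t, compute_kjc(a, b))),
               compute_kjc(drop(transform_points(t, a)),
                           drop(transform_points(t, b))),
               tolerance = 1e-9)
  expect_error(compute_kjc(a, a), "distinct")
})

test_that("ankle joint center selects the distal articular surface by talus distance", {
  ph <- phantom_fixture()
  ajc <- compute_ajc(ph$meshes$tibia, ph$meshes$fibula, ph$meshes$talus, 3)
  expect_equal(as.numeric(ajc), ph$joint_centers$ajc, tolerance = 1.5)
  expect_gt(attr(ajc, "n_selected"), 10)
  expect_error(compute_ajc(ph$meshes$tibia, ph$meshes$fibula, ph$meshes$talus,
                           0.5), "threshold")
  # monotone selection in the threshold
  n_at <- function(thr) attr(compute_ajc(ph$meshes$tibia, ph$meshes$fibula,
                                         ph$meshes$talus, thr), "n_selected")
  ns <- vapply(c(2.5, 3, 4, 6), n_at, 1L)
  expect_true(all(diff(ns) >= 0))
})

test_that("anatomical alignment meets its stated postconditions", {
  ph <- phantom_fixture()
  hjc <- fit_sphere(ph$landmarks$femoral_head_points)$center
  ajc <- ph$joint_centers$ajc
  al <- align_anatomical(hjc, ajc, ph$landmarks$patella_points)
  u <- drop(transform_points(al, hjc)) - drop(transform_points(al, ajc))
  expect_equal(u / sqrt(sum(u^2)), c(0, 1, 0), tolerance = 1e-9)
  pat <- transform_points(al, ph$landmarks$patella_points)
  n <- fit_plane(pat, orient = c(0, 0, 1))$normal
  expect_lt(abs(n[1]), 1e-9)
  expect_gt(n[3], 0)
  expect_error(align_anatomical(hjc, hjc, ph$landmarks$patella_points),
               "coincide")
})

test_that("mechanical axis angle is signed varus-positive in the frontal plane", {
  hjc <- c(0, 380, 0)
  ajc <- c(0, 0, 0)
  # construct a knee offset giving exactly 5 degrees of frontal deviation
  build_kjc <- function(dev_deg, lateral = 1) {
    # place KJC so that the hip-knee and knee-ankle lines subtend dev_deg
    k0 <- c(0, 190, 0)
    off <- 190 * tan(dev_deg * pi / 180 / 2)
    k0 + c(lateral * off, 0, 0)
  }
  expect_equal(compute_ma(hjc, c(0, 190, 0), ajc, "left"), 0, tolerance = 1e-6)
  kj <- build_kjc(5, lateral = +1)   # +x is lateral for a left leg
  expect_equal(compute_ma(hjc, kj, ajc, "left"), 5, tolerance = 1e-9)
  expect_equal(compute_ma(hjc, kj, ajc, "right"), -5, tolerance = 1e-9)
  # a purely sagittal offset vanishes after frontal projection
  expect_equal(compute_ma(hjc, c(0, 190, 40), ajc, "left"), 0, tolerance = 1e-6)
  expect_error(compute_ma(hjc, hjc, ajc, "left"), "coincide")
})

test_that("condyle tangent recovers constructed condyle geometry", {
  # synthetic femur in the aligned frame: shaft along +y, two condyle
  # spheres with a 2 mm height offset over 50 mm separation
  shaft <- limbalign:::mesh_cylinder_parts(c(0, 40, 0), c(0, 240, 0), 12)
  c1 <- limbalign:::mesh_sphere_parts(c(-25, 16, 0), 16)
  c2 <- limbalign:::mesh_sphere_parts(c(25, 18, 0), 16)
  femur <- limbalign:::merge_parts(list(shaft, c1, c2), "femur")
  fct <- compute_fct(femur)
  slope <- abs(fct$direction[2] / fct$direction[1])
  expect_equal(atan(slope) * 180 / pi, atan(2 / 50) * 180 / pi,
               tolerance = 0.35)

  # equal-height condyles: tangent parallel to the mediolateral axis
  c2e <- limbalign:::mesh_sphere_parts(c(25, 16, 0), 16)
  femur_sym <- limbalign:::merge_parts(list(shaft, c1, c2e), "femur")
  fct_sym <- compute_fct(femur_sym)
  expect_lt(abs(fct_sym$direction[2]), 1e-9)

  # cluster assignment equals a mediolateral half-space split
  v <- femur$vertices
  axis <- stats::prcomp(v)$rotation[, 1]
  if (axis[2] < 0) axis <- -axis
  s <- drop(v %*% axis)
  epi <- v[s <= min(s) + 0.15 * (max(s) - min(s)), ]
  seeds <- epi[c(which.min(epi[, 1]), which.max(epi[, 1])), ]
  km <- stats::kmeans(epi, centers = seeds)
  split <- ifelse(epi[, 1] < 0, 1L, 2L)
  expect_true(mean(km$cluster == split) > 0.99)
})

test_that("joint line convergence angle is signed lateral-opening-positive", {
  fct <- list(direction = c(1, 0, 0))
  level <- list(normal = c(0, 1, 0))
  expect_equal(compute_jlca(fct, level, "left"), 0)
  # plateau descending laterally by 3 degrees: lateral opening, positive
  tilt3 <- list(normal = c(tan(3 * pi / 180), 1, 0))
  expect_equal(compute_jlca(fct, tilt3, "left"), 3, tolerance = 1e-9)
  # mirroring the geometry across the sagittal plane with the side flipped
  # preserves the value
  fct_m <- list(direction = c(-1, 0, 0))
  tilt3_m <- list(normal = c(-tan(3 * pi / 180), 1, 0))
  expect_equal(compute_jlca(fct_m, tilt3_m, "right"),
               compute_jlca(fct, tilt3, "left"))
  # medial opening is negative
  expect_equal(compute_jlca(fct, list(normal = c(-tan(2 * pi / 180), 1, 0)),
                            "left"), -2, tolerance = 1e-9)
  expect_error(compute_jlca(list(direction = c(0, 0, 1)), level, "left"),
               "perpendicular")
})

test_that("measurements are invariant under a common rigid motion of all inputs", {
  ph <- phantom_fixture()
  base <- measure_alignment(ph$meshes, ph$landmarks, ph$side)
  set.seed(31)
  t <- random_rigid(max_deg = 60, max_mm = 80)
  meshes_t <- lapply(ph$meshes, transform_mesh, transform = t)
  lm_t <- lapply(ph$landmarks, function(m) transform_points(t, m))
  moved <- measure_alignment(meshes_t, lm_t, ph$side)
  expect_equal(moved$ma, base$ma, tolerance = 1e-6)
  expect_equal(moved$jlca, base$jlca, tolerance = 1e-6)
})
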