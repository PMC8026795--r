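test_that("arrow annotations validate endpoint separation", {
  expect_error(
    arrow_annotation(c(1, 1), c(1, 1), c(0, 0), c(1, 1), c(0, 0, 0), c(1, 1, 1)),
    "coincide")
  expect_error(
    arrow_annotation(c(0, 0), c(1, 1), c(0, 0), c(1, 1), c(2, 2, 2), c(2, 2, 2)),
    "coincide")
})

test_that("an already-aligned arrow initializes to the identity", {
  g <- phantom_geometry()
  s <- c(5, -10, 100)
  e <- c(8, 4, 300)
  a <- arrow_annotation(project_point(s, g, "frontal"), project_point(e, g, "frontal"),
                        project_point(s, g, "lateral"), project_point(e, g, "lateral"),
                        s, e)
  expect_transform_equal(initialize_pose(a, g), diag(4), tol = 1e-9)
})

test_that("initialization from exactly annotated projections recovers the arrow axis", {
  g <- phantom_geometry()
  truth <- pose_to_transform(c(4, -3, 8, 12, -6, 9), center = c(0, 0, 200))
  s <- c(2, -4, 120)
  e <- c(-1, 3, 310)
  sp <- drop(transform_points(truth, s))
  ep <- drop(transform_points(truth, e))
  a <- arrow_annotation(project_point(sp, g, "frontal"), project_point(ep, g, "frontal"),
                        project_point(sp, g, "lateral"), project_point(ep, g, "lateral"),
                        s, e)
  init <- initialize_pose(a, g)
  # the arrow's direction and midpoint are reproduced exactly; the residual
  # is a pure roll about the arrow axis
  u_true <- (ep - sp) / sqrt(sum((ep - sp)^2))
  u_init <- drop(init[1:3, 1:3] %*% (e - s))
  u_init <- u_init / sqrt(sum(u_init^2))
  expect_equal(u_init, u_true, tolerance = 1e-9)
  mid <- (s + e) / 2
  expect_equal(drop(transform_points(init, mid)), (sp + ep) / 2,
               tolerance = 1e-9)
  resid <- init %*% transform_invert(truth)
  ang <- acos((sum(diag(resid[1:3, 1:3])) - 1) / 2)
  ax <- c(resid[3, 2] - resid[2, 3], resid[1, 3] - resid[3, 1],
          resid[2, 1] - resid[1, 2])
  ax <- ax / sqrt(sum(ax^2))
  expect_equal(abs(sum(ax * u_true)), 1, tolerance = 1e-6)
})

test_that("registration cost decomposes into the two per-plane similarities", {
  sim <- simulation_fixture()
  cfg <- registration_config()
  g <- phantom_geometry()
  pose <- sim$poses$femur
  ctr <- c(0, 0, 300)
  cost <- registration_cost(rep(0, 6), sim$att$femur, sim$sim$pair,
                            sim$sim$masks$femur, cfg, init = pose, center = ctr)
  total <- 0
  for (plane in c("frontal", "lateral")) {
    drr <- render_drr(sim$att$femur, pose, g, plane)
    total <- total + lncc_similarity(drr, sim$sim$pair[[plane]],
                                     sim$sim$masks$femur[[plane]],
                                     cfg$patch_size)
  }
  expect_equal(cost, -total, tolerance = 1e-9)
})

test_that("self-match cost is -2 and grows along every pose axis", {
  sim <- simulation_fixture()
  cfg <- registration_config()
  ctr <- drop(transform_points(sim$poses$tibia,
                               limbalign:::volume_centroid(sim$att$tibia)))
  at <- function(p) registration_cost(p, sim$att$tibia, sim$sim$pair,
                                      sim$sim$masks$tibia, cfg,
                                      init = sim$poses$tibia, center = ctr)
  expect_equal(at(rep(0, 6)), -2, tolerance = 1e-6)
  for (axis in 1:6) {
    offs <- c(5, 2.5)
    if (axis <= 3) offs <- c(5, 2.5)       # degrees
    vals <- vapply(offs, function(o) {
      p <- rep(0, 6)
      p[axis] <- o
      at(p)
    }, 1)
    # cost decreases monotonically approaching the truth from a 5 unit offset
    expect_gt(vals[1], vals[2])
    expect_gt(vals[2], at(rep(0, 6)))
  }
})

test_that("registering radiographs rendered at the initialization returns it", {
  sim <- simulation_fixture()
  cfg <- registration_config(maxfun = 90L, rhobeg = 1)
  fit <- register_bone(sim$att$tibia, sim$sim$pair, NULL, sim$sim$masks$tibia,
                       cfg, init = sim$poses$tibia)
  err <- registration_error(fit$transform, sim$poses$tibia)
  expect_lt(max(abs(err$translation)), 0.1)
  expect_lt(max(abs(err$rotation)), 0.1)
  expect_true(is_rigid_transform(fit$transform))
  expect_gt(fit$evaluations, 6)
})

test_that("pose parameterization matches its documented conventions", {
  expect_transform_equal(pose_to_transform(rep(0, 6), c(1, 2, 3)), diag(4))
  t <- pose_to_transform(c(90, 0, 0, 0, 0, 0))
  expect_equal(drop(transform_points(t, c(0, 1, 0))), c(0, 0, 1),
               tolerance = 1e-12)
})
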