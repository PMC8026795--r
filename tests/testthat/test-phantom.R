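test_that("the default phantom carries six 3 mm fiducials per bone", {
  ph <- phantom_fixture()
  expect_equal(sum(grepl("^fem", ph$markers$labels)), 6)
  expect_equal(sum(grepl("^tib", ph$markers$labels)), 6)
  # recover them from the CT volume: 12 components passing the 3 +/- 0.5 mm
  # diameter gate, each within half a voxel of its recorded center
  ms <- marker_centers_from_volume(ph$volume, 2000, 3)
  expect_equal(nrow(ms$centers), 12)
  d <- as.matrix(dist(rbind(ms$centers, ph$markers$centers)))
  err <- apply(d[1:12, 13:24, drop = FALSE], 2, min)
  expect_lt(max(err), 0.5 * ph$spec$spacing)
})

test_that("measurements on the noiseless meshes recover the constructed deformity", {
  ph <- phantom_fixture()
  m <- measure_alignment(ph$meshes, ph$landmarks, ph$side)
  expect_equal(m$ma, ph$ma, tolerance = 0.2 / max(1, abs(ph$ma)))
  expect_equal(m$jlca, ph$jlca, tolerance = 0.2 / max(1, abs(ph$jlca)))
})

test_that("deformity signs follow the varus and lateral-opening conventions", {
  valgus <- build_phantom(phantom_spec(ma = -4, jlca = -2))
  m <- measure_alignment(valgus$meshes, valgus$landmarks, valgus$side)
  expect_equal(m$ma, -4, tolerance = 0.05)
  expect_equal(m$jlca, -2, tolerance = 0.1)
  right <- build_phantom(phantom_spec(ma = 5, jlca = 3, side = "right"))
  mr <- measure_alignment(right$meshes, right$landmarks, "right")
  expect_equal(mr$ma, 5, tolerance = 0.05)
  expect_equal(mr$jlca, 3, tolerance = 0.1)
})

test_that("phantom construction is bit-reproducible for a fixed seed", {
  s <- phantom_spec(noise_sd = 25, seed = 9)
  a <- build_phantom(s)
  b <- build_phantom(s)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$meshes$femur$vertices, b$meshes$femur$vertices)
})

test_that("identity poses reproduce the per-assembly renders and noiseless runs repeat", {
  ph <- phantom_fixture()
  g <- phantom_geometry()
  s1 <- simulate_eos_pair(ph, diag(4), diag(4), g)
  att <- lapply(ph$segment_volumes, hu_to_attenuation)
  direct <- render_drr(att$femur, diag(4), g, "frontal") +
    render_drr(att$tibia, diag(4), g, "frontal")
  expect_equal(s1$pair$frontal, direct, tolerance = 1e-12)
  s2 <- simulate_eos_pair(ph, diag(4), diag(4), g)
  expect_identical(s1$pair$lateral, s2$pair$lateral)
})

test_that("emitted 2D annotations agree with the forward projection of posed truth", {
  sim <- simulation_fixture()
  g <- phantom_geometry()
  ph <- sim$truth
  bone <- ifelse(grepl("^fem", ph$markers$labels), "femur", "tibia")
  posed <- ph$markers$centers
  for (b in c("femur", "tibia")) {
    posed[bone == b, ] <- transform_points(sim$poses[[b]],
                                           posed[bone == b, , drop = FALSE])
  }
  for (pl in c("frontal", "lateral")) {
    px <- project_point(posed, g, pl)
    expect_equal(sim$sim$markers2d[[pl]]$h, unname(px[, 1]), tolerance = 1e-9)
    expect_equal(sim$sim$markers2d[[pl]]$v, unname(px[, 2]), tolerance = 1e-9)
  }
  # triangulating the emitted annotations reproduces the posed 3D centers
  ms <- triangulate_markers(sim$sim$markers2d$frontal,
                            sim$sim$markers2d$lateral, g)
  expect_lt(max(abs(ms$centers - posed)), 1e-9)
})

test_that("registration is equivariant under a common vertical shift of the scene", {
  sim <- simulation_fixture()
  g <- phantom_geometry()
  ph <- sim$truth
  cfg <- registration_config(maxfun = 150L, rhobeg = 1)
  run_at <- function(delta) {
    shift <- rigid_transform(diag(3), delta)
    s <- simulate_eos_pair(ph, shift %*% sim$poses$femur,
                           shift %*% sim$poses$tibia, g)
    init <- initialize_pose(s$annotations$tibia, g)
    fit <- register_bone(sim$att$tibia, s$pair, NULL, s$masks$tibia, cfg,
                         init = init)
    fit$transform
  }
  base <- run_at(c(0, 0, 0))
  for (delta in list(c(0, 0, 6), c(3, 0, -6))) {
    shifted <- run_at(delta)
    expect_transform_equal(shifted,
                           rigid_transform(diag(3), delta) %*% base,
                           tol = 0.05)
  }
})

test_that("impossible specs are rejected", {
  expect_error(phantom_spec(marker_diameter = 1), "detectability")
  expect_error(phantom_spec(spacing = -1))
  expect_error(build_phantom(phantom_spec(ma = 60)), "impossible")
})
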