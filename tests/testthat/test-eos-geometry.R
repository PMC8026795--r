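test_that("points on the isocenter vertical axis project to the principal pixel", {
  g <- eos_geometry()
  for (z in c(-100, 0, 250.5)) {
    p <- project_point(c(0, 0, z), g, "frontal")
    expect_equal(unname(p["h"]), g$principal_f)
    expect_equal(unname(p["v"]), (g$z0 - z) / g$lambda_z)
    p <- project_point(c(0, 0, z), g, "lateral")
    expect_equal(unname(p["h"]), g$principal_l)
  }
})

test_that("a horizontal offset at isocenter depth projects at unit magnification", {
  g <- eos_geometry()
  p <- project_point(c(10, 0, 0), g, "frontal")
  expect_equal(unname(p["h"]), g$principal_f + 10 / g$lambda_h_f)
})

test_that("projection matches an independent ray-intersection oracle", {
  g <- eos_geometry(lambda_h_f = 0.21, lambda_h_l = 0.15, principal_f = 700,
                    principal_l = 820)
  set.seed(11)
  for (i in 1:50) {
    p <- c(runif(1, -150, 150), runif(1, -150, 150), runif(1, -300, 400))
    p[2] <- 100  # stated oracle case: fixed posterior offset
    expect_equal(unname(project_point(p, g, "frontal")["h"]),
                 project_oracle(p, g, "frontal"), tolerance = 1e-12)
    expect_equal(unname(project_point(p, g, "lateral")["h"]),
                 project_oracle(p, g, "lateral"), tolerance = 1e-12)
  }
})

test_that("triangulation reproduces the emitter start height at vertical pixel 0", {
  g <- eos_geometry()  # printed calibration constants
  p <- triangulate_point(c(g$principal_f, 0), c(g$principal_l, 0), g)
  expect_equal(unname(p), c(0, 0, 477.5))
})

test_that("vertical world coordinate follows the averaged vertical pixel readings", {
  g <- eos_geometry()
  p <- triangulate_point(c(g$principal_f, 100), c(g$principal_l, 300), g)
  expect_equal(unname(p["z"]), g$z0 - 200 * g$lambda_z)
})

test_that("triangulation inverts projection to sub-nanometer precision", {
  g <- eos_geometry(lambda_h_f = 0.3, principal_l = 600)
  set.seed(42)
  pts <- cbind(runif(1000, -200, 200), runif(1000, -200, 200),
               runif(1000, -400, 450))
  fr <- project_point(pts, g, "frontal")
  la <- project_point(pts, g, "lateral")
  rec <- triangulate_point(fr, la, g)
  expect_lt(max(abs(rec - pts)), 1e-9)
})

test_that("vertical coordinate is affine in height with slope -1/lambda_z", {
  g <- eos_geometry()
  z <- seq(-300, 400, by = 50)
  for (plane in c("frontal", "lateral")) {
    v <- project_point(cbind(25, -40, z), g, plane)[, "v"]
    slopes <- diff(v) / diff(z)
    expect_equal(slopes, rep(-1 / g$lambda_z, length(slopes)))
  }
})

test_that("horizontal magnification is 1 at isocenter depth and monotone toward the source", {
  g <- eos_geometry()
  seg <- function(y) {
    h <- project_point(rbind(c(-5, y, 0), c(5, y, 0)), g, "frontal")[, "h"]
    diff(h) * g$lambda_h_f / 10
  }
  expect_equal(seg(0), 1)
  depths <- seq(-400, 400, by = 100)
  mags <- vapply(depths, seg, 1)
  expect_true(all(diff(mags) < 0))          # shrinks moving away from the source
  expect_true(all(mags[depths < 0] > 1))    # nearer the source: magnified
})

test_that("triangulated horizontal position equals the least-squares ray intersection", {
  g <- eos_geometry()
  set.seed(7)
  for (i in 1:10) {
    p <- c(runif(1, -150, 150), runif(1, -150, 150), runif(1, 0, 300))
    fr <- project_point(p, g, "frontal")
    la <- project_point(p, g, "lateral")
    rec <- triangulate_point(fr, la, g)
    # brute-force: minimize summed squared distances to the two horizontal rays
    sf <- c(0, -g$f_f)
    df <- c((fr["h"] - g$principal_f) * g$lambda_h_f, g$f_f)
    df <- df / sqrt(sum(df^2))
    sl <- c(-g$f_l, 0)
    dl <- c(g$f_l, (la["h"] - g$principal_l) * g$lambda_h_l)
    dl <- dl / sqrt(sum(dl^2))
    obj <- function(q) {
      d1 <- q - sf - sum((q - sf) * df) * df
      d2 <- q - sl - sum((q - sl) * dl) * dl
      sum(d1^2) + sum(d2^2)
    }
    opt <- optim(c(0, 0), obj, method = "BFGS",
                 control = list(reltol = 1e-14))
    expect_equal(unname(rec[1:2]), opt$par, tolerance = 1e-5)
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  g <- eos_geometry()
  expect_error(project_point(c(0, -g$f_f, 0), g, "frontal"), "source plane")
  # horizontal offsets so extreme the two rays become parallel
  big <- g$f_f / g$lambda_h_f
  expect_error(
    triangulate_point(c(g$principal_f + big, 0), c(g$principal_l + big, 0), g),
    "singular|parallel")
})

test_that("calibration defaults carry the bundled constants and are validated", {
  g <- geometry_from_parameters()
  expect_equal(g$f_f, 918)
  expect_equal(g$f_l, 918)
  expect_equal(g$z0, 477.5)
  expect_equal(g$lambda_z, 0.179363)
  expect_equal(g$lambda_h_f, g$lambda_z)   # square pixels by default
  expect_error(geometry_from_parameters(list(lambda_z = 0)), "lambda_z")
  expect_error(geometry_from_parameters(list(f_f = -5)), "f_f")
  expect_error(geometry_from_parameters(list(bogus = 1)), "bogus")
})

test_that("geometry serialization round-trips bit-exactly", {
  g <- eos_geometry(f_f = 917.25, lambda_z = 0.179363, n_rows = 2751,
                    principal_f = 612.375)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_eos_geometry(g, path)
  g2 <- read_eos_geometry(path)
  expect_identical(unclass(g2)[names(g)], unclass(g)[names(g)])
})
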