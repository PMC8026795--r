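# Shared fixtures, memoized per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

phantom_fixture <- function() memo("phantom", function() build_phantom(phantom_spec()))

simulation_fixture <- function() {
  memo("sim", function() {
    ph <- phantom_fixture()
    poses <- phantom_weightbearing_poses(ph)
    sim <- simulate_eos_pair(ph, poses$femur, poses$tibia, phantom_geometry())
    list(truth = ph, poses = poses, sim = sim,
         att = lapply(ph$segment_volumes, hu_to_attenuation))
  })
}

# independent ray-intersection oracle for the slot-scan projection:
# intersect the source -> point ray with the isocenter detector plane
project_oracle <- function(p, g, plane) {
  if (plane == "frontal") {
    s <- c(0, -g$f_f, p[3])
    tpar <- (0 - s[2]) / (p[2] - s[2])
    hit <- s + tpar * (p - s)
    g$principal_f + hit[1] / g$lambda_h_f
  } else {
    s <- c(-g$f_l, 0, p[3])
    tpar <- (0 - s[1]) / (p[1] - s[1])
    hit <- s + tpar * (p - s)
    g$principal_l + hit[2] / g$lambda_h_l
  }
}

# brute-force variance-weighted LNCC with explicit loops
lncc_oracle <- function(a, b, mask, patch) {
  r <- (patch - 1) / 2
  nr <- nrow(a)
  nc <- ncol(a)
  num <- 0
  den <- 0
  for (i in (mask$r0 + 1):mask$r1) {
    for (j in (mask$c0 + 1):mask$c1) {
      ri <- max(1, i - r):min(nr, i + r)
      ci <- max(1, j - r):min(nc, j + r)
      pa <- as.vector(a[ri, ci])
      pb <- as.vector(b[ri, ci])
      va <- mean(pa^2) - mean(pa)^2
      vb <- mean(pb^2) - mean(pb)^2
      eps <- 1e-12 * max(1, max(abs(a)), max(abs(b)))^2
      if (va > eps && vb > eps) {
        ncc <- (mean(pa * pb) - mean(pa) * mean(pb)) / sqrt(va * vb)
        num <- num + vb * ncc
        den <- den + vb
      }
    }
  }
  if (den <= 0) 0 else num / den
}

# random rigid transform with bounded magnitude
random_rigid <- function(max_deg = 180, max_mm = 50) {
  ang <- stats::runif(3, -max_deg, max_deg)
  rigid_transform(euler_to_rotmat(ang), stats::runif(3, -max_mm, max_mm))
}

expect_transform_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
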