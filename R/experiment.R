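#' Default weight-bearing poses for the phantom experiment
#'
#' Modest per-bone rigid adjustments emulating the postural change between
#' supine CT and standing acquisition: a few millimetres of translation and
#' a couple of degrees of rotation per bone, the knee-level change being
#' carried by the tibia.
#'
#' @param truth a [build_phantom()] result (rotation centers are taken at
#'   the joint centers).
#' @return list with elements `femur` and `tibia`, each a 4x4 rigid
#'   transform.
#' @export
phantom_weightbearing_poses <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  list(
    femur = pose_to_transform(c(0.5, -0.5, 1.0, 2.0, -1.0, 0.5),
                              center = truth$joint_centers$hjc),
    tibia = pose_to_transform(c(1.0, 0.5, -1.0, -1.5, 1.0, 0.0),
                              center = truth$joint_centers$kjc)
  )
}

# random rigid perturbation: `deg` about a uniform random axis through
# `center`, plus `mm` along a uniform random direction
random_perturbation <- function(mm, deg, center) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  t <- rigid_transform(rodrigues(ax, deg * pi / 180), c(0, 0, 0))
  t[1:3, 4] <- center - t[1:3, 1:3] %*% center + mm * dir
  t
}

#' Phantom registration accuracy experiment
#'
#' Runs the full validation loop on the synthetic phantom: simulate the
#' biplanar radiograph pair at known per-bone poses, initialize each bone
#' from its arrow annotations, perturb the initialization by a fixed
#' translation magnitude and rotation angle in a seeded random direction,
#' run the intensity-based registration, and decompose the error matrix
#' `E = T^-1 GT` into per-axis translation (mm) and intrinsic x-y-z
#' rotation (degrees) errors.
#'
#' @param seeds integer vector; one registration pair (femur + tibia) per
#'   seed, the seed driving the perturbation direction.
#' @param spec a [phantom_spec()].
#' @param g an [eos_geometry()]; default [phantom_geometry()].
#' @param poses list of true per-bone poses; default
#'   [phantom_weightbearing_poses()].
#' @param perturb_mm,perturb_deg initialization perturbation magnitudes.
#' @param cfg a [registration_config()].
#' @param truth optionally a pre-built [build_phantom()] result (the
#'   phantom itself is deterministic given `spec`).
#' @return data frame with one row per seed x bone: per-axis translation
#'   and rotation errors, translation norm, final similarity, evaluation
#'   count and convergence flag.
#' @export
phantom_registration_experiment <- function(seeds = 1:5,
                                            spec = phantom_spec(),
                                            g = phantom_geometry(),
                                            poses = NULL,
                                            perturb_mm = 5, perturb_deg = 5,
                                            cfg = registration_config(),
                                            truth = NULL) {
  if (is.null(truth)) truth <- build_phantom(spec)
  if (is.null(poses)) poses <- phantom_weightbearing_poses(truth)
  sim <- simulate_eos_pair(truth, poses$femur, poses$tibia, g,
                           noise_sigma = 0)
  att <- lapply(truth$segment_volumes, hu_to_attenuation)
  rows <- list()
  for (seed in seeds) {
    for (bone in c("femur", "tibia")) {
      init <- initialize_pose(sim$annotations[[bone]], g)
      center <- drop(transform_points(init, volume_centroid(att[[bone]])))
      pert <- with_seed(seed + 7L * (bone == "tibia"), {
        random_perturbation(perturb_mm, perturb_deg, center)
      })
      fit <- register_bone(att[[bone]], sim$pair, NULL, sim$masks[[bone]],
                           cfg, init = pert %*% init)
      err <- registration_error(fit$transform, poses[[bone]])
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, bone = bone,
        tx = err$translation[1], ty = err$translation[2],
        tz = err$translation[3],
        rx = err$rotation[1], ry = err$rotation[2], rz = err$rotation[3],
        translation_norm = err$translation_norm,
        similarity = fit$similarity, evaluations = fit$evaluations,
        converged = fit$converged)
    }
  }
  do.call(rbind, rows)
}
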