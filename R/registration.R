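#' Arrow annotation for registration initialization
#'
#' The user draws one arrow connecting the same two anatomical landmarks in
#' three images: the frontal radiograph, the lateral radiograph, and the CT
#' volume (3D).  Any consistent landmark pair works; typical choices are the
#' distal tibia to the tibial plateau center, or the condyle midpoint to the
#' femoral head center.
#'
#' @param frontal_start,frontal_end,lateral_start,lateral_end pixel
#'   coordinates `c(h, v)` on the respective plane.
#' @param ct_start,ct_end 3D points (mm) in CT coordinates.
#' @return an object of class `arrow_annotation`.
#' @export
arrow_annotation <- function(frontal_start, frontal_end,
                             lateral_start, lateral_end,
                             ct_start, ct_end) {
  a <- list(frontal_start = as.numeric(frontal_start),
            frontal_end = as.numeric(frontal_end),
            lateral_start = as.numeric(lateral_start),
            lateral_end = as.numeric(lateral_end),
            ct_start = as.numeric(ct_start), ct_end = as.numeric(ct_end))
  stopifnot(lengths(a[1:4]) == 2, lengths(a[5:6]) == 3)
  if (sum((a$frontal_end - a$frontal_start)^2) == 0 ||
      sum((a$lateral_end - a$lateral_start)^2) == 0 ||
      sum((a$ct_end - a$ct_start)^2) == 0) {
    stop("arrow endpoints coincide in at least one view")
  }
  structure(a, class = "arrow_annotation")
}

#' Registration configuration
#'
#' @param patch_size LNCC patch size in pixels (odd, >= 3); default 9.
#' @param bound_rot,bound_trans box bounds on the six pose parameters
#'   around the initialization (degrees, mm); default 30 each.
#' @param step DRR ray sampling step (mm); `NULL` = half the smallest voxel
#'   spacing.
#' @param maxfun maximum cost evaluations for the optimizer.
#' @param rhobeg,rhoend initial and final BOBYQA trust-region radii, in the
#'   mixed mm/degree parameter units.
#' @param levels 1 (single resolution, default) or 2 (coarse-to-fine: a
#'   first pass at doubled ray step before the full-resolution pass).
#' @param seed integer seed for any stochastic element (reserved; the
#'   default pipeline is deterministic).
#' @return an object of class `registration_config`.
#' @export
registration_config <- function(patch_size = 9L, bound_rot = 30, bound_trans = 30,
                                step = NULL, maxfun = 400L, rhobeg = 3,
                                rhoend = 1e-3, levels = 1L, seed = NULL) {
  patch_size <- as.integer(patch_size)
  if (patch_size < 3L || patch_size %% 2L == 0L) {
    stop("patch_size must be odd and >= 3")
  }
  stopifnot(is.finite(bound_rot), is.finite(bound_trans),
            bound_rot > 0, bound_trans > 0, levels %in% c(1L, 2L))
  structure(list(patch_size = patch_size, bound_rot = bound_rot,
                 bound_trans = bound_trans, step = step,
                 maxfun = as.integer(maxfun), rhobeg = rhobeg,
                 rhoend = rhoend, levels = as.integer(levels), seed = seed),
            class = "registration_config")
}

#' Initialize the pose from arrow annotations
#'
#' The 2D arrow endpoints in the two radiographs are triangulated to 3D
#' world coordinates.  The initial rigid transform is the minimal rotation
#' (axis = cross product of the two arrow directions) taking the CT arrow
#' direction onto the triangulated arrow direction, combined with the
#' translation that maps the CT arrow midpoint onto the triangulated
#' midpoint.  Rotation about the arrow axis (roll) is unobservable from one
#' arrow and left at zero; the intensity-based optimization resolves it.
#'
#' @param a an [arrow_annotation()].
#' @param g an [eos_geometry()].
#' @return a 4x4 rigid transform mapping CT coordinates to the world frame.
#' @export
initialize_pose <- function(a, g) {
  stopifnot(inherits(a, "arrow_annotation"), inherits(g, "eos_geometry"))
  s3 <- triangulate_point(a$frontal_start, a$lateral_start, g)
  e3 <- triangulate_point(a$frontal_end, a$lateral_end, g)
  u <- e3 - s3
  w <- a$ct_end - a$ct_start
  nu <- sqrt(sum(u^2))
  nw <- sqrt(sum(w^2))
  if (nu < 1e-9 || nw < 1e-9) stop("arrow has zero length")
  u <- u / nu
  w <- w / nw
  ax <- c(w[2] * u[3] - w[3] * u[2],
          w[3] * u[1] - w[1] * u[3],
          w[1] * u[2] - w[2] * u[1])
  s <- sqrt(sum(ax^2))
  d <- sum(w * u)
  if (s < 1e-12) {
    if (d > 0) {
      r <- diag(3)
    } else {
      # antiparallel: rotate 180 degrees about a fixed perpendicular axis
      p <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      ax <- p - sum(p * w) * w
      ax <- ax / sqrt(sum(ax^2))
      r <- rodrigues(ax, pi)
    }
  } else {
    r <- rodrigues(ax / s, atan2(s, d))
  }
  m_ct <- (a$ct_start + a$ct_end) / 2
  m_eos <- (s3 + e3) / 2
  rigid_transform(r, m_eos - r %*% m_ct)
}

# rotation about unit axis by angle (radians)
rodrigues <- function(axis, angle) {
  k <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * k %*% k
}

# expand an ROI by the LNCC patch radius and clip to the image
expand_roi <- function(mask, r, d) {
  roi_rect(max(0, mask$r0 - r), max(0, mask$c0 - r),
           min(d[1], mask$r1 + r), min(d[2], mask$c1 + r))
}

#' Registration cost at a pose
#'
#' Renders frontal and lateral DRRs of the attenuation volume at the pose
#' given by `params` (relative to `init`, rotation about `center`) and
#' returns the negated sum of the two masked variance-weighted LNCC scores,
#' suitable for minimization.  A perfect match on both planes gives -2.
#'
#' @param params pose parameter 6-vector (degrees, mm); see
#'   [pose_to_transform()].
#' @param ct an `attenuation_volume`.
#' @param radiographs a [radiograph_pair()].
#' @param masks list with elements `frontal` and `lateral`, each an
#'   [roi_rect()].
#' @param cfg a [registration_config()].
#' @param init 4x4 rigid transform the parameters are relative to
#'   (identity by default).
#' @param center rotation center (mm, world frame).
#' @return scalar cost (negated similarity sum).
#' @export
registration_cost <- function(params, ct, radiographs, masks, cfg,
                              init = diag(4), center = c(0, 0, 0)) {
  pose <- pose_to_transform(params, center) %*% init
  g <- radiographs$geometry
  r <- (cfg$patch_size - 1L) %/% 2L
  step <- if (is.null(cfg$step)) min(ct$spacing) / 2 else cfg$step
  total <- 0
  for (plane in c("frontal", "lateral")) {
    mask <- masks[[plane]]
    d <- c(g$n_rows, g$n_cols)
    ext <- expand_roi(mask, r, d)
    sel <- roi_index(ext, d)
    drr <- render_drr(ct, pose, g, plane, step = step,
                      rows = sel$rows - 1L, vcols = sel$cols - 1L)
    eos <- radiographs[[plane]][sel$rows, sel$cols, drop = FALSE]
    # mask relative to the rendered window
    rel <- roi_rect(mask$r0 - ext$r0, mask$c0 - ext$c0,
                    min(mask$r1, d[1]) - ext$r0, min(mask$c1, d[2]) - ext$c0)
    total <- total + lncc_similarity(drr, eos, rel, cfg$patch_size)
  }
  -total
}

#' Intensity-based 2D-3D rigid registration of one bone
#'
#' Registers a CT (or attenuation) volume of one bone to a biplanar
#' radiograph pair: the pose is initialized from the arrow annotations (or a
#' supplied transform), then the six pose parameters (three intrinsic x-y-z
#' Euler angles about the volume centroid, three translations) are optimized
#' by BOBYQA, a bound-constrained derivative-free quadratic-model method,
#' maximizing the summed variance-weighted LNCC between the DRRs and the
#' radiographs inside the per-plane masks.
#'
#' @param ct a [ct_volume()] (converted by [hu_to_attenuation()]) or an
#'   `attenuation_volume` of the bone to register.
#' @param radiographs a [radiograph_pair()].
#' @param annotation an [arrow_annotation()]; may be `NULL` when `init` is
#'   given.
#' @param masks list with `frontal` and `lateral` [roi_rect()] masks.
#' @param cfg a [registration_config()].
#' @param init optional 4x4 initialization overriding the annotation-based
#'   one (also the restart hook: re-invoke with an adjusted pose).
#' @return an object of class `bone_registration` with elements `transform`
#'   (4x4, CT to world), `cost`, `similarity`, `evaluations`, `converged`,
#'   `status`, `init` and `params`.
#' @export
register_bone <- function(ct, radiographs, annotation, masks,
                          cfg = registration_config(), init = NULL) {
  stopifnot(inherits(radiographs, "radiograph_pair"))
  if (!identical(ct$unit, "mu")) ct <- hu_to_attenuation(ct)
  if (is.null(init)) {
    if (is.null(annotation)) stop("either an annotation or an init transform is required")
    init <- initialize_pose(annotation, radiographs$geometry)
  }
  stopifnot(is_rigid_transform(init, tol = 1e-6))
  center <- drop(transform_points(init, volume_centroid(ct)))

  lower <- c(rep(-cfg$bound_rot, 3), rep(-cfg$bound_trans, 3))
  upper <- -lower
  evals <- 0L

  run_level <- function(cfg_level, start) {
    fn <- function(p) {
      evals <<- evals + 1L
      registration_cost(p, ct, radiographs, masks, cfg_level,
                        init = init, center = center)
    }
    withCallingHandlers(
      minqa::bobyqa(start, fn, lower = lower, upper = upper,
                    control = list(rhobeg = cfg_level$rhobeg,
                                   rhoend = cfg_level$rhoend,
                                   maxfun = cfg_level$maxfun)),
      warning = function(w) {
        if (grepl("maxfun", conditionMessage(w))) invokeRestart("muffleWarning")
      })
  }

  start <- rep(0, 6)
  if (cfg$levels == 2L) {
    coarse <- cfg
    coarse$step <- 2 * (if (is.null(cfg$step)) min(ct$spacing) / 2 else cfg$step)
    coarse$rhoend <- max(cfg$rhoend, 0.1)
    fit0 <- run_level(coarse, start)
    start <- fit0$par
  }
  fit <- run_level(cfg, start)

  at_bound <- any(abs(fit$par - lower) < 1e-8) || any(abs(fit$par - upper) < 1e-8)
  status <- if (fit$ierr != 0) {
    paste0("optimizer stopped early (code ", fit$ierr, "); best-so-far returned")
  } else if (at_bound) {
    "solution saturates a parameter bound"
  } else {
    "converged"
  }
  transform <- orthonormalize_transform(
    pose_to_transform(fit$par, center) %*% init)
  structure(list(transform = transform, params = fit$par, cost = fit$fval,
                 similarity = -fit$fval, evaluations = evals,
                 converged = fit$ierr == 0 && !at_bound, status = status,
                 init = init),
            class = "bone_registration")
}

#' @export
print.bone_registration <- function(x, ...) {
  cat("2D-3D rigid registration\n")
  cat(sprintf("  summed LNCC similarity: %.4f (of 2 attainable)\n", x$similarity))
  cat(sprintf("  %d cost evaluations, %s\n", x$evaluations, x$status))
  cat("  CT -> world transform:\n")
  print(round(x$transform, 4))
  invisible(x)
}
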