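#' Parametric digital leg phantom specification
#'
#' The phantom emulates a desk-scale analog of a rigid full-leg validation
#' phantom: femur (head sphere, shaft, two condyle spheres), tibia (plateau
#' disk, shaft), fibula, patella and talus built from implicit solids,
#' voxelized into a CT volume, with six spherical radiopaque fiducial
#' markers embedded per bone and every measurement landmark recorded.  The
#' frontal-plane deformity is constructed directly: the tibial mechanical
#' axis is tilted by the requested MA (varus positive) and the tibial
#' plateau plane by the requested JLCA (lateral opening positive), so the
#' ground-truth angles are known analytically.
#'
#' Default voxel spacing is 1.5 mm, coarser than clinical CT (0.5-1 mm
#' slices), which keeps full registration loops in the minutes range on one
#' CPU; pass a smaller `spacing` for higher-resolution studies.
#'
#' @param spacing isotropic voxel spacing (mm).
#' @param leg_length hip-to-ankle scale of the phantom (mm).
#' @param shaft_radius,condyle_radius,head_radius bone radii (mm).
#' @param ma,jlca target deformity angles (degrees; varus and lateral
#'   opening positive).
#' @param side `"left"` or `"right"`.
#' @param markers_per_bone number of fiducials per bone (default 6).
#' @param marker_diameter fiducial diameter (mm, default 3); must be at
#'   least twice the voxel spacing to stay detectable.
#' @param hu named list of tissue HU values (`bone`, `marker`, `soft`,
#'   `air`).
#' @param noise_sd additive Gaussian HU noise in the volume (0 = off).
#' @param seed integer seed driving every stochastic element (noise).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(spacing = 1.5, leg_length = 400,
                         shaft_radius = 12, condyle_radius = 16,
                         head_radius = 18,
                         ma = 5, jlca = 3, side = c("left", "right"),
                         markers_per_bone = 6L, marker_diameter = 3,
                         hu = list(bone = 1200, marker = 3000,
                                   soft = 40, air = -1000),
                         noise_sd = 0, seed = 1L) {
  side <- match.arg(side)
  stopifnot(spacing > 0, leg_length > 100, shaft_radius > 0,
            condyle_radius > 0, head_radius > 0, noise_sd >= 0)
  if (marker_diameter < 2 * spacing) {
    stop("marker diameter must be >= 2 * spacing for detectability")
  }
  if (markers_per_bone != 6L) {
    stop("the reference setup uses six markers per bone")
  }
  structure(list(spacing = spacing, leg_length = leg_length,
                 shaft_radius = shaft_radius,
                 condyle_radius = condyle_radius, head_radius = head_radius,
                 ma = ma, jlca = jlca, side = side,
                 markers_per_bone = as.integer(markers_per_bone),
                 marker_diameter = marker_diameter, hu = hu,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Desk-scale biplanar geometry matched to the default phantom
#'
#' Same 918 mm source-to-isocenter distance and 477.5 mm emitter start
#' height as the bundled clinical calibration, but with a 1.5 mm pixel
#' pitch and a 320 x 96 image so that simulated radiographs of the
#' desk-scale phantom stay small.
#'
#' @return an [eos_geometry()].
#' @export
phantom_geometry <- function() {
  eos_geometry(f_f = 918, f_l = 918, z0 = 477.5, lambda_z = 1.5,
               n_rows = 320L, n_cols = 96L)
}

# ---- implicit solids ---------------------------------------------------

solid_sphere <- function(center, r) list(type = "sphere", center = center, r = r)
solid_cylinder <- function(p0, p1, r) list(type = "cylinder", p0 = p0, p1 = p1, r = r)

solid_bbox <- function(s) {
  if (s$type == "sphere") {
    rbind(s$center - s$r, s$center + s$r)
  } else {
    rbind(pmin(s$p0, s$p1) - s$r, pmax(s$p0, s$p1) + s$r)
  }
}

# paint `value` into vol (3D array) wherever inside the solid
paint_solid <- function(vol, coords, s, value) {
  bb <- solid_bbox(s)
  idx <- lapply(1:3, function(k) {
    which(coords[[k]] >= bb[1, k] - 1e-9 & coords[[k]] <= bb[2, k] + 1e-9)
  })
  if (any(lengths(idx) == 0)) return(vol)
  x <- coords[[1]][idx[[1]]]
  y <- coords[[2]][idx[[2]]]
  z <- coords[[3]][idx[[3]]]
  nx <- length(x); ny <- length(y); nz <- length(z)
  X <- array(rep(x, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(y, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(z, each = nx * ny), c(nx, ny, nz))
  inside <- if (s$type == "sphere") {
    (X - s$center[1])^2 + (Y - s$center[2])^2 + (Z - s$center[3])^2 <= s$r^2
  } else {
    d <- s$p1 - s$p0
    len <- sqrt(sum(d^2))
    d <- d / len
    vx <- X - s$p0[1]; vy <- Y - s$p0[2]; vz <- Z - s$p0[3]
    sp <- vx * d[1] + vy * d[2] + vz * d[3]
    rho2 <- vx^2 + vy^2 + vz^2 - sp^2
    sp >= 0 & sp <= len & rho2 <= s$r^2
  }
  sub <- vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  sub[inside] <- value
  vol[idx[[1]], idx[[2]], idx[[3]]] <- sub
  vol
}

voxelize_solids <- function(solids, values, bbox, spacing) {
  coords <- lapply(1:3, function(k) seq(bbox[1, k], bbox[2, k], by = spacing))
  vol <- array(-1000, vapply(coords, length, 1L))
  for (i in seq_along(solids)) {
    vol <- paint_solid(vol, coords, solids[[i]], values[i])
  }
  ct_volume(vol, spacing = rep(spacing, 3),
            origin = vapply(coords, min, 1))
}

# ---- analytic surface meshes -------------------------------------------

mesh_sphere_parts <- function(center, r, n_theta = 16L, n_phi = 28L) {
  th <- seq(0, pi, length.out = n_theta + 1)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  verts <- rbind(center + c(0, 0, r))
  ring_start <- integer(0)
  for (i in 2:n_theta) {
    ring_start <- c(ring_start, nrow(verts) + 1L)
    verts <- rbind(verts, t(vapply(ph, function(p) {
      center + r * c(sin(th[i]) * cos(p), sin(th[i]) * sin(p), cos(th[i]))
    }, numeric(3))))
  }
  verts <- rbind(verts, center - c(0, 0, r))
  bottom <- nrow(verts)
  faces <- NULL
  # top cap
  r1 <- ring_start[1]
  for (j in seq_len(n_phi)) {
    faces <- rbind(faces, c(1L, r1 + j - 1L, r1 + j %% n_phi))
  }
  # bands
  for (i in seq_len(length(ring_start) - 1)) {
    a <- ring_start[i]; b <- ring_start[i + 1]
    for (j in seq_len(n_phi)) {
      j2 <- j %% n_phi + 1L
      faces <- rbind(faces,
                     c(a + j - 1L, b + j - 1L, b + j2 - 1L),
                     c(a + j - 1L, b + j2 - 1L, a + j2 - 1L))
    }
  }
  # bottom cap
  rl <- ring_start[length(ring_start)]
  for (j in seq_len(n_phi)) {
    faces <- rbind(faces, c(bottom, rl + j %% n_phi, rl + j - 1L))
  }
  list(vertices = verts, faces = faces)
}

# flat-capped cylinder with symmetric polar cap sampling
mesh_cylinder_parts <- function(p0, p1, r, n_circ = 28L, n_len = 6L,
                                n_cap = 3L) {
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  d <- d / len
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  ph <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  circ <- t(vapply(ph, function(p) cos(p) * e1 + sin(p) * e2, numeric(3)))

  verts <- NULL
  faces <- NULL
  ring <- function(center, radius) t(center + t(radius * circ))
  add_ring <- function(center, radius) {
    verts <<- rbind(verts, ring(center, radius))
    nrow(verts) - n_circ + 1L
  }
  band <- function(a, b) {
    for (j in seq_len(n_circ)) {
      j2 <- j %% n_circ + 1L
      faces <<- rbind(faces,
                      c(a + j - 1L, b + j - 1L, b + j2 - 1L),
                      c(a + j - 1L, b + j2 - 1L, a + j2 - 1L))
    }
  }
  cap <- function(center, flip) {
    ctr_idx <- nrow(verts %||% matrix(0, 0, 3)) + 1L
    verts <<- rbind(verts, matrix(center, 1, 3))
    starts <- vapply(seq_len(n_cap), function(k) add_ring(center, r * k / n_cap), 1L)
    for (j in seq_len(n_circ)) {
      tri <- c(ctr_idx, starts[1] + j - 1L, starts[1] + j %% n_circ)
      if (flip) tri <- rev(tri)
      faces <<- rbind(faces, tri)
    }
    if (n_cap > 1) {
      for (k in seq_len(n_cap - 1)) {
        if (flip) band(starts[k + 1], starts[k]) else band(starts[k], starts[k + 1])
      }
    }
    starts[n_cap]   # outermost ring index
  }
  bot_rim <- cap(p0, flip = TRUE)
  top_rim <- cap(p1, flip = FALSE)
  # interior side rings only: the cap rims provide the end rings
  if (n_len > 1) {
    side_starts <- vapply(seq_len(n_len - 1) / n_len, function(tq) {
      add_ring(p0 + tq * len * d, r)
    }, 1L)
    band(bot_rim, side_starts[1])
    for (k in seq_len(n_len - 2)) band(side_starts[k], side_starts[k + 1])
    band(side_starts[n_len - 1], top_rim)
  } else {
    band(bot_rim, top_rim)
  }
  list(vertices = verts, faces = faces)
}

merge_parts <- function(parts, label) {
  verts <- NULL
  faces <- NULL
  for (p in parts) {
    off <- nrow(verts %||% matrix(0, 0, 3))
    verts <- rbind(verts, p$vertices)
    faces <- rbind(faces, p$faces + off)
  }
  bone_mesh(verts, faces, label)
}

# ---- phantom construction ----------------------------------------------

#' Build the synthetic leg phantom
#'
#' Constructs the full phantom from a [phantom_spec()]: per-segment surface
#' meshes, the CT volume (bone + soft-tissue envelope + fiducials, with
#' optional seeded Gaussian noise), per-assembly bone-plus-marker volumes
#' for registration (thigh: femur + patella; shank: tibia + fibula +
#' talus), the labeled fiducial set, all measurement landmarks and arrow
#' annotations, and the analytically known ground-truth MA and JLCA.
#' Deterministic for a given spec and seed.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_truth`.
#' @export
build_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  lat <- lateral_sign(spec$side)
  L <- spec$leg_length
  hjc <- c(0, 0, 0.95 * L)
  kjc <- c(0, 0, 0.48 * L)
  tib_len <- 0.375 * L
  r_def <- rot_y(lat * spec$ma)
  dir_t <- drop(r_def %*% c(0, 0, -1))      # tibial mechanical axis direction
  ajc_true <- kjc + tib_len * dir_t
  if (spec$ma >= 45 || spec$jlca >= 30) {
    stop("deformity angles produce a geometrically impossible phantom")
  }

  rs <- spec$shaft_radius
  rc <- spec$condyle_radius
  rh <- spec$head_radius
  c_sep <- rc + 1
  z_cond <- kjc[3] + 4 + rc                  # condyle centers; distal tips 4 mm above plateau

  # femur
  fem_solids <- list(
    solid_sphere(hjc, rh),
    solid_cylinder(c(0, 0, z_cond + 2), c(0, 0, hjc[3] - rh + 4), rs),
    solid_sphere(c(c_sep, 0, z_cond), rc),
    solid_sphere(c(-c_sep, 0, z_cond), rc)
  )
  fem_mesh <- merge_parts(list(
    mesh_sphere_parts(hjc, rh),
    mesh_cylinder_parts(c(0, 0, z_cond + 2), c(0, 0, hjc[3] - rh + 4), rs),
    mesh_sphere_parts(c(c_sep, 0, z_cond), rc),
    mesh_sphere_parts(c(-c_sep, 0, z_cond), rc)
  ), "femur")

  # tibia: plateau disk normal encodes the JLCA (plane descends laterally
  # for a lateral opening, the femoral tangent being horizontal)
  n_pl <- c(lat * tan(spec$jlca * pi / 180), 0, 1)
  n_pl <- n_pl / sqrt(sum(n_pl^2))
  u_pl <- c(1, 0, 0) - n_pl[1] * n_pl
  u_pl <- u_pl / sqrt(sum(u_pl^2))
  w_pl <- c(n_pl[2] * u_pl[3] - n_pl[3] * u_pl[2],
            n_pl[3] * u_pl[1] - n_pl[1] * u_pl[3],
            n_pl[1] * u_pl[2] - n_pl[2] * u_pl[1])
  r_plat <- 2 * rs + 2
  q_distal <- kjc + tib_len * dir_t
  tib_solids <- list(
    solid_cylinder(kjc - 10 * n_pl, kjc, r_plat),
    solid_cylinder(kjc + 8 * dir_t, q_distal, rs)
  )
  tib_mesh <- merge_parts(list(
    mesh_cylinder_parts(kjc - 10 * n_pl, kjc, r_plat, n_cap = 4L),
    mesh_cylinder_parts(kjc + 8 * dir_t, q_distal, rs, n_cap = 4L)
  ), "tibia")

  fib_p0 <- kjc + 25 * dir_t + lat * 20 * c(1, 0, 0)
  fib_p1 <- kjc + 135 * dir_t + lat * 20 * c(1, 0, 0)
  fib_solids <- list(solid_cylinder(fib_p0, fib_p1, 4))
  fib_mesh <- merge_parts(list(mesh_cylinder_parts(fib_p0, fib_p1, 4,
                                                   n_circ = 16L, n_cap = 2L)),
                          "fibula")

  talus_c <- q_distal + 14 * dir_t           # 2 mm articular gap below the distal face
  tal_solids <- list(solid_sphere(talus_c, 12))
  tal_mesh <- merge_parts(list(mesh_sphere_parts(talus_c, 12)), "talus")

  pat_c <- c(0, -30, kjc[3] + 13)            # anterior = -y
  pat_solids <- list(solid_sphere(pat_c, 9))
  pat_mesh <- merge_parts(list(mesh_sphere_parts(pat_c, 9)), "patella")

  # fiducial markers (6 per bone, inside the bone material)
  fem_markers <- rbind(
    hjc + c(0, 5, -5),
    c(5, 3, 330 / 400 * L), c(-5, -3, 292 / 400 * L), c(4, -4, 252 / 400 * L),
    c(c_sep - 3, 2, z_cond), c(-c_sep + 3, -2, z_cond - 2))
  tib_axis_pt <- function(s, off) kjc + s * dir_t + c(off[1], off[2], 0)
  tib_markers <- rbind(
    kjc - 5 * n_pl + 10 * u_pl,
    tib_axis_pt(30, c(5, 3)), tib_axis_pt(60, c(-5, -3)),
    tib_axis_pt(90, c(4, -4)), tib_axis_pt(120, c(-3, 4)),
    tib_axis_pt(140, c(0, 4)))
  markers <- marker_set(rbind(fem_markers, tib_markers),
                        c(paste0("fem", 1:6), paste0("tib", 1:6)), "CT")
  r_mark <- spec$marker_diameter / 2
  marker_solids <- lapply(seq_len(12), function(i) {
    solid_sphere(markers$centers[i, ], r_mark)
  })

  # landmarks
  set_lm <- function() {
    ph <- seq(0, 2 * pi, length.out = 13)[-13]
    head_pts <- t(vapply(ph, function(p) {
      hjc + rh * c(sin(0.6) * cos(p), sin(0.6) * sin(p), cos(0.6))
    }, numeric(3)))
    head_pts <- rbind(head_pts, t(vapply(ph + 0.26, function(p) {
      hjc + rh * c(sin(1.1) * cos(p), sin(1.1) * sin(p), cos(1.1))
    }, numeric(3))), hjc + c(0, 0, rh))
    plateau_pts <- t(vapply(seq(0, 2 * pi, length.out = 9)[-9], function(p) {
      kjc + (r_plat - 6) * (cos(p) * u_pl + sin(p) * w_pl)
    }, numeric(3)))
    pat_pts <- t(vapply(ph, function(p) {
      pat_c + 9 * c(sin(0.4) * cos(p), -cos(0.4), sin(0.4) * sin(p))
    }, numeric(3)))
    list(
      femoral_head_points = head_pts,
      eminences = rbind(kjc + 4 * u_pl, kjc - 4 * u_pl),
      plateau_points = plateau_pts,
      patella_points = pat_pts,
      epicondyles = rbind(c(c_sep + rc, 0, z_cond), c(-c_sep - rc, 0, z_cond))
    )
  }
  landmarks <- set_lm()

  arrows <- list(
    femur = list(ct_start = c(0, 0, z_cond), ct_end = hjc),
    tibia = list(ct_start = q_distal, ct_end = kjc)
  )

  # full CT volume: soft tissue envelope + all bones + markers
  margin <- 8
  bbox <- rbind(c(-r_plat - 40, -55, q_distal[3] - 28) - margin,
                c(r_plat + 40, 45, hjc[3] + rh) + margin)
  soft <- list(
    solid_cylinder(c(0, 0, kjc[3] + 5), c(0, 0, hjc[3] - 5), 45),
    solid_cylinder(c(0, 0, ajc_true[3] - 20), c(0, 0, kjc[3] + 5), 38)
  )
  bone_solids <- c(fem_solids, tib_solids, fib_solids, tal_solids, pat_solids)
  all_solids <- c(soft, bone_solids, marker_solids)
  values <- c(rep(spec$hu$soft, length(soft)),
              rep(spec$hu$bone, length(bone_solids)),
              rep(spec$hu$marker, length(marker_solids)))
  volume <- voxelize_solids(all_solids, values, bbox, spec$spacing)
  if (spec$noise_sd > 0) {
    volume$data <- volume$data + with_seed(spec$seed, {
      array(stats::rnorm(length(volume$data), 0, spec$noise_sd),
            dim = dim(volume$data))
    })
  }

  # per-assembly registration volumes (bone + own markers, no soft tissue)
  seg_volume <- function(solids, marker_idx, pad = 6) {
    bb <- Reduce(function(a, b) rbind(pmin(a[1, ], b[1, ]), pmax(a[2, ], b[2, ])),
                 lapply(solids, solid_bbox))
    bb <- rbind(bb[1, ] - pad, bb[2, ] + pad)
    voxelize_solids(c(solids, marker_solids[marker_idx]),
                    c(rep(spec$hu$bone, length(solids)),
                      rep(spec$hu$marker, length(marker_idx))),
                    bb, spec$spacing)
  }
  segment_volumes <- list(
    femur = seg_volume(c(fem_solids, pat_solids), 1:6),
    tibia = seg_volume(c(tib_solids, fib_solids, tal_solids), 7:12)
  )

  structure(list(
    spec = spec,
    volume = volume,
    segment_volumes = segment_volumes,
    meshes = list(femur = fem_mesh, tibia = tib_mesh, fibula = fib_mesh,
                  patella = pat_mesh, talus = tal_mesh),
    markers = markers,
    landmarks = landmarks,
    arrows = arrows,
    joint_centers = list(hjc = hjc, kjc = kjc, ajc = ajc_true),
    ma = spec$ma, jlca = spec$jlca, side = spec$side
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  d <- dim(x$volume$data)
  cat(sprintf("Synthetic leg phantom (%s leg): MA %+.1f deg, JLCA %+.1f deg\n",
              x$side, x$ma, x$jlca))
  cat(sprintf("  CT volume %d x %d x %d @ %.2g mm, %d fiducials\n",
              d[1], d[2], d[3], x$spec$spacing, nrow(x$markers$centers)))
  invisible(x)
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a biplanar radiograph pair of the posed phantom
#'
#' Renders frontal and lateral projections of the phantom with each rigid
#' assembly at its own pose (thigh assembly: femur + patella; shank
#' assembly: tibia + fibula + talus), composited additively -- a rigid
#' per-bone approximation of a postural change that ignores soft tissue.
#' Also emits exact 2D fiducial projections, arrow annotations derived from
#' the true landmarks, and per-bone region-of-interest masks.
#'
#' @param truth a [build_phantom()] result.
#' @param pose_femur,pose_tibia 4x4 rigid transforms (CT to world) for the
#'   two assemblies.
#' @param g an [eos_geometry()]; default [phantom_geometry()].
#' @param noise_sigma additive Gaussian image noise (same units as the DRR
#'   line integrals), seeded from the phantom spec.
#' @return list with `pair` (a [radiograph_pair()]), `markers2d` (per-plane
#'   data frames of posed fiducial projections), `annotations` (per-bone
#'   [arrow_annotation()]), `masks` (per-bone per-plane [roi_rect()]), and
#'   `poses`.
#' @export
simulate_eos_pair <- function(truth, pose_femur = diag(4), pose_tibia = diag(4),
                              g = phantom_geometry(), noise_sigma = 0) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (!is_rigid_transform(pose_femur, tol = 1e-6) ||
      !is_rigid_transform(pose_tibia, tol = 1e-6)) {
    stop("poses must be rigid transforms")
  }
  poses <- list(femur = pose_femur, tibia = pose_tibia)
  att <- lapply(truth$segment_volumes, hu_to_attenuation)
  imgs <- list()
  for (plane in c("frontal", "lateral")) {
    img <- render_drr(att$femur, pose_femur, g, plane) +
      render_drr(att$tibia, pose_tibia, g, plane)
    if (noise_sigma > 0) {
      img <- img + with_seed(truth$spec$seed + plane_index(plane), {
        matrix(stats::rnorm(length(img), 0, noise_sigma), nrow(img))
      })
    }
    imgs[[plane]] <- img
  }
  pair <- radiograph_pair(imgs$frontal, imgs$lateral, g)

  bone_of_marker <- ifelse(grepl("^fem", truth$markers$labels), "femur", "tibia")
  posed_centers <- truth$markers$centers
  for (b in c("femur", "tibia")) {
    sel <- bone_of_marker == b
    posed_centers[sel, ] <- transform_points(poses[[b]],
                                             posed_centers[sel, , drop = FALSE])
  }
  markers2d <- lapply(c(frontal = "frontal", lateral = "lateral"), function(pl) {
    p <- project_point(posed_centers, g, pl)
    data.frame(label = truth$markers$labels, h = p[, 1], v = p[, 2])
  })

  annotations <- lapply(c(femur = "femur", tibia = "tibia"), function(b) {
    s <- truth$arrows[[b]]$ct_start
    e <- truth$arrows[[b]]$ct_end
    sp <- drop(transform_points(poses[[b]], s))
    ep <- drop(transform_points(poses[[b]], e))
    arrow_annotation(project_point(sp, g, "frontal"), project_point(ep, g, "frontal"),
                     project_point(sp, g, "lateral"), project_point(ep, g, "lateral"),
                     s, e)
  })

  # region-of-interest masks: tight box around each bone's own projected
  # silhouette.  The knee-side edge is retracted by the similarity patch
  # radius so that no patch window reaches across the joint space into the
  # other bone's (differently posed) content.
  retract <- 5L
  masks <- lapply(c(femur = "femur", tibia = "tibia"), function(b) {
    pv <- transform_points(poses[[b]], truth$meshes[[b]]$vertices)
    out <- list()
    for (pl in c("frontal", "lateral")) {
      px <- project_point(pv, g, pl)
      m <- 2
      r0 <- max(0, floor(min(px[, 2])) - m)
      r1 <- min(g$n_rows, ceiling(max(px[, 2])) + m)
      if (b == "femur") r1 <- r1 - m - retract else r0 <- r0 + m + retract
      out[[pl]] <- roi_rect(r0, max(0, floor(min(px[, 1])) - m), r1,
                            min(g$n_cols, ceiling(max(px[, 1])) + m))
    }
    out
  })

  list(pair = pair, markers2d = markers2d, annotations = annotations,
       masks = masks, poses = poses)
}
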