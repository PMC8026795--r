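#' Least-squares sphere fit
#'
#' Algebraic least squares: the sphere equation is linearized as
#' `2 c . p + (r^2 - |c|^2) = |p|^2` and solved for center and radius by
#' ordinary least squares.  Used for the hip joint center (points picked on
#' the femoral head) and for fiducial marker localization.
#'
#' @param points n x 3 matrix, n >= 4, not coplanar.
#' @return list with `center` (length 3), `radius` (mm) and `rms` residual
#'   (mm, geometric distances to the fitted sphere).
#' @export
fit_sphere <- function(points) {
  p <- as.matrix(points)
  stopifnot(ncol(p) == 3)
  if (nrow(p) < 4) stop("sphere fit needs at least 4 points")
  a <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  qa <- qr(a)
  if (qa$rank < 4) stop("points are coplanar or otherwise degenerate for a sphere fit")
  # guard against numerically near-coplanar sets that keep full rank
  if (kappa(a, exact = FALSE) > 1e10) {
    stop("points are coplanar or otherwise degenerate for a sphere fit")
  }
  sol <- qr.coef(qa, b)
  center <- sol[1:3]
  radius <- sqrt(sol[4] + sum(center^2))
  d <- sqrt(rowSums((p - rep(center, each = nrow(p)))^2)) - radius
  list(center = unname(center), radius = unname(radius),
       rms = sqrt(mean(d^2)))
}

#' Total-least-squares plane fit
#'
#' Minimizes orthogonal distances: the plane passes through the centroid
#' with normal given by the smallest right singular vector of the centered
#' points.  The normal is oriented so that its dot product with `orient` is
#' positive (superior by default).
#'
#' @param points n x 3 matrix, n >= 3, not collinear.
#' @param orient direction the returned normal should point along.
#' @return list with `point` (centroid), `normal` (unit), and `rms`
#'   orthogonal residual (mm).
#' @export
fit_plane <- function(points, orient = c(0, 1, 0)) {
  p <- as.matrix(points)
  stopifnot(ncol(p) == 3)
  if (nrow(p) < 3) stop("plane fit needs at least 3 points")
  ctr <- colMeans(p)
  x <- sweep(p, 2, ctr)
  s <- svd(x)
  if (s$d[2] < 1e-9 * max(s$d[1], 1)) {
    stop("points are collinear: plane is underdetermined")
  }
  n <- s$v[, 3]
  if (sum(n * orient) < 0) n <- -n
  list(point = unname(ctr), normal = unname(n),
       rms = sqrt(mean((x %*% n)^2)))
}

#' Knee joint center
#'
#' Arithmetic midpoint between the medial and lateral intercondylar
#' eminences of the tibial plateau.
#'
#' @param medial_eminence,lateral_eminence 3D points (mm).
#' @return length-3 point.
#' @export
compute_kjc <- function(medial_eminence, lateral_eminence) {
  stopifnot(length(medial_eminence) == 3, length(lateral_eminence) == 3)
  if (all(medial_eminence == lateral_eminence)) {
    stop("eminence points must be distinct")
  }
  (as.numeric(medial_eminence) + as.numeric(lateral_eminence)) / 2
}

#' Ankle joint center
#'
#' Centroid of the distal articular surface: all tibia and fibula vertices
#' whose closest-point distance to the talus surface is below the threshold.
#' The selected-vertex count is attached so the threshold can be adjusted
#' until the whole articular surface is covered, mirroring the visual
#' workflow.
#'
#' @param tibia,fibula,talus [bone_mesh()] objects (`fibula` may be `NULL`).
#' @param threshold selection distance (mm), > 0; default 3.
#' @return length-3 point with attribute `n_selected`.
#' @export
compute_ajc <- function(tibia, fibula, talus, threshold = 3) {
  stopifnot(inherits(tibia, "bone_mesh"), inherits(talus, "bone_mesh"),
            threshold > 0)
  pts <- tibia$vertices
  if (!is.null(fibula)) pts <- rbind(pts, fibula$vertices)
  d <- point_mesh_distance_cpp(pts, talus$vertices, talus$faces)
  sel <- d < threshold
  if (!any(sel)) {
    stop(sprintf("no articular-surface vertices within %.3g mm of the talus; increase the threshold", threshold))
  }
  structure(colMeans(pts[sel, , drop = FALSE]), n_selected = sum(sel))
}

#' Anatomical reorientation transform
#'
#' Returns the rigid transform that places the mechanical leg axis
#' (ankle to hip joint center) along +y (superior) and then rotates about
#' this axis until the best-fit plane of the anterior patellar surface
#' points is parallel to the frontal plane, its normal in the y-z plane
#' with positive z (anterior).  The ankle joint center maps to the origin.
#' In the resulting frame, +x is the patient's left, so the frontal plane
#' is the x-y plane and frontal-plane measures are obtained by dropping z.
#'
#' @param hjc,ajc hip and ankle joint centers (mm).
#' @param patella_points n x 3 points on the anterior patellar surface
#'   (n >= 3, not collinear).
#' @return 4x4 rigid transform.
#' @export
align_anatomical <- function(hjc, ajc, patella_points) {
  hjc <- as.numeric(hjc)
  ajc <- as.numeric(ajc)
  u <- hjc - ajc
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stop("hip and ankle joint centers coincide")
  u <- u / nu
  r1 <- rotation_between(u, c(0, 1, 0))

  pl <- fit_plane(patella_points, orient = c(0, 0, 1))
  # orient the patellar normal away from the leg axis (anterior)
  ctr <- colMeans(as.matrix(patella_points))
  axis_pt <- ajc + sum((ctr - ajc) * (hjc - ajc)) / nu^2 * (hjc - ajc)
  away <- ctr - axis_pt
  n <- pl$normal
  if (sum(n * away) < 0) n <- -n

  n1 <- drop(r1 %*% n)
  r2 <- rot_y(-atan2(n1[1], n1[3]) * 180 / pi)
  r <- r2 %*% r1
  rigid_transform(r, -r %*% ajc)
}

# minimal rotation taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  ax <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(ax^2))
  d <- sum(a * b)
  if (s < 1e-12) {
    if (d > 0) return(diag(3))
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a
    return(rodrigues(ax / sqrt(sum(ax^2)), pi))
  }
  rodrigues(ax / s, atan2(s, d))
}

lateral_sign <- function(side) {
  side <- match.arg(side, c("left", "right"))
  if (side == "left") 1 else -1   # +x is the patient's left in the aligned frame
}

#' Mechanical axis angle (3D, frontal-plane projection)
#'
#' Projects the hip, knee and ankle joint centers onto the frontal (x-y)
#' plane of the anatomically aligned frame and returns the
#' deviation-from-collinearity angle between the hip-knee and knee-ankle
#' lines (a straight leg measures 0).  The sign is positive when the knee
#' deviates laterally from the hip-ankle line (varus) and negative for
#' valgus, using `side` to resolve which x direction is lateral.
#'
#' @param hjc,kjc,ajc joint centers (mm) in the aligned frame (see
#'   [align_anatomical()]).
#' @param side `"left"` or `"right"`.
#' @return signed angle in degrees.
#' @export
compute_ma <- function(hjc, kjc, ajc, side = c("left", "right")) {
  side <- match.arg(side)
  h <- as.numeric(hjc)[1:2]
  k <- as.numeric(kjc)[1:2]
  a <- as.numeric(ajc)[1:2]
  u <- k - h
  w <- a - k
  if (sqrt(sum(u^2)) < 1e-9 || sqrt(sum(w^2)) < 1e-9) {
    stop("projected joint centers coincide")
  }
  ang <- acos(max(-1, min(1, sum(u * w) / sqrt(sum(u^2) * sum(w^2))))) * 180 / pi
  # signed lateral offset of the knee from the hip-ankle chord
  d <- a - h
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) stop("projected hip and ankle centers coincide")
  perp <- (k - h) - sum((k - h) * d) / nd^2 * d
  s <- sign(perp[1] * lateral_sign(side))
  if (s == 0) s <- 1
  ang * s
}

#' Femoral condyle tangent
#'
#' The femoral longitudinal axis is the first principal component of the
#' mesh vertices, oriented proximally.  The distal epiphysis is isolated by
#' a cut plane perpendicular to this axis right above the femoral
#' epicondyles: 5 mm proximal of the more proximal epicondyle landmark when
#' landmarks are supplied, otherwise at the most distal `cut_fraction` of
#' the femoral length.  A 2-means split (seeded deterministically with the
#' two extremal epiphysis vertices along the mediolateral axis) separates
#' the condyles; in each condyle the three most distal vertices along the
#' longitudinal axis are averaged and the tangent joins the two means.
#'
#' @param femur a [bone_mesh()] spanning shaft and condyles, in the
#'   anatomically aligned frame (y superior, x mediolateral).
#' @param cut_fraction distal fraction of femoral length kept as epiphysis
#'   when no epicondyle landmarks are given; default 0.15.
#' @param epicondyles optional 2 x 3 matrix of epicondyle landmarks (mm).
#' @return list with `point`, `direction` (unit, oriented laterally is not
#'   imposed), and `condyle_points` (2 x 3 matrix of the per-condyle means).
#' @export
compute_fct <- function(femur, cut_fraction = 0.15, epicondyles = NULL) {
  stopifnot(inherits(femur, "bone_mesh"))
  v <- femur$vertices
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  axis <- pc$rotation[, 1]
  if (axis[2] < 0) axis <- -axis           # point proximal (superior)
  s <- drop(v %*% axis)
  len <- max(s) - min(s)
  cut <- if (!is.null(epicondyles)) {
    epi <- as.matrix(epicondyles)
    stopifnot(nrow(epi) == 2, ncol(epi) == 3)
    max(epi %*% axis) + 5
  } else {
    min(s) + cut_fraction * len
  }
  epi_idx <- which(s <= cut)
  if (length(epi_idx) < 6) stop("epiphysis cut leaves too few vertices")
  ep <- v[epi_idx, , drop = FALSE]
  # deterministic seeds: extremal vertices along the mediolateral (x) axis
  seeds <- ep[c(which.min(ep[, 1]), which.max(ep[, 1])), , drop = FALSE]
  km <- stats::kmeans(ep, centers = seeds)
  pts <- lapply(1:2, function(k) {
    ck <- ep[km$cluster == k, , drop = FALSE]
    if (nrow(ck) < 3) stop("condyle cluster has fewer than 3 points")
    sk <- drop(ck %*% axis)
    colMeans(ck[order(sk)[1:3], , drop = FALSE])
  })
  cp <- do.call(rbind, pts)
  dir <- cp[2, ] - cp[1, ]
  dir <- dir / sqrt(sum(dir^2))
  list(point = colMeans(cp), direction = unname(dir), condyle_points = cp)
}

#' Joint line convergence angle (3D, frontal-plane projection)
#'
#' Projects the femoral condyle tangent and the tibial plateau plane onto
#' the frontal (x-y) plane of the aligned frame; the plateau plane appears
#' as its trace line (the tibial condyle tangent).  Returns the angle
#' between the two lines, signed positive when the joint space opens
#' laterally (the femoral tangent climbing superiorly relative to the
#' plateau as one moves laterally) and negative for medial opening.
#'
#' @param fct femoral condyle tangent: a list with `direction` (see
#'   [compute_fct()]).
#' @param tct_plane tibial plateau plane: list with `normal` (see
#'   [fit_plane()]).
#' @param side `"left"` or `"right"`.
#' @return signed angle in degrees.
#' @export
compute_jlca <- function(fct, tct_plane, side = c("left", "right")) {
  side <- match.arg(side)
  lat <- lateral_sign(side)
  f2 <- fct$direction[1:2]
  if (sqrt(sum(f2^2)) < 1e-9) {
    stop("condyle tangent is perpendicular to the frontal plane")
  }
  n <- tct_plane$normal
  t2 <- c(n[2], -n[1])                     # trace of the plane in the frontal view
  if (sqrt(sum(t2^2)) < 1e-9) {
    stop("plateau plane is parallel to the frontal plane: no trace line")
  }
  ang_of <- function(d2) {
    if (d2[1] * lat < 0) d2 <- -d2         # orient toward lateral
    atan2(d2[2], d2[1] * lat) * 180 / pi
  }
  ang_of(f2) - ang_of(t2)
}

#' Full MA/JLCA measurement from meshes and landmarks
#'
#' Runs the complete 3D measurement chain on one leg: sphere-fit hip
#' center, eminence-midpoint knee center, articular-surface ankle center,
#' anatomical reorientation, then the frontal-plane mechanical axis and
#' joint line convergence angle with the varus-positive / lateral-opening-
#' positive sign convention.
#'
#' @param meshes named list of [bone_mesh()] objects: `femur`, `tibia`,
#'   `talus` required, `fibula` and `patella` optional (patella points come
#'   from landmarks).
#' @param landmarks named list: `femoral_head_points` (n x 3),
#'   `eminences` (2 x 3), `plateau_points` (8 x 3), `patella_points`
#'   (n x 3), optional `epicondyles` (2 x 3).  CT-frame mm, same frame as
#'   the meshes.
#' @param side `"left"` or `"right"`.
#' @param ajc_threshold articular-surface selection distance (mm).
#' @param cut_fraction see [compute_fct()].
#' @return object of class `alignment_measurement`: `ma`, `jlca` (degrees,
#'   signed), `hjc`, `kjc`, `ajc` (aligned frame), `fct`, `tct`,
#'   `alignment` (the reorientation transform), `n_ajc`.
#' @export
measure_alignment <- function(meshes, landmarks, side = c("left", "right"),
                              ajc_threshold = 3, cut_fraction = 0.15) {
  side <- match.arg(side)
  for (nm in c("femur", "tibia", "talus")) {
    if (is.null(meshes[[nm]])) stop("missing mesh: ", nm)
  }
  for (nm in c("femoral_head_points", "eminences", "plateau_points",
               "patella_points")) {
    if (is.null(landmarks[[nm]])) stop("missing landmark set: ", nm)
  }
  hjc <- fit_sphere(landmarks$femoral_head_points)$center
  em <- as.matrix(landmarks$eminences)
  kjc <- compute_kjc(em[1, ], em[2, ])
  ajc <- compute_ajc(meshes$tibia, meshes$fibula, meshes$talus,
                     threshold = ajc_threshold)
  n_ajc <- attr(ajc, "n_selected")

  al <- align_anatomical(hjc, ajc, landmarks$patella_points)
  hjc_a <- drop(transform_points(al, hjc))
  kjc_a <- drop(transform_points(al, kjc))
  ajc_a <- drop(transform_points(al, as.numeric(ajc)))
  femur_a <- transform_mesh(meshes$femur, al)

  epi <- if (!is.null(landmarks$epicondyles)) {
    transform_points(al, as.matrix(landmarks$epicondyles))
  } else NULL
  fct <- compute_fct(femur_a, cut_fraction = cut_fraction, epicondyles = epi)
  tct <- fit_plane(transform_points(al, as.matrix(landmarks$plateau_points)),
                   orient = c(0, 1, 0))

  structure(list(
    ma = compute_ma(hjc_a, kjc_a, ajc_a, side),
    jlca = compute_jlca(fct, tct, side),
    hjc = hjc_a, kjc = kjc_a, ajc = ajc_a,
    fct = fct, tct = tct, alignment = al,
    n_ajc = n_ajc, side = side
  ), class = "alignment_measurement")
}

#' @export
print.alignment_measurement <- function(x, ...) {
  cat(sprintf("Lower-limb alignment (%s leg)\n", x$side))
  cat(sprintf("  MA:   %+.1f deg (varus positive)\n", x$ma))
  cat(sprintf("  JLCA: %+.1f deg (lateral opening positive)\n", x$jlca))
  cat(sprintf("  ankle articular surface: %d vertices selected\n", x$n_ajc))
  invisible(x)
}
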