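#' Labeled fiducial marker sets
#'
#' A `marker_set` carries labeled 3D marker centers (mm), per-marker fit
#' residuals and a frame tag (`"CT"` or `"EOS"`).  In the reference
#' validation setup each bone carries six radiopaque spherical markers of
#' 3 mm diameter, visible both in the CT volume and in the radiographs.
#'
#' @param centers n x 3 matrix of centers (mm).
#' @param labels unique character labels, one per marker.
#' @param frame `"CT"` or `"EOS"`.
#' @param residuals optional per-marker fit residual (mm).
#' @return an object of class `marker_set`.
#' @export
marker_set <- function(centers, labels, frame = c("CT", "EOS"),
                       residuals = NULL) {
  frame <- match.arg(frame)
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3, nrow(centers) == length(labels))
  if (anyDuplicated(labels)) stop("marker labels must be unique")
  rownames(centers) <- labels
  structure(list(centers = centers, labels = as.character(labels),
                 frame = frame,
                 residuals = residuals %||% rep(NA_real_, nrow(centers))),
            class = "marker_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("%d fiducial markers (%s frame)\n", nrow(x$centers), x$frame))
  print(round(x$centers, 3))
  invisible(x)
}

#' Extract spherical marker centers from a CT volume
#'
#' Thresholds the volume, labels 6-connected components, and localizes each
#' component as a sphere.  When a component offers enough boundary voxels
#' (voxels with a sub-threshold face neighbor, i.e. the discrete marker
#' surface), their centers are sphere-fitted with [fit_sphere()] and the
#' radius is corrected by half a voxel for the inward bias of inside-surface
#' voxel centers.  Small components -- markers spanning only a handful of
#' voxels at coarse spacing -- fall back to the component centroid with an
#' equivalent-volume diameter estimate.  Components whose estimated
#' diameter deviates from the expected marker diameter by more than 50% are
#' rejected, filtering bone fragments and clutter.
#'
#' @param vol a [ct_volume()].
#' @param intensity_threshold HU threshold separating markers from
#'   background/bone.
#' @param expected_diameter nominal marker diameter (mm); default 3.
#' @return a [marker_set()] in the CT frame, labels `m1`, `m2`, ... in
#'   component order.
#' @export
marker_centers_from_volume <- function(vol, intensity_threshold,
                                       expected_diameter = 3) {
  stopifnot(inherits(vol, "ct_volume"))
  mask <- vol$data > intensity_threshold
  if (!any(mask)) stop("no voxels above the intensity threshold")
  d <- dim(vol$data)
  lab <- array(label_components_cpp(as.logical(mask), d), dim = d)

  # boundary voxels: inside the mask but with a face neighbor outside
  interior <- array(TRUE, d)
  pad <- function(m, shift, axis) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (shift > 0) {
      idx_dst[[axis]] <- 2:n
      idx_src[[axis]] <- 1:(n - 1)
    } else {
      idx_dst[[axis]] <- 1:(n - 1)
      idx_src[[axis]] <- 2:n
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (axis in 1:3) {
    for (shift in c(-1, 1)) interior <- interior & pad(mask, shift, axis)
  }
  boundary <- mask & !interior

  centers <- NULL
  res <- numeric(0)
  voxvol <- prod(vol$spacing)
  halfvox <- mean(vol$spacing) / 2
  for (k in seq_len(max(lab))) {
    cidx <- which(lab == k, arr.ind = TRUE)
    bidx <- which(boundary & lab == k, arr.ind = TRUE)
    world_b <- sweep(sweep(bidx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
    fit <- if (nrow(bidx) >= 12) {
      tryCatch(fit_sphere(world_b), error = function(e) NULL)
    } else NULL
    if (!is.null(fit)) {
      ctr <- fit$center
      diam <- 2 * (fit$radius + halfvox)
      rms <- fit$rms
    } else {
      world_c <- sweep(sweep(cidx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
      ctr <- colMeans(world_c)
      diam <- 2 * (3 * nrow(cidx) * voxvol / (4 * pi))^(1 / 3)
      rms <- NA_real_
    }
    if (abs(diam - expected_diameter) > 0.5 * expected_diameter) next
    centers <- rbind(centers, ctr)
    res <- c(res, rms)
  }
  if (is.null(centers)) {
    stop("no components passed the spherical-marker diameter gate")
  }
  marker_set(centers, paste0("m", seq_len(nrow(centers))), "CT",
             residuals = res)
}

#' Triangulate labeled 2D marker annotations to 3D
#'
#' Per label, the frontal and lateral pixel coordinates are triangulated
#' with [triangulate_point()]; the result is tagged as the EOS (world)
#' frame.  Labels present in only one plane raise an error naming them.
#'
#' @param frontal,lateral data frames with columns `label`, `h`, `v`.
#' @param g an [eos_geometry()].
#' @return a [marker_set()] in the EOS frame.
#' @export
triangulate_markers <- function(frontal, lateral, g) {
  fr <- as.data.frame(frontal)
  la <- as.data.frame(lateral)
  stopifnot(all(c("label", "h", "v") %in% names(fr)),
            all(c("label", "h", "v") %in% names(la)))
  un <- union(fr$label, la$label)
  missing <- setdiff(un, intersect(fr$label, la$label))
  if (length(missing)) {
    stop("labels present in only one plane: ", paste(sort(missing), collapse = ", "))
  }
  la <- la[match(fr$label, la$label), ]
  p <- triangulate_point(cbind(fr$h, fr$v), cbind(la$h, la$v), g)
  marker_set(p, fr$label, "EOS")
}

#' Least-squares rigid fit between labeled point sets
#'
#' Closed-form rigid registration (Kabsch/Umeyama, rotation + translation,
#' no scaling) of labeled correspondences: with known correspondence the
#' iterative closest-point loop terminates after a single assignment, so
#' the closed-form solution is exact.  Minimizes the sum of squared
#' distances `sum ||T s_i - t_i||^2`.
#'
#' @param source,target [marker_set()] objects (or bare n x 3 matrices with
#'   common row order) with >= 3 non-collinear correspondences; labels
#'   define the correspondence.
#' @return list with `transform` (4x4, source to target frame) and `rmsd`
#'   (mm).
#' @export
rigid_fit_points <- function(source, target) {
  s <- if (inherits(source, "marker_set")) source$centers else as.matrix(source)
  t <- if (inherits(target, "marker_set")) target$centers else as.matrix(target)
  if (inherits(source, "marker_set") && inherits(target, "marker_set")) {
    common <- intersect(source$labels, target$labels)
    if (length(common) < 3) stop("need at least 3 common labeled markers")
    s <- s[common, , drop = FALSE]
    t <- t[common, , drop = FALSE]
  }
  stopifnot(nrow(s) == nrow(t), ncol(s) == 3, ncol(t) == 3)
  if (nrow(s) < 3) stop("need at least 3 point correspondences")
  cs <- colMeans(s)
  ct <- colMeans(t)
  xs <- sweep(s, 2, cs)
  xt <- sweep(t, 2, ct)
  if (svd(xs)$d[2] < 1e-9 * max(1, svd(xs)$d[1])) {
    stop("source points are collinear: rotation is underdetermined")
  }
  h <- crossprod(xs, xt)
  sv <- svd(h)
  dsign <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  r <- sv$v %*% dsign %*% t(sv$u)
  tf <- rigid_transform(r, ct - r %*% cs)
  rmsd <- sqrt(mean(rowSums((transform_points(tf, s) - t)^2)))
  list(transform = tf, rmsd = rmsd)
}

#' Registration error between a recovered and a ground-truth transform
#'
#' Computes the error matrix `E = T^-1 GT`, reporting its translation
#' components (mm, per world axis), its rotation decomposed into intrinsic
#' x-y-z Euler angles (degrees), and the Euclidean norm of the translation
#' error.
#'
#' @param transform recovered 4x4 rigid transform `T`.
#' @param ground_truth reference 4x4 rigid transform `GT`.
#' @return object of class `registration_error`: `translation` (length 3,
#'   mm), `rotation` (length 3, degrees), `translation_norm` (mm), and the
#'   error matrix `E`.
#' @export
registration_error <- function(transform, ground_truth) {
  stopifnot(is_rigid_transform(transform, tol = 1e-6),
            is_rigid_transform(ground_truth, tol = 1e-6))
  e <- transform_invert(transform) %*% ground_truth
  tr <- e[1:3, 4]
  rot <- rotmat_to_euler(e[1:3, 1:3])
  structure(list(translation = unname(tr), rotation = unname(rot),
                 translation_norm = sqrt(sum(tr^2)), E = e),
            class = "registration_error")
}

#' @export
print.registration_error <- function(x, ...) {
  cat("Registration error (E = T^-1 GT)\n")
  cat(sprintf("  translation: (%.1f, %.1f, %.1f) mm, norm %.1f mm\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$translation_norm))
  cat(sprintf("  rotation:    (%.1f, %.1f, %.1f) deg about x, y, z\n",
              x$rotation[1], x$rotation[2], x$rotation[3]))
  invisible(x)
}

#' Read and write labeled marker coordinate CSV files
#'
#' 2D files have columns `label,h,v` (one file per plane); 3D files have
#' columns `label,x,y,z`.
#'
#' @param path file path.
#' @param markers a [marker_set()] (3D write).
#' @return `read_markers_2d()`: a data frame; `read_markers_3d()`: a
#'   [marker_set()].
#' @export
read_markers_2d <- function(path) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "h", "v") %in% names(df)))
  df
}

#' @rdname read_markers_2d
#' @param frame frame tag for the markers read from a 3D file.
#' @export
read_markers_3d <- function(path, frame = "CT") {
  if (!file.exists(path)) stop("marker file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x", "y", "z") %in% names(df)))
  marker_set(cbind(df$x, df$y, df$z), df$label, frame)
}

#' @rdname read_markers_2d
#' @export
write_markers_3d <- function(markers, path) {
  stopifnot(inherits(markers, "marker_set"))
  df <- data.frame(label = markers$labels, x = markers$centers[, 1],
                   y = markers$centers[, 2], z = markers$centers[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
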