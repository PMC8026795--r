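#' Render a digitally reconstructed radiograph
#'
#' Casts the horizontal fan-beam rays of the slot-scanning geometry through
#' an attenuation volume placed at a rigid pose and integrates the linear
#' attenuation along each ray (monochromatic line integral, trilinear
#' interpolation, samples outside the volume contribute zero).  For row `v`
#' the emitter sits at height `z = z0 - lambda_z * v` on its source line;
#' the ray passes through the pixel's position on the virtual isocenter
#' detector.
#'
#' No exponential/flat-panel conversion is applied: the downstream
#' similarity (localized NCC) is invariant to monotone local rescaling, so
#' the raw line integral is compared directly.
#'
#' @param vol an `attenuation_volume` (see [hu_to_attenuation()]).
#' @param pose 4x4 rigid transform mapping volume (CT) coordinates into the
#'   world (EOS) frame.
#' @param g an [eos_geometry()].
#' @param plane `"frontal"` or `"lateral"`.
#' @param step ray sampling step (mm); default half the smallest voxel
#'   spacing.
#' @param rows,vcols optional 0-based pixel index subsets to render (a
#'   region of interest); defaults to the full image.
#' @return numeric matrix `length(rows)` x `length(vcols)` of line
#'   integrals (dimensionless).
#' @export
render_drr <- function(vol, pose, g, plane = c("frontal", "lateral"),
                       step = NULL, rows = NULL, vcols = NULL) {
  plane <- match.arg(plane)
  stopifnot(inherits(vol, "ct_volume"))
  if (!identical(vol$unit, "mu")) {
    stop("render_drr() expects an attenuation volume; see hu_to_attenuation()")
  }
  if (!is_rigid_transform(pose, tol = 1e-6)) stop("pose must be a rigid transform")
  if (is.null(step)) step <- min(vol$spacing) / 2
  if (step <= 0) stop("step must be > 0")
  if (is.null(rows)) rows <- 0:(g$n_rows - 1L)
  if (is.null(vcols)) vcols <- 0:(g$n_cols - 1L)
  tinv <- transform_invert(pose)
  f <- if (plane == "frontal") g$f_f else g$f_l
  pitch <- if (plane == "frontal") g$lambda_h_f else g$lambda_h_l
  pp <- if (plane == "frontal") g$principal_f else g$principal_l
  render_drr_cpp(as.numeric(vol$data), dim(vol$data), vol$spacing, vol$origin,
                 tinv, plane_index(plane), f, g$z0, g$lambda_z, pitch, pp,
                 as.integer(rows), as.integer(vcols), step)
}

#' A pair of biplanar radiographs tied to a geometry
#'
#' @param frontal,lateral 2D numeric matrices (rows x cols) matching the
#'   geometry's image dimensions.
#' @param geometry an [eos_geometry()].
#' @return an object of class `radiograph_pair`.
#' @export
radiograph_pair <- function(frontal, lateral, geometry) {
  stopifnot(inherits(geometry, "eos_geometry"),
            is.matrix(frontal), is.matrix(lateral))
  dims <- c(geometry$n_rows, geometry$n_cols)
  if (!all(dim(frontal) == dims) || !all(dim(lateral) == dims)) {
    stop("image dimensions must match the geometry (",
         dims[1], " x ", dims[2], ")")
  }
  structure(list(frontal = frontal, lateral = lateral, geometry = geometry),
            class = "radiograph_pair")
}

#' @export
print.radiograph_pair <- function(x, ...) {
  cat(sprintf("Biplanar radiograph pair, %d x %d px per plane\n",
              nrow(x$frontal), ncol(x$frontal)))
  invisible(x)
}
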