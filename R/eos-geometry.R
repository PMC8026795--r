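#' EOS-style biplanar slot-scanning geometry
#'
#' Models the imaging geometry of a calibrated biplanar slot-scanning
#' radiography system.  Two perpendicular horizontal fan beams (frontal and
#' lateral) scan the standing patient vertically, so the vertical image axis
#' maps to world height without magnification, while the horizontal axis is a
#' perspective projection.  The device rescales images to a virtual detector
#' through the isocenter, so a structure at isocenter depth appears at unit
#' magnification.
#'
#' World frame (right-handed): x to the patient's left, y posterior,
#' z superior.  The frontal source line sits at `y = -f_f`, the lateral
#' source line at `x = -f_l`; both emitters travel downwards along z.
#' Pixel coordinates are 0-based: column `h` (horizontal), row `v`
#' (vertical), with `v = 0` at emitter start height `z0`.
#'
#' @param f_f,f_l frontal/lateral source-to-isocenter distance (mm).
#' @param z0 initial emitter height (mm); the world height imaged at `v = 0`.
#' @param lambda_z vertical pixel pitch (mm/pixel), identical in both planes.
#' @param lambda_h_f,lambda_h_l horizontal pixel pitch (mm/pixel) at the
#'   isocenter-rescaled detector; default `lambda_z` (square pixels).
#' @param n_rows,n_cols image dimensions in pixels (both planes).
#' @param principal_f,principal_l horizontal principal pixel (column hit by
#'   the central ray); default the image-center column `(n_cols - 1) / 2`.
#' @return an object of class `eos_geometry`.
#' @examples
#' g <- eos_geometry()
#' project_point(c(0, 0, 100), g, "frontal")
#' @export
eos_geometry <- function(f_f = 918, f_l = 918, z0 = 477.5,
                         lambda_z = 0.179363,
                         lambda_h_f = lambda_z, lambda_h_l = lambda_z,
                         n_rows = 3000L, n_cols = 1500L,
                         principal_f = (n_cols - 1) / 2,
                         principal_l = (n_cols - 1) / 2) {
  g <- list(f_f = f_f, f_l = f_l, z0 = z0, lambda_z = lambda_z,
            lambda_h_f = lambda_h_f, lambda_h_l = lambda_h_l,
            n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            principal_f = principal_f, principal_l = principal_l)
  for (f in c("f_f", "f_l", "lambda_z", "lambda_h_f", "lambda_h_l")) {
    if (!is.numeric(g[[f]]) || length(g[[f]]) != 1 || !is.finite(g[[f]]) ||
        g[[f]] <= 0) {
      stop(sprintf("field '%s' must be a strictly positive number", f))
    }
  }
  if (!is.finite(g$z0)) stop("field 'z0' must be finite")
  if (g$n_rows < 1L || g$n_cols < 1L) {
    stop("image dimensions 'n_rows'/'n_cols' must be >= 1")
  }
  structure(g, class = "eos_geometry")
}

#' @export
print.eos_geometry <- function(x, ...) {
  cat("Biplanar slot-scan geometry\n")
  cat(sprintf("  source-isocenter: frontal %.1f mm, lateral %.1f mm\n", x$f_f, x$f_l))
  cat(sprintf("  emitter start height z0: %.3f mm, vertical pitch: %.6f mm/px\n",
              x$z0, x$lambda_z))
  cat(sprintf("  image: %d x %d px, horizontal pitch %.6f / %.6f mm/px\n",
              x$n_rows, x$n_cols, x$lambda_h_f, x$lambda_h_l))
  invisible(x)
}

plane_index <- function(plane) {
  plane <- match.arg(plane, c("frontal", "lateral"))
  if (plane == "frontal") 0L else 1L
}

#' Project 3D world points to pixel coordinates
#'
#' Forward model of the slot-scanning fan beam.  Vertical: `v = (z0 - Pz) /
#' lambda_z` (affine, no magnification).  Horizontal: perspective ratio of
#' the in-plane coordinates rescaled to the isocenter detector, e.g. frontal
#' `h = principal + f_f Px / ((f_f + Py) lambda_h_f)`.
#'
#' @param p length-3 point or n x 3 matrix (mm, world frame).
#' @param g an [eos_geometry()].
#' @param plane `"frontal"` or `"lateral"`.
#' @return a named vector `c(h, v)` or an n x 2 matrix with columns `h`, `v`.
#' @export
project_point <- function(p, g, plane = c("frontal", "lateral")) {
  plane <- match.arg(plane)
  vec <- is.null(dim(p))
  pm <- if (vec) matrix(p, 1, 3) else as.matrix(p)
  stopifnot(ncol(pm) == 3)
  if (plane == "frontal") {
    den <- g$f_f + pm[, 2]
    num <- g$f_f * pm[, 1]
    pitch <- g$lambda_h_f
    pp <- g$principal_f
  } else {
    den <- g$f_l + pm[, 1]
    num <- g$f_l * pm[, 2]
    pitch <- g$lambda_h_l
    pp <- g$principal_l
  }
  if (any(abs(den) < 1e-9)) stop("point at source plane: projection undefined")
  h <- pp + (num / den) / pitch
  v <- (g$z0 - pm[, 3]) / g$lambda_z
  out <- cbind(h = unname(h), v = unname(v))
  if (vec) c(h = as.numeric(out[1, 1]), v = as.numeric(out[1, 2])) else out
}

#' Triangulate a 3D point from its frontal and lateral projections
#'
#' Inverts the forward projection: the two horizontal perspective
#' constraints form a 2x2 linear system in `(Px, Py)`, and the vertical
#' world coordinate is recovered without magnification as
#' `Pz = z0 - lambda_z * (v_f + v_l) / 2`, averaging the two (ideally
#' identical) vertical readings.
#'
#' @param frontal,lateral pixel coordinates `c(h, v)` or n x 2 matrices.
#' @param g an [eos_geometry()].
#' @return a named vector `c(x, y, z)` or an n x 3 matrix (mm).
#' @export
triangulate_point <- function(frontal, lateral, g) {
  vec <- is.null(dim(frontal))
  fm <- if (vec) matrix(frontal, 1, 2) else as.matrix(frontal)
  lm <- if (is.null(dim(lateral))) matrix(lateral, 1, 2) else as.matrix(lateral)
  stopifnot(ncol(fm) == 2, ncol(lm) == 2, nrow(fm) == nrow(lm))
  a <- (fm[, 1] - g$principal_f) * g$lambda_h_f  # frontal horizontal offset, mm
  b <- (lm[, 1] - g$principal_l) * g$lambda_h_l  # lateral horizontal offset, mm
  # f_f Px - a Py = a f_f ;  -b Px + f_l Py = b f_l
  det2 <- g$f_f * g$f_l - a * b
  if (any(abs(det2) < 1e-6 * g$f_f * g$f_l)) {
    stop("rays parallel/ill-conditioned: triangulation system is singular")
  }
  px <- (a * g$f_f * g$f_l + a * g$f_l * b) / det2
  py <- (b * g$f_l * g$f_f + b * g$f_f * a) / det2
  pz <- g$z0 - g$lambda_z * (lm[, 2] + fm[, 2]) / 2
  out <- cbind(x = unname(px), y = unname(py), z = unname(pz))
  if (vec) c(x = as.numeric(out[1, 1]), y = as.numeric(out[1, 2]), z = as.numeric(out[1, 3])) else out
}

#' Build a validated geometry from a calibration parameter set
#'
#' Accepts a flat named list (e.g. parsed from a YAML/JSON calibration file,
#' or assembled from DICOM tags of the radiographs).  Missing keys fall back
#' to the bundled defaults of [eos_geometry()]; supplied values are
#' validated and errors name the offending field.
#'
#' The expected DICOM provenance of each field, for ingestion from the
#' device's image headers, is: `f_f`/`f_l` from Distance Source to Isocenter
#' (0018,9402-group private equivalents on EOS exports), `lambda_z` and the
#' horizontal pitches from Imager Pixel Spacing (0018,1164), `n_rows`/
#' `n_cols` from Rows/Columns (0028,0010/0011), and `z0` from the table/
#' emitter start position private tag.  Calibration files produced by
#' [write_eos_geometry()] round-trip bit-exactly.
#'
#' @param params named list of calibration values.
#' @return an [eos_geometry()].
#' @export
geometry_from_parameters <- function(params = list()) {
  known <- c("f_f", "f_l", "z0", "lambda_z", "lambda_h_f", "lambda_h_l",
             "n_rows", "n_cols", "principal_f", "principal_l")
  bad <- setdiff(names(params), known)
  if (length(bad)) stop("unknown calibration field(s): ", paste(bad, collapse = ", "))
  do.call(eos_geometry, params)
}

#' Read and write geometry calibration files
#'
#' Flat YAML with one key per [eos_geometry()] field.
#'
#' @param g an [eos_geometry()].
#' @param path file path.
#' @return `read_eos_geometry()` returns an [eos_geometry()].
#' @export
write_eos_geometry <- function(g, path) {
  yaml::write_yaml(unclass(g), path, precision = 15)
  invisible(path)
}

#' @rdname write_eos_geometry
#' @export
read_eos_geometry <- function(path) {
  if (!file.exists(path)) stop("geometry file not found: ", path)
  geometry_from_parameters(yaml::read_yaml(path))
}
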