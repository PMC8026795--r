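#' 3D scalar volumes
#'
#' A `ct_volume` is a 3D array of Hounsfield units on a regular axis-aligned
#' lattice with voxel spacing and world origin in mm (the origin is the
#' world position of the center of voxel `[1, 1, 1]`; axis orientation is
#' identity, i.e. array axes map directly to world x/y/z).  An
#' `attenuation_volume` shares the lattice but holds linear attenuation
#' coefficients (1/mm).
#'
#' @param data 3D numeric array.
#' @param spacing length-3 voxel spacing (mm), strictly positive.
#' @param origin length-3 world position of the first voxel center (mm).
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            length(spacing) == 3, length(origin) == 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be strictly positive")
  }
  if (any(!is.finite(data))) stop("volume intensities must be finite")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), unit = "HU"),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("%s volume %d x %d x %d, spacing (%.3g, %.3g, %.3g) mm\n",
              x$unit, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.1f, %.1f, %.1f) mm, range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Convert Hounsfield units to linear attenuation
#'
#' Monochromatic single-material model: `mu = max(0, (HU + 1000) / 1000) *
#' mu_water`, clipped at zero so air and sub-air values do not attenuate.
#' The similarity metric used downstream (localized NCC) is invariant to
#' monotone local rescaling, so an absolute attenuation calibration is not
#' required.
#'
#' @param v a [ct_volume()].
#' @param mu_water attenuation of water (1/mm); default 0.02 (about 60 keV).
#' @return an `attenuation_volume` on the same lattice.
#' @export
hu_to_attenuation <- function(v, mu_water = 0.02) {
  stopifnot(inherits(v, "ct_volume"))
  if (identical(v$unit, "mu")) return(v)
  mu <- array(pmax(0, (v$data + 1000) / 1000) * mu_water, dim = dim(v$data))
  out <- v
  out$data <- mu
  out$unit <- "mu"
  class(out) <- c("attenuation_volume", "ct_volume")
  out
}

#' Crop a volume to a world-coordinate box
#'
#' @param v a [ct_volume()].
#' @param xlim,ylim,zlim length-2 world ranges (mm), inclusive.
#' @return a volume of the same class restricted to voxels whose centers lie
#'   inside the box.
#' @export
crop_volume <- function(v, xlim, ylim, zlim) {
  stopifnot(inherits(v, "ct_volume"))
  d <- dim(v$data)
  idx <- lapply(1:3, function(k) {
    w <- v$origin[k] + (seq_len(d[k]) - 1) * v$spacing[k]
    lim <- list(xlim, ylim, zlim)[[k]]
    which(w >= lim[1] & w <= lim[2])
  })
  if (any(lengths(idx) == 0)) stop("crop box contains no voxel centers")
  out <- v
  out$data <- v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out$origin <- v$origin + (vapply(idx, min, 1L) - 1) * v$spacing
  out
}

#' Read and write volumes as NIfTI
#'
#' @param v a [ct_volume()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_ct_volume()` returns a [ct_volume()].
#' @export
write_ct_volume <- function(v, path) {
  stopifnot(inherits(v, "ct_volume"))
  img <- RNifti::asNifti(v$data, pixdim = v$spacing)
  # encode the world origin in the sform (RAS-agnostic plain scaling)
  m <- diag(4)
  diag(m)[1:3] <- v$spacing
  m[1:3, 4] <- v$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_ct_volume
#' @export
read_ct_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  m <- RNifti::xform(img)
  ct_volume(array(as.numeric(img), dim = dim(img)),
            spacing = abs(diag(m)[1:3]), origin = m[1:3, 4])
}

# world coordinates of voxel centers along one axis
axis_coords <- function(v, k) {
  v$origin[k] + (seq_len(dim(v$data)[k]) - 1) * v$spacing[k]
}

# intensity-weighted centroid (mm); used as default rotation center
volume_centroid <- function(v) {
  w <- pmax(v$data, 0)
  s <- sum(w)
  if (s <= 0) {
    return(v$origin + (dim(v$data) - 1) * v$spacing / 2)
  }
  m1 <- apply(w, 1, sum)
  m2 <- apply(w, 2, sum)
  m3 <- apply(w, 3, sum)
  c(sum(m1 * axis_coords(v, 1)), sum(m2 * axis_coords(v, 2)),
    sum(m3 * axis_coords(v, 3))) / s
}
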