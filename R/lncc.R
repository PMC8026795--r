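#' Variance-weighted localized normalized cross correlation
#'
#' At every pixel inside the region of interest, the normalized cross
#' correlation of the `patch_size` x `patch_size` neighborhoods of the two
#' images is computed (neighborhoods are clipped at image borders).  The
#' patch NCCs are aggregated into one score by a weighted mean, with weights
#' proportional to the local variance of `image_b` (the fixed radiograph),
#' so featureless regions do not dilute the score.  Patches in which either
#' image has (numerically) zero variance contribute weight zero, which also
#' makes constant images well defined.  The score lies in `[-1, 1]`; 1 means
#' perfect local correlation everywhere that the radiograph has structure.
#'
#' @param image_a,image_b numeric matrices of identical dimensions
#'   (`image_a`: the rendered DRR; `image_b`: the measured radiograph).
#' @param mask an [roi_rect()] (0-based, half-open) or `NULL` for the full
#'   image.
#' @param patch_size odd integer >= 3; default 9.
#' @return a single similarity score in `[-1, 1]`.
#' @export
lncc_similarity <- function(image_a, image_b, mask = NULL, patch_size = 9L) {
  stopifnot(is.matrix(image_a), is.matrix(image_b),
            all(dim(image_a) == dim(image_b)))
  patch_size <- as.integer(patch_size)
  if (patch_size < 3L || patch_size %% 2L == 0L) {
    stop("patch_size must be odd and >= 3")
  }
  r <- (patch_size - 1L) %/% 2L
  n <- box_filter(matrix(1, nrow(image_a), ncol(image_a)), r)
  sa <- box_filter(image_a, r)
  sb <- box_filter(image_b, r)
  saa <- box_filter(image_a * image_a, r)
  sbb <- box_filter(image_b * image_b, r)
  sab <- box_filter(image_a * image_b, r)
  var_a <- saa / n - (sa / n)^2
  var_b <- sbb / n - (sb / n)^2
  cov_ab <- sab / n - (sa / n) * (sb / n)
  eps <- 1e-12 * max(1, max(abs(image_a)), max(abs(image_b)))^2
  ok <- var_a > eps & var_b > eps
  ncc <- matrix(0, nrow(image_a), ncol(image_a))
  ncc[ok] <- cov_ab[ok] / sqrt(var_a[ok] * var_b[ok])
  w <- ifelse(ok, pmax(var_b, 0), 0)

  if (!is.null(mask)) {
    sel <- roi_index(mask, dim(image_a))
    if (length(sel$rows) == 0 || length(sel$cols) == 0) {
      stop("mask is empty after intersection with the image")
    }
    ncc <- ncc[sel$rows, sel$cols, drop = FALSE]
    w <- w[sel$rows, sel$cols, drop = FALSE]
  }
  sw <- sum(w)
  if (sw <= 0) return(0)
  sum(w * ncc) / sw
}

# sliding-window sum with border clipping, via 2D cumulative sums
box_filter <- function(m, r) {
  nr <- nrow(m)
  nc <- ncol(m)
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed cumulative table
  cs <- t(cs)
  # pad with a zero row/col so inclusive prefix lookups are uniform
  z <- matrix(0, nr + 1, nc + 1)
  z[-1, -1] <- cs
  i1 <- pmax(seq_len(nr) - r, 1L)
  i2 <- pmin(seq_len(nr) + r, nr)
  j1 <- pmax(seq_len(nc) - r, 1L)
  j2 <- pmin(seq_len(nc) + r, nc)
  z[i2 + 1, j2 + 1, drop = FALSE] - z[i1, j2 + 1, drop = FALSE] -
    z[i2 + 1, j1, drop = FALSE] + z[i1, j1, drop = FALSE]
}

#' Rectangular region of interest in pixel coordinates
#'
#' Axis-aligned rectangle in 0-based, half-open pixel coordinates:
#' rows `[r0, r1)`, columns `[c0, c1)` (matching the 0-based `v`/`h`
#' convention of [project_point()]).
#'
#' @param r0,c0,r1,c1 rectangle bounds (0-based, half-open).
#' @return an object of class `roi_rect`.
#' @export
roi_rect <- function(r0, c0, r1, c1) {
  stopifnot(is.finite(c(r0, c0, r1, c1)), r1 > r0, c1 > c0)
  structure(list(r0 = r0, c0 = c0, r1 = r1, c1 = c1), class = "roi_rect")
}

# 1-based index vectors of the ROI clipped to an image of dims `d`
roi_index <- function(mask, d) {
  stopifnot(inherits(mask, "roi_rect"))
  clip <- function(a, b, n) {
    a <- max(0, a)
    b <- min(n, b)
    if (b <= a) integer(0) else seq.int(a, b - 1)
  }
  list(rows = clip(mask$r0, mask$r1, d[1]) + 1L,
       cols = clip(mask$c0, mask$c1, d[2]) + 1L)
}
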