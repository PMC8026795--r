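#' Read and write radiograph images
#'
#' Images are stored as 32-bit float TIFF normalized to `[0, 1]`, with the
#' scale factor kept in a JSON sidecar (`<path>.json`) so absolute line-
#' integral values round-trip to float precision.
#'
#' @param img numeric matrix.
#' @param path TIFF file path.
#' @return `read_radiograph()` returns a numeric matrix.
#' @export
write_radiograph <- function(img, path) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  mx <- max(img, 1e-30)
  tiff::writeTIFF(pmax(img, 0) / mx, path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale = mx), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_radiograph
#' @export
read_radiograph <- function(path) {
  if (!file.exists(path)) stop("radiograph file not found: ", path)
  img <- tiff::readTIFF(path)
  side <- paste0(path, ".json")
  scale <- if (file.exists(side)) jsonlite::read_json(side)$scale else 1
  img * scale
}

#' Read and write 4x4 rigid transforms
#'
#' Text format: a comment line stating the frame direction (CT to world)
#' followed by four whitespace-delimited rows.  A `.json` path stores the
#' matrix as nested arrays.
#'
#' @param transform 4x4 rigid transform.
#' @param path file path (`.txt` or `.json`).
#' @return `read_transform()` returns a 4x4 matrix.
#' @export
write_transform <- function(transform, path) {
  stopifnot(is_rigid_transform(transform, tol = 1e-6))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(frame = "CT -> EOS world",
                              matrix = unclass(transform)),
                         path, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# rigid transform, CT -> EOS world frame", con)
    writeLines(apply(transform, 1, function(r) paste(sprintf("%.17g", r),
                                                     collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("transform file not found: ", path)
  m <- if (grepl("\\.json$", path)) {
    do.call(rbind, lapply(jsonlite::read_json(path)$matrix, unlist))
  } else {
    lines <- grep("^\\s*#", readLines(path), value = TRUE, invert = TRUE)
    lines <- lines[nzchar(trimws(lines))]
    do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  }
  stopifnot(all(dim(m) == c(4, 4)))
  orthonormalize_transform(m)
}

#' Read and write registration annotation files
#'
#' JSON schema, one object per bone:
#' `{"bone": "femur", "arrows": {"frontal": [[h,v],[h,v]], "lateral":
#' [...], "ct": [[x,y,z],[x,y,z]]}, "masks": {"frontal": [r0,c0,r1,c1],
#' "lateral": [...]}}`.
#'
#' @param annotations named list (per bone) of lists with elements `arrow`
#'   (an [arrow_annotation()]) and `masks` (per-plane [roi_rect()]).
#' @param path JSON file path.
#' @return `read_annotations()` returns the named per-bone list.
#' @export
write_annotations <- function(annotations, path) {
  objs <- lapply(names(annotations), function(b) {
    a <- annotations[[b]]$arrow
    m <- annotations[[b]]$masks
    list(bone = jsonlite::unbox(b),
         arrows = list(
           frontal = list(unname(a$frontal_start), unname(a$frontal_end)),
           lateral = list(unname(a$lateral_start), unname(a$lateral_end)),
           ct = list(unname(a$ct_start), unname(a$ct_end))),
         masks = lapply(m, function(r) c(r$r0, r$c0, r$r1, r$c1)))
  })
  jsonlite::write_json(objs, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  objs <- jsonlite::read_json(path)
  out <- list()
  for (o in objs) {
    o$bone <- unlist(o$bone)
    arr <- lapply(o$arrows, function(x) lapply(x, function(p) unlist(p)))
    masks <- lapply(o$masks, function(r) {
      r <- unlist(r)
      roi_rect(r[1], r[2], r[3], r[4])
    })
    out[[o$bone]] <- list(
      arrow = arrow_annotation(arr$frontal[[1]], arr$frontal[[2]],
                               arr$lateral[[1]], arr$lateral[[2]],
                               arr$ct[[1]], arr$ct[[2]]),
      masks = masks)
  }
  out
}

#' Read and write measurement landmark files
#'
#' JSON with one key per landmark set (`femoral_head_points`, `eminences`,
#' `plateau_points`, `patella_points`, optional `epicondyles`), each an
#' array of `[x, y, z]` points in mm.
#'
#' @param landmarks named list of point matrices.
#' @param path JSON file path.
#' @return `read_landmarks()` returns a named list of matrices.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(lapply(landmarks, function(m) {
    lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  }), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  lapply(jsonlite::read_json(path), function(x) {
    do.call(rbind, lapply(x, unlist))
  })
}
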