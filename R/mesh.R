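#' Triangular bone surface meshes
#'
#' A `bone_mesh` holds vertices (mm), 1-based triangle indices and an
#' anatomical segment label.  Meshes need not be closed surfaces; degenerate
#' (zero-area) triangles are rejected.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param label segment label, one of femur, tibia, fibula, patella, talus.
#' @return an object of class `bone_mesh`.
#' @export
bone_mesh <- function(vertices, faces,
                      label = c("femur", "tibia", "fibula", "patella", "talus")) {
  label <- match.arg(label)
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, nrow(vertices) >= 4, all(is.finite(vertices)))
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range")
  }
  if (any(triangle_areas(vertices, faces) <= 0)) {
    stop("mesh contains degenerate (zero-area) triangles")
  }
  structure(list(vertices = vertices, faces = faces, label = label),
            class = "bone_mesh")
}

triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  u <- vertices[faces[, 2], , drop = FALSE] - a
  v <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' @export
print.bone_mesh <- function(x, ...) {
  cat(sprintf("%s mesh: %d vertices, %d triangles\n",
              x$label, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Rigidly transform a mesh
#'
#' Maps every vertex by the 4x4 transform; topology and the segment label
#' are unchanged.  Used to move bone models from the supine CT frame into
#' the registered weight-bearing pose.
#'
#' @param mesh a [bone_mesh()].
#' @param transform 4x4 rigid transform.
#' @return the transformed [bone_mesh()].
#' @export
transform_mesh <- function(mesh, transform) {
  stopifnot(inherits(mesh, "bone_mesh"), is_rigid_transform(transform, tol = 1e-6))
  mesh$vertices <- transform_points(transform, mesh$vertices)
  mesh
}

#' Read and write meshes as ASCII STL
#'
#' Minimal stereolithography I/O.  STL stores independent triangles, so
#' `read_stl()` merges exactly coincident vertices to rebuild shared
#' topology.
#'
#' @param mesh a [bone_mesh()].
#' @param path file path.
#' @param label segment label to assign on read.
#' @return `read_stl()` returns a [bone_mesh()].
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "bone_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - a
  w <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-30)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$label), con)
  tri <- character(7 * nrow(f))
  for (i in seq_len(nrow(f))) {
    p <- v[f[i, ], , drop = FALSE]
    tri[7 * i - 6] <- sprintf("facet normal %.10g %.10g %.10g", n[i, 1], n[i, 2], n[i, 3])
    tri[7 * i - 5] <- "  outer loop"
    tri[7 * i - 4] <- sprintf("    vertex %.10g %.10g %.10g", p[1, 1], p[1, 2], p[1, 3])
    tri[7 * i - 3] <- sprintf("    vertex %.10g %.10g %.10g", p[2, 1], p[2, 2], p[2, 3])
    tri[7 * i - 2] <- sprintf("    vertex %.10g %.10g %.10g", p[3, 1], p[3, 2], p[3, 3])
    tri[7 * i - 1] <- "  endloop"
    tri[7 * i] <- "endfacet"
  }
  writeLines(tri, con)
  writeLines(sprintf("endsolid %s", mesh$label), con)
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path, label = "femur") {
  if (!file.exists(path)) stop("STL file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0) {
    stop("not a valid ASCII STL file: ", path)
  }
  nums <- vapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]),
                 numeric(3))
  verts <- t(nums)
  key <- apply(round(verts, 9), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  uverts <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  bone_mesh(uverts, faces, label)
}
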