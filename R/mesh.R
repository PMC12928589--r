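#' Triangle mesh with ordered vertices
#'
#' A `tri_mesh` stores an ordered vertex list (millimetres) and triangle
#' faces. Vertex order carries anatomical correspondence: two meshes are
#' *corresponded* when they have the same vertex count and index `i` refers
#' to the same anatomical point in both. All registration and deviation
#' machinery in this package relies on that correspondence, never on
#' nearest-neighbour search.
#'
#' @param vertices numeric matrix, one row per vertex, three columns (mm).
#' @param faces integer matrix, one row per triangle, three vertex indices
#'   (1-based). May have zero rows for point-set use.
#' @param label free-text label, e.g. `"CA1"` or `"OB3"`.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces = matrix(integer(0), 0, 3), label = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L)
    stop("vertices must be an n x 3 matrix")
  if (nrow(vertices) < 3L)
    stop("a mesh needs at least 3 vertices")
  if (!all(is.finite(vertices)))
    stop("vertex coordinates must be finite")
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L && nrow(faces) > 0L)
    stop("faces must be an m x 3 index matrix")
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (.collinear(vertices))
    stop("mesh vertices are collinear; geometry is degenerate")
  structure(list(vertices = vertices, faces = faces,
                 label = as.character(label)[1]),
            class = "tri_mesh")
}

.collinear <- function(v, tol = 1e-12) {
  c0 <- colMeans(v)
  s <- svd(sweep(v, 2, c0), nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], 1)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh '%s': %d vertices, %d faces\n",
              x$label, nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [mm]: x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Vertex centroid of a mesh
#'
#' @param mesh a [tri_mesh()].
#' @return numeric length-3 centroid (mm).
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' Check that two meshes are corresponded
#'
#' @param a,b [tri_mesh()] objects.
#' @return `TRUE` invisibly; errors if vertex counts differ.
#' @export
stopifnot_corresponded <- function(a, b) {
  if (nrow(a$vertices) != nrow(b$vertices))
    stop(sprintf("meshes '%s' and '%s' are not corresponded: %d vs %d vertices",
                 a$label, b$label, nrow(a$vertices), nrow(b$vertices)))
  invisible(TRUE)
}

#' Apply a rigid transform to a mesh
#'
#' Vertex order and faces are preserved, so correspondence survives any
#' number of pose changes.
#'
#' @param mesh a [tri_mesh()].
#' @param transform a [rigid_transform()].
#' @param label optional new label; defaults to the input label.
#' @return the transformed [tri_mesh()].
#' @export
apply_transform <- function(mesh, transform, label = mesh$label) {
  v <- transform_points(transform, mesh$vertices)
  structure(list(vertices = v, faces = mesh$faces,
                 label = as.character(label)[1]),
            class = "tri_mesh")
}
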