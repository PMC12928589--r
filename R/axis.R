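#' Rotation-axis line
#'
#' A rotation axis (instantaneous centre of rotation) represented as a
#' start/end point pair in mm. Canonical axes — produced by
#' [canonicalize_axis()] — have endpoints exactly 200 mm apart, centred on
#' the point of the line closest to the reference mesh's vertex centroid,
#' with a deterministic direction sign. Axis comparison ([compare_axes()])
#' is only defined between axes canonicalized against the same reference
#' mesh, because the same geometric line admits many coordinate pairs.
#'
#' @param start,end length-3 points (mm); must be distinct.
#' @param source provenance tag: `"szeged"`, `"modjaw"`, `"truth"` or
#'   `"perturbed"`.
#' @param label free-text label.
#' @return An object of class `axis_line` with fields `start`, `end`,
#'   `direction` (unit vector start -> end), `source`, `label`, and
#'   canonicalization metadata `canonical` / `reference`.
#' @export
axis_line <- function(start, end, source = "truth", label = "") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 3L || length(end) != 3L ||
      !all(is.finite(c(start, end))))
    stop("axis endpoints must be finite length-3 points")
  d <- end - start
  len <- sqrt(sum(d^2))
  if (len < 1e-12)
    stop("degenerate axis: start and end coincide")
  structure(list(start = start, end = end, direction = d / len,
                 source = as.character(source)[1],
                 label = as.character(label)[1],
                 canonical = FALSE, reference = NA_character_),
            class = "axis_line")
}

#' @export
print.axis_line <- function(x, ...) {
  cat(sprintf("axis_line '%s' [%s]%s\n  start (%.3f, %.3f, %.3f)  end (%.3f, %.3f, %.3f) mm\n",
              x$label, x$source,
              if (isTRUE(x$canonical)) sprintf(" canonical vs '%s'", x$reference) else "",
              x$start[1], x$start[2], x$start[3], x$end[1], x$end[2], x$end[3]))
  invisible(x)
}

# Deterministic sign rule: largest-magnitude component of the direction is
# positive; ties broken in x -> y -> z order.
.orient_direction <- function(u) {
  k <- which(abs(u) == max(abs(u)))[1]
  if (u[k] < 0) -u else u
}

#' Canonicalize an axis against a reference mesh
#'
#' Re-parameterizes a line so its endpoints sit 100 mm either side of the
#' point on the line closest to the reference mesh's vertex centroid
#' (endpoint separation exactly 200 mm). The direction sign is fixed by a
#' deterministic rule (largest-magnitude component positive, ties broken
#' x, y, z) so that replicate axes of one jaw co-orient without manual
#' pairing.
#'
#' @param axis an [axis_line()], or a list with `point` and `direction`.
#' @param reference_mesh the [tri_mesh()] whose centroid anchors the
#'   parameterization (typically the closed/fixed scan).
#' @param half_length half the endpoint separation in mm (default 100).
#' @return a canonical [axis_line()].
#' @export
canonicalize_axis <- function(axis, reference_mesh, half_length = 100) {
  if (inherits(axis, "axis_line")) {
    p <- axis$start; u <- axis$direction
    src <- axis$source; lab <- axis$label
  } else {
    p <- as.numeric(axis$point); u <- as.numeric(axis$direction)
    src <- if (!is.null(axis$source)) axis$source else "truth"
    lab <- if (!is.null(axis$label)) axis$label else ""
  }
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) stop("axis direction must be nonzero")
  u <- .orient_direction(u / nu)
  c0 <- mesh_centroid(reference_mesh)
  mid <- p + sum((c0 - p) * u) * u
  out <- axis_line(mid - half_length * u, mid + half_length * u,
                   source = src, label = lab)
  out$canonical <- TRUE
  out$reference <- reference_mesh$label
  out
}

#' Positional and angular discrepancy between two axes
#'
#' `d_start` and `d_end` are the distances between corresponding canonical
#' endpoints after co-orienting the two directions (the second axis is
#' flipped end-for-end if the directions oppose); `d_axis` is their mean —
#' the standard axis-discrepancy summary for the 200 mm parameterization.
#' `angular_deviation` is the acute angle between the lines in degrees.
#' Both axes must be canonicalized against the same reference mesh.
#'
#' @param a,b canonical [axis_line()] objects sharing a reference mesh.
#' @return An object of class `axis_comparison`: `d_start`, `d_end`,
#'   `d_axis`, `angular_deviation`.
#' @export
compare_axes <- function(a, b) {
  if (!isTRUE(a$canonical) || !isTRUE(b$canonical))
    stop("compare_axes needs canonicalized axes; see canonicalize_axis()")
  if (!identical(a$reference, b$reference))
    stop(sprintf("axes canonicalized against different reference meshes ('%s' vs '%s')",
                 a$reference, b$reference))
  bs <- b$start; be <- b$end
  flipped <- sum(a$direction * b$direction) < 0
  if (flipped) { tmp <- bs; bs <- be; be <- tmp }
  d_start <- sqrt(sum((a$start - bs)^2))
  d_end <- sqrt(sum((a$end - be)^2))
  if (flipped) {
    # a flip pairs a's start with b's end and vice versa; label the smaller
    # distance d_start so the comparison is symmetric in its arguments
    d <- sort(c(d_start, d_end)); d_start <- d[1]; d_end <- d[2]
  }
  cosang <- min(1, abs(sum(a$direction * b$direction)))
  structure(list(d_start = d_start, d_end = d_end,
                 d_axis = (d_start + d_end) / 2,
                 angular_deviation = acos(cosang) * 180 / pi),
            class = "axis_comparison")
}

#' @export
print.axis_comparison <- function(x, ...) {
  cat(sprintf("axis_comparison: d_axis %.4f mm (start %.4f, end %.4f), angle %.4f deg\n",
              x$d_axis, x$d_start, x$d_end, x$angular_deviation))
  invisible(x)
}

#' Extract the axis line from an exported cylinder mesh
#'
#' Motion-tracking software exports computed axes as thin cylinder meshes;
#' the line is the segment joining the centres of the two end-cap vertex
#' rings. This routine identifies the two extreme planar rings along the
#' cylinder's principal direction and returns the segment through their
#' centroids, replacing the manual vertex-selection procedure.
#'
#' @param cylinder_mesh a [tri_mesh()] of a (possibly open-ended) cylinder.
#' @param tol ring coplanarity tolerance as a fraction of the cylinder
#'   length (default 1e-6).
#' @return a (pre-canonical) [axis_line()] with `source = "modjaw"`.
#' @export
axis_from_cylinder <- function(cylinder_mesh, tol = 1e-6) {
  V <- cylinder_mesh$vertices
  c0 <- colMeans(V)
  Vc <- sweep(V, 2, c0)
  u <- .orient_direction(svd(Vc, nu = 0, nv = 3)$v[, 1])
  h <- as.numeric(Vc %*% u)
  span <- max(h) - min(h)
  if (span < 1e-9)
    stop("not a cylinder export: no extent along a principal direction")
  lo <- which(h < min(h) + tol * span)
  hi <- which(h > max(h) - tol * span)
  if (length(lo) < 3L || length(hi) < 3L)
    stop("not a cylinder export: cannot identify two parallel end rings")
  # each end ring must be planar (flat to tolerance along the axis)
  if (diff(range(h[lo])) > 10 * tol * span || diff(range(h[hi])) > 10 * tol * span)
    stop("not a cylinder export: end rings are not planar")
  axis_line(colMeans(V[lo, , drop = FALSE]),
            colMeans(V[hi, , drop = FALSE]),
            source = "modjaw", label = cylinder_mesh$label)
}

#' Mode coordinates of one axis relative to another
#'
#' Decomposes the deviation of a fitted canonical axis from a reference
#' canonical axis into perpendicular-offset and tilt coordinates (mm on
#' the `d_axis` endpoint scale) expressed in an orthonormal frame
#' `(e1, e2)` normal to the reference direction, plus the (gauge) axial
#' component. A pure parallel offset of `c` mm along `e1` gives
#' `offset_1 = c`; a pure tilt about the midpoint moving each endpoint by
#' `c` mm toward `e1` gives `tilt_1 = c`. Used by the scatter-direction
#' analysis to project replicate fitted axes onto the sensitivity modes of
#' [error_direction_scan()].
#'
#' @param fitted,reference canonical [axis_line()] objects sharing a
#'   reference mesh.
#' @param frame optional 3x2 basis of the normal plane (columns `e1`,
#'   `e2`); defaults to a deterministic frame of the reference direction.
#' @return named numeric vector `offset_1`, `offset_2`, `tilt_1`,
#'   `tilt_2`, `axial` (mm).
#' @export
axis_mode_coordinates <- function(fitted, reference, frame = NULL) {
  if (!identical(fitted$reference, reference$reference))
    stop("axes canonicalized against different reference meshes")
  fs <- fitted$start; fe <- fitted$end
  if (sum(fitted$direction * reference$direction) < 0) { tmp <- fs; fs <- fe; fe <- tmp }
  ds <- fs - reference$start; de <- fe - reference$end
  off <- (ds + de) / 2
  tilt <- (de - ds) / 2
  if (is.null(frame)) frame <- .normal_frame(reference$direction)
  c(offset_1 = sum(off * frame[, 1]), offset_2 = sum(off * frame[, 2]),
    tilt_1 = sum(tilt * frame[, 1]), tilt_2 = sum(tilt * frame[, 2]),
    axial = sum(off * reference$direction))
}

# Orthonormal basis (e1, e2) of the plane normal to unit vector u.
.normal_frame <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  cbind(e1, e2)
}
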