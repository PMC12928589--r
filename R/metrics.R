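#' Corresponded-mesh deviation report
#'
#' Index-paired Euclidean distances between two poses of the same mesh.
#' `rms_error` is the root mean square over vertex pairs, `max_error` the
#' maximum. These are the two bases of every propagation ratio in the
#' package: rms is appropriate for derived parameters, the maximum is the
#' stricter, clinically oriented reading (worst occlusal point).
#'
#' @param a,b corresponded [tri_mesh()] objects.
#' @return An object of class `deviation_report`: `per_vertex` (mm),
#'   `rms_error`, `max_error`, `n_vertices`.
#' @export
deviation <- function(a, b) {
  stopifnot_corresponded(a, b)
  d <- sqrt(rowSums((a$vertices - b$vertices)^2))
  structure(list(per_vertex = d,
                 rms_error = sqrt(mean(d^2)),
                 max_error = max(d),
                 n_vertices = length(d)),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("deviation over %d vertex pairs: rms %.5f mm, max %.5f mm\n",
              x$n_vertices, x$rms_error, x$max_error))
  invisible(x)
}

# Half-up decimal rounding (spreadsheet convention), used for reported
# percentages; base round() is half-to-even.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Tally deviation values against a clinical threshold
#'
#' Counts values below/above a limit (default the 0.1 mm occlusal accuracy
#' benchmark). The comparison is strict: values exactly equal to the limit
#' count as above. The percentage below is reported to one decimal,
#' half-up.
#'
#' @param values numeric vector of deviations (mm).
#' @param limit threshold in mm (default 0.1).
#' @return An object of class `tally_report`: `n_above`, `n_below`,
#'   `pct_below`, `limit`.
#' @export
threshold_tally <- function(values, limit = 0.1) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("threshold_tally needs a non-empty vector")
  n_below <- sum(values < limit)
  structure(list(n_above = length(values) - n_below,
                 n_below = n_below,
                 pct_below = round_half_up(100 * n_below / length(values), 1),
                 limit = limit),
            class = "tally_report")
}

#' @export
print.tally_report <- function(x, ...) {
  cat(sprintf("threshold %.3g mm: %d below (%.1f%%), %d above\n",
              x$limit, x$n_below, x$pct_below, x$n_above))
  invisible(x)
}

#' EcD ratio: axis displacement per unit registration error
#'
#' Error-caused Displacement. When two axis fits share one fixed mesh and
#' differ only in the pose of their moving (open) mesh, the positional
#' discrepancy between the fitted axes divided by the mesh-level error
#' between the two moving poses gives the millimetres of axis shift per
#' millimetre of registration error.
#'
#' @param axes an `axis_comparison` between the two fitted axes.
#' @param scan_error a `deviation_report` between the two moving meshes.
#' @param basis `"rms"` or `"max"` error basis.
#' @return An object of class `ratio_record` with `kind = "EcD"`.
#' @export
ecd_ratio <- function(axes, scan_error, basis = c("rms", "max")) {
  basis <- match.arg(basis)
  denom <- if (basis == "rms") scan_error$rms_error else scan_error$max_error
  if (axes$d_axis == 0) {
    ratio <- 0
  } else if (denom <= 0) {
    stop("undefined EcD ratio: zero registration error with nonzero d_axis")
  } else ratio <- axes$d_axis / denom
  structure(list(kind = "EcD", numerator_d_axis = axes$d_axis,
                 denominator_error = denom, ratio = ratio,
                 error_basis = basis),
            class = "ratio_record")
}

#' AEcFE ratio: axis discrepancy per unit final positioning error
#'
#' Axis Error caused Final Error. After rotating the same mesh by the same
#' angle about two different axes, the axis discrepancy divided by the
#' mesh-level error between the two final poses measures error *tolerance*:
#' large values mean the articulation forgives axis misplacement. Axes
#' differing only by a slide along their common line produce zero final
#' error; that case is reported as an infinite ratio (sentinel), not an
#' error.
#'
#' @param axes an `axis_comparison` between the two axes.
#' @param final_error a `deviation_report` between the two rotated poses.
#' @param basis `"rms"` or `"max"` error basis.
#' @return An object of class `ratio_record` with `kind = "AEcFE"`.
#' @export
aecfe_ratio <- function(axes, final_error, basis = c("rms", "max")) {
  basis <- match.arg(basis)
  denom <- if (basis == "rms") final_error$rms_error else final_error$max_error
  ratio <- if (axes$d_axis == 0) 0
           else if (denom <= 0) Inf  # axial-slide case: unlimited tolerance
           else axes$d_axis / denom
  structure(list(kind = "AEcFE", numerator_d_axis = axes$d_axis,
                 denominator_error = denom, ratio = ratio,
                 error_basis = basis),
            class = "ratio_record")
}

#' @export
print.ratio_record <- function(x, ...) {
  cat(sprintf("%s (%s basis): %.4g  (d_axis %.4f mm / error %.5f mm)\n",
              x$kind, x$error_basis, x$ratio, x$numerator_d_axis,
              x$denominator_error))
  invisible(x)
}

#' Mean and standard deviation summary
#'
#' Sample (n-1) standard deviation, the spreadsheet convention used in all
#' AVG/SD table rows; `sd` is `NA` for a single value.
#'
#' @param values numeric vector, length >= 1.
#' @return list with `mean`, `sd`, `n`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("summarize_values needs at least one value")
  list(mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
       n = length(values))
}
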