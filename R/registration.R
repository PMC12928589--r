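#' Control options for the rotation-axis fit
#'
#' @param min_angle smallest fittable rotation in degrees; below it the
#'   instantaneous centre of rotation is numerically meaningless and the
#'   fit fails loudly (default 0.05).
#' @param max_iter maximum optimizer iterations (default 200).
#' @param ptol parameter-step convergence tolerance (default 1e-12).
#' @param ftol relative residual-reduction tolerance (default 1e-14).
#' @return list of options for [fit_rotation_axis()].
#' @export
axis_fit_control <- function(min_angle = 0.05, max_iter = 200,
                             ptol = 1e-12, ftol = 1e-14) {
  list(min_angle = min_angle, max_iter = max_iter, ptol = ptol, ftol = ftol)
}

#' Fit a pure rotation axis between corresponded open and closed scans
#'
#' The dual-bite axis registration: finds the axis line and signed angle
#' such that rotating the open mesh about the axis best matches the fixed
#' closed mesh, in the corresponded least-squares sense with a plain
#' (unweighted) Euclidean distance metric and *no translation term*. The
#' fit is two-stage: a closed-form corresponded rigid superposition
#' ([best_fit_rigid()]) whose screw decomposition (pitch discarded) seeds a
#' rotation-only Levenberg-Marquardt refinement over five parameters (two
#' for axis direction, two for axis position in the plane normal to the
#' direction through the closed-mesh centroid projection, one for the
#' angle). The gauge plane removes the slide-along-axis degeneracy.
#'
#' Because the model is rotation-only, any translational component of the
#' true displacement (physiological translation, bite re-seating) is
#' absorbed into an apparent shift of the fitted axis — the instantaneous
#' centre of rotation. That sensitivity is exactly what the EcD ratio
#' quantifies.
#'
#' @param open_mesh the moving (open-bite) [tri_mesh()].
#' @param closed_mesh the fixed (closed-bite) target [tri_mesh()].
#' @param control options from [axis_fit_control()].
#' @return An object of class `registration_result`: `axis` (canonical
#'   against the closed mesh), `angle` (degrees, signed), `residual_rms`,
#'   `residual_max` (mm), `iterations`, `converged`, `pair_label`,
#'   `fixed_label`, `moving_label`.
#' @export
fit_rotation_axis <- function(open_mesh, closed_mesh,
                              control = axis_fit_control()) {
  stopifnot_corresponded(open_mesh, closed_mesh)
  init <- best_fit_rigid(open_mesh, closed_mesh)
  screw <- screw_decompose(init, min_angle = control$min_angle)

  u0 <- screw$axis_direction
  c0 <- mesh_centroid(closed_mesh)
  # gauge: anchor the position parameters in the plane through the
  # projection of the closed-mesh centroid, normal to the initial direction
  p0 <- screw$axis_point +
    sum((c0 - screw$axis_point) * u0) * u0
  E <- .normal_frame(u0)
  V <- open_mesh$vertices
  W <- closed_mesh$vertices

  resid_fn <- function(par) {
    u <- u0 + par[1] * E[, 1] + par[2] * E[, 2]
    u <- u / sqrt(sum(u^2))
    p <- p0 + par[3] * E[, 1] + par[4] * E[, 2]
    R <- .rodrigues(u, par[5])
    D <- sweep(sweep(V, 2, p) %*% t(R), 2, -p) - W
    as.numeric(D)
  }

  fit <- minpack.lm::nls.lm(
    par = c(0, 0, 0, 0, screw$angle * pi / 180),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = control$max_iter, ptol = control$ptol,
      ftol = control$ftol, gtol = 0))

  par <- fit$par
  u <- u0 + par[1] * E[, 1] + par[2] * E[, 2]
  u <- u / sqrt(sum(u^2))
  p <- p0 + par[3] * E[, 1] + par[4] * E[, 2]
  angle <- par[5] * 180 / pi
  axis <- canonicalize_axis(list(point = p, direction = u, source = "szeged",
                                 label = paste0(closed_mesh$label, ":",
                                                open_mesh$label)),
                            closed_mesh)
  # canonicalization may flip the direction sign; keep the same rotation
  if (sum(u * axis$direction) < 0) angle <- -angle

  d <- sqrt(rowSums(matrix(resid_fn(par), ncol = 3)^2))
  structure(list(axis = axis, angle = angle,
                 residual_rms = sqrt(mean(d^2)), residual_max = max(d),
                 iterations = fit$niter,
                 converged = fit$info %in% 1:4,
                 pair_label = paste0(closed_mesh$label, ":", open_mesh$label),
                 fixed_label = closed_mesh$label,
                 moving_label = open_mesh$label),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("axis fit %s: angle %.4f deg, residual rms %.6f mm (max %.6f), %d iterations%s\n",
              x$pair_label, x$angle, x$residual_rms, x$residual_max,
              x$iterations, if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Fit the rotation angle about a fixed axis
#'
#' One-parameter corresponded least squares: rotates the moving mesh about
#' a given (e.g. reference-derived) axis until overlap with the target is
#' optimal under the summed squared vertex distances. For a fixed axis the
#' objective is a sinusoid in the angle, so the bracketed golden-section
#' search finds the unique optimum in the period.
#'
#' @param moving,target corresponded [tri_mesh()] objects.
#' @param axis an [axis_line()].
#' @param interval angle search interval in degrees (default the full
#'   period `c(-180, 180)`).
#' @return An object of class `angle_fit_result`: `angle` (degrees) and
#'   `deviation` (a `deviation_report` of the rotated moving mesh vs the
#'   target at the optimum).
#' @export
fit_angle_about_axis <- function(moving, axis, target,
                                 interval = c(-180, 180)) {
  stopifnot_corresponded(moving, target)
  V <- moving$vertices; W <- target$vertices
  p <- axis$start; u <- axis$direction
  obj <- function(angle) {
    R <- .rodrigues(u, angle * pi / 180)
    sum((sweep(sweep(V, 2, p) %*% t(R), 2, -p) - W)^2)
  }
  opt <- stats::optimize(obj, interval = interval, tol = 1e-9)
  rotated <- apply_transform(moving, rotation_about_axis(axis, opt$minimum))
  structure(list(angle = opt$minimum,
                 deviation = deviation(rotated, target)),
            class = "angle_fit_result")
}

#' Chairside scan selection among replicate closed scans
#'
#' Mirrors the clinical triage of triplicate closed-bite scans: pairwise
#' deviations within each group are inspected against the 0.1 mm clinical
#' limit (differences below 0.01 mm are clinically negligible). The default
#' scan — the first scan of the designated default group — is kept unless
#' its group's maximum pairwise deviation approaches the limit (>= 0.09
#' mm), in which case the scan with the smallest summed pairwise deviation
#' in the better group is chosen instead. If both groups approach the
#' limit, the overall best scan is chosen and the session flagged.
#'
#' @param group_a,group_b lists of three corresponded [tri_mesh()] scans.
#' @param default_group `"A"` or `"B"`: which group holds the default scan
#'   (default `"B"`, i.e. the first scan of group B).
#' @param fallback_limit group maximum pairwise deviation (mm) at which the
#'   default is abandoned (default 0.09, "approaching 0.1").
#' @param basis deviation summary used pairwise: `"max"` (default) or
#'   `"rms"`.
#' @return An object of class `selection_decision`: `selected_label`,
#'   `group_max_deviation` (named, mm), `rule_fired`
#'   (`"default"`/`"fallback"`), `flagged`.
#' @export
select_scan <- function(group_a, group_b, default_group = "B",
                        fallback_limit = 0.09, basis = c("max", "rms")) {
  basis <- match.arg(basis)
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop("each group needs three replicate scans")
  pair_dev <- function(grp) {
    n <- length(grp)
    idx <- utils::combn(n, 2)
    apply(idx, 2, function(ij) {
      d <- deviation(grp[[ij[1]]], grp[[ij[2]]])
      if (basis == "max") d$max_error else d$rms_error
    })
  }
  dev_a <- pair_dev(group_a); dev_b <- pair_dev(group_b)
  gmax <- c(A = max(dev_a), B = max(dev_b))
  default_group <- match.arg(default_group, c("A", "B"))
  other <- setdiff(c("A", "B"), default_group)

  summed <- function(grp, devs) {
    n <- length(grp)
    idx <- utils::combn(n, 2)
    vapply(seq_len(n), function(i) sum(devs[idx[1, ] == i | idx[2, ] == i]),
           numeric(1))
  }
  pick_best <- function(which_grp) {
    grp <- if (which_grp == "A") group_a else group_b
    devs <- if (which_grp == "A") dev_a else dev_b
    grp[[which.min(summed(grp, devs))]]$label
  }

  if (gmax[default_group] < fallback_limit) {
    sel <- (if (default_group == "A") group_a else group_b)[[1]]$label
    rule <- "default"; flagged <- FALSE
  } else if (gmax[other] < fallback_limit) {
    sel <- pick_best(other)
    rule <- "fallback"; flagged <- FALSE
  } else {
    sel <- pick_best(names(which.min(gmax)))
    rule <- "fallback"; flagged <- TRUE
  }
  structure(list(selected_label = sel, group_max_deviation = gmax,
                 rule_fired = rule, flagged = flagged),
            class = "selection_decision")
}

#' @export
print.selection_decision <- function(x, ...) {
  cat(sprintf("selected scan '%s' (%s rule%s); group max deviation A %.4f / B %.4f mm\n",
              x$selected_label, x$rule_fired,
              if (x$flagged) ", session flagged" else "",
              x$group_max_deviation["A"], x$group_max_deviation["B"]))
  invisible(x)
}

#' Flag outlier axes among replicate registrations
#'
#' Replicate reference registrations occasionally fail and land far from
#' the rest of the cluster. An axis is excluded when its mean pairwise
#' `d_axis` against the other axes exceeds twice the group median of that
#' statistic. The rule is deterministic and, by construction, excluding a
#' flagged axis reduces the group's mean pairwise discrepancy.
#'
#' @param axes list of >= 3 [axis_line()] objects (canonical or not).
#' @param reference_mesh [tri_mesh()] used to canonicalize all axes before
#'   comparison.
#' @return list with `kept` and `excluded` lists of canonical axes, plus
#'   `mean_pairwise_d_axis` (named per input axis).
#' @export
flag_outlier_axes <- function(axes, reference_mesh) {
  if (length(axes) < 3L) stop("outlier screening needs at least 3 axes")
  can <- lapply(axes, canonicalize_axis, reference_mesh = reference_mesh)
  n <- length(can)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- compare_axes(can[[i]], can[[j]])$d_axis
  mp <- rowSums(D) / (n - 1)
  names(mp) <- vapply(can, function(a) a$label, character(1))
  cut <- 2 * stats::median(mp)
  out <- mp > cut
  list(kept = can[!out], excluded = can[out], mean_pairwise_d_axis = mp)
}
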