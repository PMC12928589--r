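#' Single virtual-articulator rotation trial
#'
#' Rotates one mesh by the same signed angle about a *central* and a
#' *modified* axis and measures the consequence: the corresponded deviation
#' between the two final poses, the axis discrepancy, and the AEcFE ratios
#' on both error bases.
#'
#' @param mesh the [tri_mesh()] placed in the articulator.
#' @param central,modified canonical [axis_line()] objects (canonicalized
#'   against `mesh`).
#' @param angle signed rotation in degrees.
#' @return one-row `data.frame` with columns `central`, `modified`,
#'   `angle`, `rms_error`, `max_error`, `d_axis`, `angular_deviation`,
#'   `aecfe_rms`, `aecfe_max`.
#' @export
articulator_trial <- function(mesh, central, modified, angle) {
  a <- apply_transform(mesh, rotation_about_axis(central, angle))
  b <- apply_transform(mesh, rotation_about_axis(modified, angle))
  dev <- deviation(a, b)
  cmp <- compare_axes(central, modified)
  data.frame(central = central$label, modified = modified$label,
             angle = angle,
             rms_error = dev$rms_error, max_error = dev$max_error,
             d_axis = cmp$d_axis, angular_deviation = cmp$angular_deviation,
             aecfe_rms = aecfe_ratio(cmp, dev, "rms")$ratio,
             aecfe_max = aecfe_ratio(cmp, dev, "max")$ratio,
             stringsAsFactors = FALSE)
}

.signed_angles <- function(angles = c(1, 2, 3)) sort(c(-angles, angles))

#' Reproducibility trials within one axis group (Setup-1)
#'
#' Runs articulator trials for every unordered pair of axes from a single
#' registration method on one participant mesh, at every signed rotation
#' angle. Quantifies how reproducibly the method places the axis, in final
#' occlusal error terms.
#'
#' @param axes list of >= 2 canonical [axis_line()] objects (same method,
#'   same participant).
#' @param mesh the participant [tri_mesh()] to rotate.
#' @param angles unsigned rotation magnitudes in degrees (default
#'   `c(1, 2, 3)`; both signs are applied).
#' @return `data.frame` of trial rows (`choose(k, 2) * 2 * length(angles)`
#'   rows) with a `summary` attribute from [summarize_trials()].
#' @export
run_setup1 <- function(axes, mesh, angles = c(1, 2, 3)) {
  if (length(axes) < 2L) stop("reproducibility trials need at least 2 axes")
  idx <- utils::combn(length(axes), 2)
  rows <- list()
  for (k in seq_len(ncol(idx))) {
    for (ang in .signed_angles(angles)) {
      rows[[length(rows) + 1L]] <-
        articulator_trial(mesh, axes[[idx[1, k]]], axes[[idx[2, k]]], ang)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- summarize_trials(out)
  out
}

#' Cross-method trials: test axes against reference axes (Setup-2)
#'
#' Runs articulator trials for every cross pair (test axis x reference
#' axis) at every signed angle — the digital analogue of validating an
#' articulation method against a motion-tracking reference.
#'
#' @param szeged_axes,modjaw_axes non-empty lists of canonical
#'   [axis_line()] objects (test and reference groups).
#' @param mesh the participant [tri_mesh()].
#' @param angles unsigned rotation magnitudes in degrees.
#' @return `data.frame` of `m * n * 2 * length(angles)` trial rows with a
#'   `summary` attribute.
#' @export
run_setup2 <- function(szeged_axes, modjaw_axes, mesh, angles = c(1, 2, 3)) {
  if (length(szeged_axes) < 1L || length(modjaw_axes) < 1L)
    stop("both axis groups must be non-empty")
  rows <- list()
  for (a in szeged_axes) for (b in modjaw_axes)
    for (ang in .signed_angles(angles))
      rows[[length(rows) + 1L]] <- articulator_trial(mesh, a, b, ang)
  out <- do.call(rbind, rows)
  attr(out, "summary") <- summarize_trials(out)
  out
}

#' Summary block for a trial table
#'
#' Mean/SD (sample convention) of the error and axis-discrepancy columns
#' plus 0.1 mm threshold tallies of the per-trial rms and max errors,
#' mirroring the standard results-table layout.
#'
#' @param trials `data.frame` from [run_setup1()]/[run_setup2()].
#' @param limit clinical threshold in mm (default 0.1).
#' @return list of summaries per column and `tally_rms`/`tally_max`.
#' @export
summarize_trials <- function(trials, limit = 0.1) {
  cols <- c("rms_error", "max_error", "d_axis", "angular_deviation")
  s <- lapply(trials[cols], summarize_values)
  s$tally_rms <- threshold_tally(trials$rms_error, limit)
  s$tally_max <- threshold_tally(trials$max_error, limit)
  s$n_trials <- nrow(trials)
  s
}

#' EcD experiment over fits sharing a fixed mesh
#'
#' For every pair of axis fits that share the same fixed (closed) mesh, the
#' discrepancy between the two fitted axes is divided by the deviation
#' between the two moving (open) meshes that produced them, yielding the
#' EcD ratio on both bases. Pairs whose moving meshes carry the same bite
#' label (e.g. OA vs OA) are tagged `same_bite`; cross-bite pairs (OA vs
#' OB) are `mixed_bite`.
#'
#' @param fits list of `registration_result` objects.
#' @param moving_meshes named list of the moving [tri_mesh()] objects,
#'   keyed by label.
#' @return `data.frame`: `fixed`, `moving_1`, `moving_2`, `bite_group`,
#'   `d_axis`, `scan_rms`, `scan_max`, `ecd_rms`, `ecd_max`, `degenerate`
#'   (TRUE when the moving meshes coincide and the ratio is undefined).
#' @export
run_ecd_experiment <- function(fits, moving_meshes) {
  fixed <- vapply(fits, function(f) f$fixed_label, character(1))
  rows <- list()
  for (fx in unique(fixed)) {
    grp <- fits[fixed == fx]
    if (length(grp) < 2L) next
    idx <- utils::combn(length(grp), 2)
    for (k in seq_len(ncol(idx))) {
      f1 <- grp[[idx[1, k]]]; f2 <- grp[[idx[2, k]]]
      m1 <- moving_meshes[[f1$moving_label]]
      m2 <- moving_meshes[[f2$moving_label]]
      if (is.null(m1) || is.null(m2))
        stop(sprintf("moving mesh missing for pair %s / %s",
                     f1$moving_label, f2$moving_label))
      dev <- deviation(m1, m2)
      cmp <- compare_axes(f1$axis, f2$axis)
      degenerate <- dev$rms_error <= 0
      same <- identical(substr(f1$moving_label, 1, 2),
                        substr(f2$moving_label, 1, 2))
      rows[[length(rows) + 1L]] <- data.frame(
        fixed = fx, moving_1 = f1$moving_label, moving_2 = f2$moving_label,
        bite_group = if (same) "same_bite" else "mixed_bite",
        d_axis = cmp$d_axis,
        scan_rms = dev$rms_error, scan_max = dev$max_error,
        ecd_rms = if (degenerate) NA_real_ else ecd_ratio(cmp, dev, "rms")$ratio,
        ecd_max = if (degenerate) NA_real_ else ecd_ratio(cmp, dev, "max")$ratio,
        degenerate = degenerate, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    stop("no fit pairs share a fixed mesh")
  do.call(rbind, rows)
}

#' Reversed control trials: rotate closed scans about reference axes
#' (Setup-3)
#'
#' For each reference axis and each open target scan, the closed mesh is
#' rotated about the axis to the angle of best overlap
#' ([fit_angle_about_axis()]); the residual rms/max at the optimum measure
#' how well the reference axis explains the statically captured open pose.
#' A consistent residual with small spread across replicates signals a
#' systematic protocol offset rather than random error.
#'
#' @param closed_mesh the selected closed [tri_mesh()].
#' @param modjaw_axes list of reference [axis_line()] objects.
#' @param open_meshes list of open target [tri_mesh()] objects.
#' @return `data.frame`: `axis`, `target`, `angle`, `rms_error`,
#'   `max_error`, with a `summary` attribute (mean/sd per column).
#' @export
run_setup3 <- function(closed_mesh, modjaw_axes, open_meshes) {
  if (length(modjaw_axes) < 1L) stop("need at least one reference axis")
  rows <- list()
  for (ax in modjaw_axes) for (tg in open_meshes) {
    fit <- fit_angle_about_axis(closed_mesh, ax, tg)
    rows[[length(rows) + 1L]] <- data.frame(
      axis = ax$label, target = tg$label, angle = fit$angle,
      rms_error = fit$deviation$rms_error,
      max_error = fit$deviation$max_error, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- lapply(out[c("angle", "rms_error", "max_error")],
                                 summarize_values)
  out
}

#' Axis-error direction sensitivity scan
#'
#' Perturbs an axis by unit axis discrepancy (1 mm on the `d_axis` scale)
#' in each of three mode families — parallel perpendicular offsets around
#' the clock, a slide along the axis, and tilts about the canonical
#' midpoint around the clock — and measures the final mesh error per unit
#' `d_axis` after a prescribed articulator rotation, by rotating the mesh
#' about the central and the perturbed axis and comparing poses.
#'
#' The axial slide leaves the line unchanged (zero final error by
#' construction); every perpendicular parallel offset produces the same
#' uniform displacement field of magnitude `2 sin(angle/2)` per unit
#' offset; tilt sensitivity depends on direction and on where the mesh
#' sits along the axis. The least-sensitive non-degenerate entry is the
#' direction along which an error-minimising optimizer will preferentially
#' scatter its fitted axes.
#'
#' @param mesh the articulated [tri_mesh()].
#' @param axis canonical [axis_line()] (against `mesh`).
#' @param angle articulator rotation in degrees.
#' @param n_directions clock directions per mode family (default 12).
#' @return An object of class `sensitivity_profile`: a `data.frame` with
#'   columns `mode`, `phi_deg`, `d_axis`, `rms_per_daxis`, `max_per_daxis`,
#'   and attributes `least_sensitive` / `most_sensitive_offset` (rows) and
#'   `frame` (the normal-plane basis used).
#' @export
error_direction_scan <- function(mesh, axis, angle, n_directions = 12) {
  E <- .normal_frame(axis$direction)
  base_pose <- apply_transform(mesh, rotation_about_axis(axis, angle))
  mid <- (axis$start + axis$end) / 2
  half <- sqrt(sum((axis$end - mid)^2))
  phis <- seq(0, 360, length.out = n_directions + 1)[-(n_directions + 1)]

  measure <- function(pert_axis) {
    pose <- apply_transform(mesh, rotation_about_axis(pert_axis, angle))
    dev <- deviation(base_pose, pose)
    cmp <- compare_axes(axis, canonicalize_axis(pert_axis, .ref_stub(mesh, axis)))
    c(d_axis = cmp$d_axis, rms = dev$rms_error, max = dev$max_error)
  }

  rows <- list()
  for (phi in phis) {
    d <- cos(phi * pi / 180) * E[, 1] + sin(phi * pi / 180) * E[, 2]
    # parallel perpendicular offset of 1 mm: d_axis is exactly 1
    off <- axis_line(axis$start + d, axis$end + d, source = "perturbed")
    m <- measure(off)
    rows[[length(rows) + 1L]] <- data.frame(
      mode = "perpendicular-offset", phi_deg = phi, d_axis = m["d_axis"],
      rms_per_daxis = m["rms"] / m["d_axis"],
      max_per_daxis = m["max"] / m["d_axis"])
    # tilt about the midpoint moving the endpoints by ~1 mm each
    psi <- 2 * asin(1 / (2 * half))
    u2 <- cos(psi) * axis$direction + sin(psi) * d
    tilt <- axis_line(mid - half * u2, mid + half * u2, source = "perturbed")
    m <- measure(tilt)
    rows[[length(rows) + 1L]] <- data.frame(
      mode = "tilt", phi_deg = phi, d_axis = m["d_axis"],
      rms_per_daxis = m["rms"] / m["d_axis"],
      max_per_daxis = m["max"] / m["d_axis"])
  }
  ax_off <- axis_line(axis$start + axis$direction, axis$end + axis$direction,
                      source = "perturbed")
  pose <- apply_transform(mesh, rotation_about_axis(ax_off, angle))
  dev <- deviation(base_pose, pose)
  rows[[length(rows) + 1L]] <- data.frame(
    mode = "axial-offset", phi_deg = NA_real_, d_axis = 0,
    rms_per_daxis = dev$rms_error, max_per_daxis = dev$max_error)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  nondeg <- out[out$mode != "axial-offset", ]
  attr(out, "least_sensitive") <- nondeg[which.min(nondeg$rms_per_daxis), ]
  offs <- out[out$mode == "perpendicular-offset", ]
  attr(out, "most_sensitive_offset") <- offs[which.max(offs$rms_per_daxis), ]
  attr(out, "frame") <- E
  class(out) <- c("sensitivity_profile", class(out))
  out
}

# Minimal stand-in reference mesh carrying the label and centroid that the
# axis was canonicalized against, so perturbed variants of a canonical axis
# can be re-canonicalized compatibly inside the scan.
.ref_stub <- function(mesh, axis) {
  if (identical(axis$reference, mesh$label)) return(mesh)
  stop("axis must be canonicalized against the supplied mesh")
}
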