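# Run code with a private, restorable RNG stream so generators are
# deterministic under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed below 2^31 from a parent seed and a stream index.
.child_seed <- function(seed, k) {
  (as.double(seed) * 7919 + 104729 * k) %% 2147483629
}

#' Parameters of the synthetic dental-arch mesh
#'
#' Footprint and sampling of the parametric lower-arch band generated by
#' [make_arch_mesh()]. Defaults emulate an adult lower arch: 55 mm wide,
#' 45 mm deep, with a sinusoidal cusp relief.
#'
#' @param arch_width mediolateral width in mm (default 55).
#' @param arch_depth anteroposterior depth in mm (default 45).
#' @param band_height occlusal band width in mm (default 9).
#' @param cusp_amplitude cusp relief amplitude in mm (default 1.5).
#' @param vertex_budget approximate vertex count (default 3000, minimum 50).
#' @param seed integer seed controlling the deterministic surface detail.
#' @return list of class `arch_params`.
#' @export
arch_params <- function(arch_width = 55, arch_depth = 45, band_height = 9,
                        cusp_amplitude = 1.5, vertex_budget = 3000,
                        seed = 1L) {
  p <- list(arch_width = arch_width, arch_depth = arch_depth,
            band_height = band_height, cusp_amplitude = cusp_amplitude,
            vertex_budget = as.integer(vertex_budget),
            seed = as.integer(seed))
  if (any(unlist(p[1:5]) <= 0)) stop("arch parameters must be positive")
  if (p$vertex_budget < 50L) stop("vertex budget below 50 is unusable")
  structure(p, class = "arch_params")
}

#' Generate a synthetic lower-arch scan mesh
#'
#' Builds an open band mesh along a semi-elliptic dental arch with
#' sinusoidal cusp relief, in the scan coordinate convention used
#' throughout the package: the incisal midpoint near the origin, +x
#' mediolateral, -y posterior, +z superior. Deterministic: the same
#' parameters and seed reproduce the vertex array bitwise.
#'
#' @param params an [arch_params()].
#' @return a [tri_mesh()] labelled `"arch"`.
#' @export
make_arch_mesh <- function(params = arch_params()) {
  n_across <- max(4L, as.integer(round(sqrt(params$vertex_budget / 6))))
  n_along <- max(12L, as.integer(round(params$vertex_budget / n_across)))
  phi <- seq(-pi / 2, pi / 2, length.out = n_along)
  s <- seq(-0.5, 0.5, length.out = n_across)
  jitter_amp <- 0.02 * params$cusp_amplitude
  with_seed(params$seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    jit <- matrix(stats::rnorm(n_along * n_across, sd = jitter_amp),
                  n_along, n_across)
    # centerline of the arch: incisal point near (0, 0), molars posteriorly;
    # half-axes shrunk by the band so the overall footprint stays at the
    # requested width x depth
    a_half <- (params$arch_width - params$band_height) / 2
    d_eff <- params$arch_depth - params$band_height / 2
    cx <- a_half * sin(phi)
    cy <- -d_eff * (1 - cos(phi))
    # outward normal of the centerline in the occlusal plane
    nx <- sin(phi); ny <- cos(phi) * (d_eff / a_half)
    nn <- sqrt(nx^2 + ny^2); nx <- nx / nn; ny <- ny / nn
    V <- matrix(0, n_along * n_across, 3)
    k <- 0L
    for (i in seq_len(n_along)) {
      for (j in seq_len(n_across)) {
        k <- k + 1L
        off <- s[j] * params$band_height
        V[k, 1] <- cx[i] + off * nx[i]
        V[k, 2] <- cy[i] + off * ny[i]
        V[k, 3] <- params$cusp_amplitude *
          sin(14 * phi[i] + phase) * cos(pi * s[j]) + jit[i, j]
      }
    }
    faces <- matrix(0L, 2 * (n_along - 1) * (n_across - 1), 3)
    f <- 0L
    for (i in seq_len(n_along - 1)) {
      for (j in seq_len(n_across - 1)) {
        v00 <- (i - 1L) * n_across + j
        v01 <- v00 + 1L
        v10 <- v00 + n_across
        v11 <- v10 + 1L
        faces[f + 1L, ] <- c(v00, v10, v11)
        faces[f + 2L, ] <- c(v00, v11, v01)
        f <- f + 2L
      }
    }
    tri_mesh(V, faces, label = "arch")
  })
}

#' Default condylar hinge axis for a synthetic arch
#'
#' Places the hinge 75 mm posterior and 40 mm superior of the incisal
#' midpoint, directed mediolaterally (+x) — representative condylar
#' geometry for an adult mandible.
#'
#' @param incisal_point length-3 incisal midpoint (default origin).
#' @param posterior,superior hinge offsets in mm.
#' @return a (pre-canonical) [axis_line()] with `source = "truth"`.
#' @export
default_hinge_axis <- function(incisal_point = c(0, 0, 0),
                               posterior = 75, superior = 40) {
  p <- incisal_point + c(0, -posterior, superior)
  axis_line(p - c(100, 0, 0), p + c(100, 0, 0),
            source = "truth", label = "hinge")
}

#' Opening angle produced by a bite block
#'
#' Chord relation at the incisal point: a block of thickness `t` held at
#' incisal radius `r` from the hinge opens the jaw by
#' `2 asin(t / (2 r))` degrees.
#'
#' @param bite_thickness block thickness in mm (default 2).
#' @param incisal_radius distance from incisal point to hinge axis in mm.
#' @return opening angle in degrees.
#' @export
opening_angle_from_bite <- function(bite_thickness = 2, incisal_radius) {
  2 * asin(bite_thickness / (2 * incisal_radius)) * 180 / pi
}

#' Simulate a jaw-opening pose
#'
#' Rotates the closed-pose mesh about the hinge axis by the opening angle,
#' then applies an optional rigid translational contamination (bite
#' re-seating / physiological translation). Correspondence is preserved.
#'
#' The rotation sign convention: a positive opening rotates the incisal
#' point downwards (about +x mediolateral with -y posterior, this is a
#' negative right-hand rotation), handled internally so `opening >= 0`
#' always opens the mouth.
#'
#' @param mesh closed-pose [tri_mesh()].
#' @param hinge the hinge [axis_line()].
#' @param opening opening angle in degrees (>= 0).
#' @param contamination length-3 translation in mm applied after the
#'   rotation (default zero).
#' @param label label for the output mesh.
#' @return the opened [tri_mesh()].
#' @export
simulate_opening <- function(mesh, hinge, opening,
                             contamination = c(0, 0, 0),
                             label = mesh$label) {
  stopifnot(opening >= 0)
  rot <- rotation_about_axis(hinge, -opening)
  tr <- rigid_transform(diag(3), as.numeric(contamination))
  apply_transform(mesh, compose_transforms(tr, rot), label = label)
}

#' Apply calibrated rigid alignment noise
#'
#' Draws a random small rigid twist (rotation about a random axis through
#' the mesh centroid plus a random translation) and scales it so that the
#' induced corresponded-vertex rms deviation equals `target_rms` to 1e-9.
#' This emulates bite-alignment error of an intraoral scanner: the surface
#' itself is untouched (the dual-bite method presumes identical,
#' corresponded meshes), only the pose wobbles.
#'
#' @param mesh a [tri_mesh()].
#' @param target_rms requested rms pose error in mm (>= 0).
#' @param seed integer seed for the draw.
#' @param rot_trans_mix fraction of the unit twist allotted to rotation
#'   vs translation (default 0.5).
#' @return the perturbed [tri_mesh()].
#' @export
apply_alignment_noise <- function(mesh, target_rms, seed,
                                  rot_trans_mix = 0.5) {
  stopifnot(target_rms >= 0)
  if (target_rms == 0) return(mesh)
  with_seed(seed, {
    axis_dir <- stats::rnorm(3); axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
    tdir <- stats::rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
    c0 <- mesh_centroid(mesh)
    twist <- function(eps) {
      R <- .rodrigues(axis_dir, eps * rot_trans_mix / 20)
      tv <- c0 - as.numeric(R %*% c0) + eps * (1 - rot_trans_mix) * tdir
      rigid_transform(R, tv)
    }
    f <- function(eps) deviation(mesh, apply_transform(mesh, twist(eps)))$rms_error -
      target_rms
    hi <- 2 * target_rms
    while (f(hi) < 0) hi <- hi * 2
    eps <- stats::uniroot(f, c(0, hi), tol = 1e-15)$root
    # polish: rms is near-linear in eps, one secant step nails 1e-9
    r <- f(eps)
    if (abs(r) > 1e-12) eps <- eps * target_rms / (r + target_rms)
    apply_transform(mesh, twist(eps))
  })
}

#' Scenario for a synthetic dual-bite scan session
#'
#' Encodes the study conditions a session emulates: a ~2 mm bite block
#' opening, scanner bite-alignment noise at the observed closed/open rms
#' scales, optional translational contamination of the open pose, an
#' independent re-seating offset between the A and B bite-block groups,
#' and a cloud of replicate reference axes scattered about the truth.
#'
#' @param bite_thickness bite block thickness in mm (default 2).
#' @param opening_angle opening in degrees; `NULL` (default) derives it
#'   from the bite thickness and the incisal-point-to-hinge distance.
#' @param closed_noise_rms,open_noise_rms per-scan alignment noise rms in
#'   mm (defaults 0.036 and 0.145, the observed closed/open accuracy
#'   scales).
#' @param contamination length-3 systematic translation of the open pose
#'   (mm, default zero).
#' @param reseat_rms rms of the independent translational re-seating
#'   offset between the A and B open-bite groups (mm, default 0.05).
#' @param n_modjaw number of replicate reference axes (default 5).
#' @param modjaw_scatter target mean pairwise `d_axis` of the reference
#'   axes in mm (default 1.7).
#' @param seed integer session seed.
#' @return list of class `scan_scenario`.
#' @export
scan_scenario <- function(bite_thickness = 2, opening_angle = NULL,
                          closed_noise_rms = 0.036, open_noise_rms = 0.145,
                          contamination = c(0, 0, 0), reseat_rms = 0.05,
                          n_modjaw = 5, modjaw_scatter = 1.7, seed = 1L) {
  structure(list(bite_thickness = bite_thickness,
                 opening_angle = opening_angle,
                 closed_noise_rms = closed_noise_rms,
                 open_noise_rms = open_noise_rms,
                 contamination = as.numeric(contamination),
                 reseat_rms = reseat_rms,
                 n_modjaw = as.integer(n_modjaw),
                 modjaw_scatter = modjaw_scatter,
                 seed = as.integer(seed)),
            class = "scan_scenario")
}

#' Generate a full synthetic dual-bite scan session
#'
#' Emulates one participant's acquisition: triplicate closed scans in two
#' bite groups (CA1-3, CB1-3), triplicate open scans in two bite-block
#' groups (OA1-3, OB1-3), and replicate reference axes. The closed scans
#' are alignment-noise-perturbed copies of the closed pose; the open scans
#' are noise-perturbed copies of the opened pose, with an independent
#' translational re-seating offset between the A and B block groups. The
#' reference axes are the truth axis perturbed (offset + tilt) and scaled
#' so their mean pairwise `d_axis` equals the scenario's scatter target.
#' Ground truth is stored for test harnesses; no analysis code reads it.
#'
#' @param arch an [arch_params()].
#' @param scenario a [scan_scenario()].
#' @return An object of class `scan_session`: `scans` (named list of 12
#'   [tri_mesh()]), `modjaw_axes` (canonical against the session base
#'   mesh), `truth_axis` (canonical), `opening_angle` (degrees),
#'   `base_mesh`, `scenario`.
#' @export
make_session <- function(arch = arch_params(), scenario = scan_scenario()) {
  base <- make_arch_mesh(arch)
  hinge <- default_hinge_axis()
  incisal <- c(0, 0, 0)
  r_inc <- .point_line_distance(incisal, hinge)
  opening <- if (is.null(scenario$opening_angle))
    opening_angle_from_bite(scenario$bite_thickness, r_inc)
    else scenario$opening_angle

  closed_pose <- base
  seed <- scenario$seed
  reseat <- function(k) {
    if (scenario$reseat_rms == 0) return(c(0, 0, 0))
    with_seed(.child_seed(seed, 900 + k), {
      v <- stats::rnorm(3); v / sqrt(sum(v^2)) * scenario$reseat_rms
    })
  }
  open_pose <- list(
    A = simulate_opening(base, hinge, opening,
                         scenario$contamination + reseat(1)),
    B = simulate_opening(base, hinge, opening,
                         scenario$contamination + reseat(2)))

  scans <- list()
  k <- 0L
  for (pos in c("CA", "CB", "OA", "OB")) {
    pose <- if (substr(pos, 1, 1) == "C") closed_pose
            else open_pose[[substr(pos, 2, 2)]]
    rms <- if (substr(pos, 1, 1) == "C") scenario$closed_noise_rms
           else scenario$open_noise_rms
    for (i in 1:3) {
      k <- k + 1L
      lab <- paste0(pos, i)
      m <- apply_alignment_noise(pose, rms, seed = .child_seed(seed, k))
      m$label <- lab
      scans[[lab]] <- m
    }
  }

  truth <- canonicalize_axis(hinge, base)
  modjaw <- .scatter_axes(truth, base, scenario$n_modjaw,
                          scenario$modjaw_scatter,
                          seed = .child_seed(seed, 500))
  structure(list(scans = scans, modjaw_axes = modjaw, truth_axis = truth,
                 opening_angle = opening, base_mesh = base,
                 scenario = scenario),
            class = "scan_session")
}

#' @export
print.scan_session <- function(x, ...) {
  cat(sprintf("scan_session: 12 scans (%s), %d reference axes, opening %.3f deg, seed %d\n",
              paste(names(x$scans)[c(1, 4, 7, 10)], collapse = "/"),
              length(x$modjaw_axes), x$opening_angle, x$scenario$seed))
  invisible(x)
}

.point_line_distance <- function(point, axis) {
  w <- point - axis$start
  perp <- w - sum(w * axis$direction) * axis$direction
  sqrt(sum(perp^2))
}

# Replicate reference axes: random offset+tilt perturbations of the truth
# axis, rescaled so the mean pairwise d_axis of the canonical axes matches
# the requested scatter (exact to the uniroot tolerance).
.scatter_axes <- function(truth, reference_mesh, n, scatter, seed) {
  if (n < 2L) stop("need at least two reference axes")
  with_seed(seed, {
    d_start <- matrix(stats::rnorm(3 * n), n, 3)
    d_end <- matrix(stats::rnorm(3 * n), n, 3)
    build <- function(scale) {
      lapply(seq_len(n), function(i) {
        canonicalize_axis(
          axis_line(truth$start + scale * d_start[i, ],
                    truth$end + scale * d_end[i, ],
                    source = "modjaw", label = paste0("modjaw-", i)),
          reference_mesh)
      })
    }
    mean_pairwise <- function(axes) {
      idx <- utils::combn(length(axes), 2)
      mean(apply(idx, 2, function(ij)
        compare_axes(axes[[ij[1]]], axes[[ij[2]]])$d_axis))
    }
    if (scatter == 0) return(build(0))
    f <- function(s) mean_pairwise(build(s)) - scatter
    hi <- 1
    while (f(hi) < 0) hi <- hi * 2
    s <- stats::uniroot(f, c(0, hi), tol = 1e-10)$root
    build(s)
  })
}
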