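# Fixture builders and independent oracles, all generated in code.

rand_mesh <- function(n = 30, seed = 1, sd = 15, label = "m") {
  set.seed(seed)
  tri_mesh(matrix(rnorm(3 * n, sd = sd), n, 3), label = label)
}

rand_canonical_axis <- function(seed, reference_mesh, source = "truth",
                                label = "") {
  set.seed(seed)
  canonicalize_axis(axis_line(rnorm(3, sd = 10),
                              rnorm(3, sd = 10) + c(25, 5, 2),
                              source = source, label = label),
                    reference_mesh)
}

# Open-ended cylinder: two rings of n_seg vertices; optional cap-centre
# vertices with triangle-fan caps (as axis exports from motion-tracking
# software look after meshing).
make_cylinder_mesh <- function(c0, c1, radius = 2, n_seg = 64,
                               caps = FALSE, label = "cyl") {
  u <- (c1 - c0) / sqrt(sum((c1 - c0)^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  th <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  ring <- function(ct) t(vapply(th, function(t0)
    ct + radius * (cos(t0) * e1 + sin(t0) * e2), numeric(3)))
  V <- rbind(ring(c0), ring(c1))
  F <- do.call(rbind, lapply(seq_len(n_seg), function(i) {
    j <- i %% n_seg + 1L
    rbind(c(i, n_seg + i, n_seg + j), c(i, n_seg + j, j))
  }))
  if (caps) {
    V <- rbind(V, c0, c1)
    i0 <- 2L * n_seg + 1L; i1 <- i0 + 1L
    F <- rbind(F,
               do.call(rbind, lapply(seq_len(n_seg), function(i)
                 c(i0, i, i %% n_seg + 1L))),
               do.call(rbind, lapply(seq_len(n_seg), function(i)
                 c(i1, n_seg + i %% n_seg + 1L, n_seg + i))))
  }
  tri_mesh(V, F, label = label)
}

# Brute-force randomized-restart rigid (rotation + translation) fit:
# independent of the closed-form path.
brute_rigid_rms <- function(source, target, n_starts = 30, seed = 1) {
  V <- source$vertices; W <- target$vertices
  obj <- function(par) {
    th <- sqrt(sum(par[1:3]^2))
    R <- if (th < 1e-12) diag(3) else hingefit:::.rodrigues(par[1:3] / th, th)
    sum((sweep(V %*% t(R), 2, -par[4:6]) - W)^2)
  }
  set.seed(seed)
  best <- Inf
  for (k in seq_len(n_starts)) {
    o <- optim(c(rnorm(3, sd = 1), rnorm(3, sd = 5)), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-15))
    if (o$value < best) { best <- o$value; bp <- o$par }
  }
  o <- optim(bp, obj, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-16))
  sqrt(min(best, o$value) / nrow(V))
}

# Brute-force multi-start rotation-only (axis + angle) objective: the
# independent oracle for the 5-parameter axis fit. Returns the minimal sum
# of squared corresponded distances.
brute_axis_objective <- function(source, target, n_starts = 25, seed = 1) {
  V <- source$vertices; W <- target$vertices
  obj <- function(par) {
    u <- c(cos(par[4]) * cos(par[5]), cos(par[4]) * sin(par[5]), sin(par[4]))
    p <- par[1:3]
    R <- hingefit:::.rodrigues(u, par[6])
    sum((sweep(sweep(V, 2, p) %*% t(R), 2, -p) - W)^2)
  }
  set.seed(seed)
  best <- Inf
  for (k in seq_len(n_starts)) {
    p0 <- c(rnorm(3, sd = 10), runif(1, -pi / 2, pi / 2), runif(1, -pi, pi),
            sample(c(-1, 1), 1) * runif(1, 0.005, 0.1))
    o <- try(optim(p0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)), silent = TRUE)
    if (!inherits(o, "try-error") && o$value < best) { best <- o$value; bp <- o$par }
  }
  o <- optim(bp, obj, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-16))
  min(best, o$value)
}

# Dense grid scan oracle for the one-parameter angle fit.
grid_angle_fit <- function(moving, axis, target, lo = -5, hi = 5,
                           step = 0.001) {
  angles <- seq(lo, hi, by = step)
  vals <- vapply(angles, function(a) {
    r <- apply_transform(moving, rotation_about_axis(axis, a))
    sum((r$vertices - target$vertices)^2)
  }, numeric(1))
  k <- which.min(vals)
  rot <- apply_transform(moving, rotation_about_axis(axis, angles[k]))
  list(angle = angles[k], deviation = deviation(rot, target))
}

# A noiseless synthetic fit instance: closed arch + exact rotation about a
# known axis, for recovery tests.
small_session <- function(seed, vertex_budget = 300, ...) {
  make_session(arch_params(vertex_budget = vertex_budget, seed = seed),
               scan_scenario(seed = seed, ...))
}
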