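test_that("rotation about an axis fixes the line and moves off-axis points by the chord", {
  m <- rand_mesh(20, seed = 1)
  ax <- canonicalize_axis(axis_line(c(0, 0, 0), c(0, 0, 50)), m)

  t0 <- rotation_about_axis(ax, 0)
  expect_equal(t0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(t0$translation, c(0, 0, 0), tolerance = 1e-12)

  on_line <- rbind(ax$start, ax$end, (ax$start + ax$end) / 2)
  moved <- transform_points(rotation_about_axis(ax, 37.3), on_line)
  expect_equal(moved, on_line, tolerance = 1e-9)

  # perpendicular distance 100 mm, 1 degree -> chord 2 * 100 * sin(0.5 deg)
  p <- matrix(c(100, 0, 10), 1)
  q <- transform_points(rotation_about_axis(ax, 1), p)
  expect_equal(sqrt(sum((q - p)^2)), 2 * 100 * sin(0.5 * pi / 180),
               tolerance = 1e-9)

  # distances to the axis are preserved for every point and angle
  dist_to_axis <- function(P) {
    w <- sweep(P, 2, ax$start)
    para <- w %*% ax$direction
    sqrt(rowSums((w - para %*% t(ax$direction))^2))
  }
  for (ang in c(-171.2, -12, 0.4, 45, 179.9)) {
    P2 <- transform_points(rotation_about_axis(ax, ang), m$vertices)
    expect_equal(dist_to_axis(P2), dist_to_axis(m$vertices), tolerance = 1e-9)
  }
})

test_that("apply_transform preserves order, faces, and rigidity, and composes", {
  m <- make_arch_mesh(arch_params(vertex_budget = 120, seed = 3))
  id <- rigid_transform()
  expect_identical(apply_transform(m, id)$vertices, m$vertices)

  tr <- rigid_transform(diag(3), c(1, 2, 3))
  shifted <- apply_transform(m, tr)
  expect_equal(shifted$vertices, sweep(m$vertices, 2, -c(1, 2, 3)),
               tolerance = 1e-12)
  expect_identical(shifted$faces, m$faces)

  ax <- canonicalize_axis(axis_line(c(5, -3, 1), c(7, 40, 9)), m)
  t1 <- rotation_about_axis(ax, 23)
  t2 <- rigid_transform(hingefit:::.rodrigues(c(0, 1, 0), 0.3), c(-4, 2, 7))
  two_step <- apply_transform(apply_transform(m, t1), t2)
  one_step <- apply_transform(m, compose_transforms(t2, t1))
  expect_equal(two_step$vertices, one_step$vertices, tolerance = 1e-9)

  d_before <- dist(m$vertices[1:15, ])
  d_after <- dist(two_step$vertices[1:15, ])
  expect_equal(as.numeric(d_after), as.numeric(d_before), tolerance = 1e-9)

  inv <- invert_transform(t1)
  back <- apply_transform(apply_transform(m, t1), inv)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-9)
})

test_that("best_fit_rigid recovers exact transforms and matches a brute-force oracle", {
  m <- rand_mesh(30, seed = 7)
  fit0 <- best_fit_rigid(m, m)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(attr(fit0, "residual_rms"), 0, tolerance = 1e-12)

  ax <- rand_canonical_axis(2, m)
  truth <- compose_transforms(rigid_transform(diag(3), c(0.3, -1, 2)),
                              rotation_about_axis(ax, 11.7))
  target <- apply_transform(m, truth)
  fit <- best_fit_rigid(m, target)
  expect_equal(fit$rotation, truth$rotation, tolerance = 1e-9)
  expect_equal(fit$translation, truth$translation, tolerance = 1e-9)

  set.seed(99)
  noisy <- tri_mesh(target$vertices + matrix(rnorm(90, sd = 0.05), 30, 3))
  fitn <- best_fit_rigid(m, noisy)
  expect_equal(attr(fitn, "residual_rms"),
               brute_rigid_rms(m, noisy, n_starts = 30, seed = 5),
               tolerance = 1e-6)

  line_pts <- outer(seq_len(10), c(1, 2, 3))
  expect_error(best_fit_rigid(tri_mesh(line_pts + 1e-15), tri_mesh(line_pts)),
               "collinear|rank-deficient|degenerate")
})

test_that("screw decomposition is exact, reports pitch, and obeys the planar ICR law", {
  m <- rand_mesh(10, seed = 4)
  ax <- canonicalize_axis(axis_line(c(3, -2, 5), c(3, -2, 5) + c(2, 1, 4)), m)

  t_rot <- rotation_about_axis(ax, 1.5)
  sc <- screw_decompose(t_rot)
  expect_equal(sc$angle, 1.5, tolerance = 1e-9)
  expect_equal(sc$pitch, 0, tolerance = 1e-9)
  expect_equal(abs(sum(sc$axis_direction * ax$direction)), 1, tolerance = 1e-9)

  slide <- rigid_transform(diag(3), 0.4 * ax$direction)
  sc2 <- screw_decompose(compose_transforms(slide, t_rot))
  expect_equal(abs(sc2$pitch), 0.4, tolerance = 1e-9)
  expect_equal(sc2$angle, 1.5, tolerance = 1e-9)

  # recomposition round trip over random transforms
  set.seed(11)
  for (k in 1:20) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    tt <- rigid_transform(hingefit:::.rodrigues(u, runif(1, 0.01, 3)),
                          rnorm(3, sd = 4))
    sc3 <- screw_decompose(tt)
    rec <- screw_recompose(sc3)
    expect_equal(rec$rotation, tt$rotation, tolerance = 1e-9)
    expect_equal(rec$translation, tt$translation, tolerance = 1e-9)
  }

  # planar ICR law: rotation + in-plane translation = pure rotation about a
  # line displaced by delta / (2 sin(theta / 2))
  frame <- hingefit:::.normal_frame(ax$direction)
  for (theta in c(0.5, 1.53, 4, 10)) {
    for (delta in c(0.05, 0.4, 1)) {
      contaminated <- compose_transforms(
        rigid_transform(diag(3), delta * frame[, 1]),
        rotation_about_axis(ax, theta))
      sc4 <- screw_decompose(contaminated)
      expect_equal(sc4$pitch, 0, tolerance = 1e-9)
      expect_equal(sc4$angle, theta, tolerance = 1e-9)
      shift <- sc4$axis_point - ax$start
      shift <- shift - sum(shift * ax$direction) * ax$direction
      expect_equal(sqrt(sum(shift^2)), delta / (2 * sin(theta * pi / 360)),
                   tolerance = 1e-9)
    }
  }

  expect_error(screw_decompose(rotation_about_axis(ax, 0.01)),
               "degenerate rotation")
})

test_that("canonicalization centres the 200 mm parameterization on the centroid projection", {
  m <- tri_mesh(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0.5)))
  # centroid at (0, 0, 0.125); line through the centroid along +y
  c0 <- mesh_centroid(m)
  ax <- canonicalize_axis(list(point = c0, direction = c(0, 1, 0)), m)
  expect_equal(ax$start, c0 - c(0, 100, 0), tolerance = 1e-12)
  expect_equal(ax$end, c0 + c(0, 100, 0), tolerance = 1e-12)

  # worked projection: centroid at origin, line {x = 10, y = 0} along z
  m0 <- tri_mesh(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 1), c(0, -1, -1)))
  ax2 <- canonicalize_axis(list(point = c(10, 0, 55), direction = c(0, 0, 1)), m0)
  expect_equal(ax2$start, c(10, 0, -100), tolerance = 1e-12)
  expect_equal(ax2$end, c(10, 0, 100), tolerance = 1e-12)

  # 200 mm separation and orientation rule for arbitrary inputs
  set.seed(21)
  for (k in 1:25) {
    axk <- canonicalize_axis(list(point = rnorm(3, sd = 40),
                                  direction = rnorm(3)), m)
    expect_equal(sqrt(sum((axk$end - axk$start)^2)), 200, tolerance = 1e-9)
    u <- axk$direction
    expect_gt(u[which.max(abs(u))], 0)
  }
  # the sign rule flips a descending direction
  axf <- canonicalize_axis(list(point = c(0, 0, 0), direction = c(0, 0, -1)), m)
  expect_equal(axf$direction, c(0, 0, 1), tolerance = 1e-12)
})

test_that("axis comparison measures endpoint and angular discrepancy symmetrically", {
  m <- rand_mesh(12, seed = 5)
  # anchor the axis through the mesh centroid so canonical midpoints of
  # tilted variants coincide and the chord closed form is exact
  a <- canonicalize_axis(list(point = mesh_centroid(m),
                              direction = c(0.2, 0.9, 0.3)), m)
  expect_equal(compare_axes(a, a)$d_axis, 0, tolerance = 1e-12)

  # parallel offset of 2 mm perpendicular to the direction
  frame <- hingefit:::.normal_frame(a$direction)
  b <- canonicalize_axis(list(point = a$start + 2 * frame[, 1],
                              direction = a$direction), m)
  cab <- compare_axes(a, b)
  expect_equal(cab$d_axis, 2, tolerance = 1e-9)
  expect_equal(cab$angular_deviation, 0, tolerance = 1e-7)

  # axes crossing at their midpoints with a 1 degree tilt
  mid <- (a$start + a$end) / 2
  psi <- 1 * pi / 180
  u2 <- cos(psi) * a$direction + sin(psi) * frame[, 1]
  tilted <- canonicalize_axis(list(point = mid, direction = u2), m)
  ct <- compare_axes(a, tilted)
  expect_equal(ct$d_start, 2 * 100 * sin(psi / 2), tolerance = 1e-6)
  expect_equal(ct$d_end, 2 * 100 * sin(psi / 2), tolerance = 1e-6)
  expect_equal(ct$angular_deviation, 1, tolerance = 1e-9)

  # symmetry in all fields, and invariance to flipping the stored direction
  set.seed(77)
  for (k in 1:10) {
    x <- rand_canonical_axis(100 + k, m)
    y <- rand_canonical_axis(200 + k, m)
    cxy <- compare_axes(x, y); cyx <- compare_axes(y, x)
    expect_equal(unclass(cxy), unclass(cyx), tolerance = 1e-12)
    yf <- y; yf$start <- y$end; yf$end <- y$start; yf$direction <- -y$direction
    expect_equal(compare_axes(x, yf)$d_axis, cxy$d_axis, tolerance = 1e-12)
  }

  other <- rand_mesh(12, seed = 6, label = "other")
  b2 <- rand_canonical_axis(31, other)
  expect_error(compare_axes(a, b2), "different reference meshes")
  expect_error(compare_axes(a, axis_line(c(0, 0, 0), c(1, 1, 1))),
               "canonicalized")
})

test_that("axis extraction from exported cylinder meshes recovers the end-cap line", {
  cyl <- make_cylinder_mesh(c(0, 0, 0), c(0, 0, 50))
  ax <- axis_from_cylinder(cyl)
  expect_equal(ax$start, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(ax$end, c(0, 0, 50), tolerance = 1e-9)
  expect_equal(ax$direction, c(0, 0, 1), tolerance = 1e-9)

  tr <- c(12.5, -3, 8)
  cyl2 <- make_cylinder_mesh(c(0, 0, 0) + tr, c(0, 0, 50) + tr, caps = TRUE)
  ax2 <- axis_from_cylinder(cyl2)
  expect_equal(ax2$start, tr, tolerance = 1e-9)
  expect_equal(ax2$end, c(0, 0, 50) + tr, tolerance = 1e-9)

  u <- c(1, 1, 1) / sqrt(3)
  cyl3 <- make_cylinder_mesh(c(5, 1, -2), c(5, 1, -2) + 60 * u)
  ax3 <- axis_from_cylinder(cyl3)
  expect_equal(abs(sum(ax3$direction * u)), 1, tolerance = 1e-9)

  blob <- rand_mesh(40, seed = 13)
  expect_error(axis_from_cylinder(blob), "not a cylinder export")
})

test_that("axis mode coordinates separate offset, tilt and axial components", {
  m <- rand_mesh(15, seed = 8)
  a <- canonicalize_axis(list(point = mesh_centroid(m),
                              direction = c(0.1, 0.3, 0.94)), m)
  E <- hingefit:::.normal_frame(a$direction)

  off <- canonicalize_axis(list(point = a$start + 1.5 * E[, 1],
                                direction = a$direction), m)
  co <- axis_mode_coordinates(off, a, E)
  expect_equal(unname(co[c("offset_1", "offset_2")]), c(1.5, 0),
               tolerance = 1e-9)
  expect_equal(unname(co[c("tilt_1", "tilt_2")]), c(0, 0), tolerance = 1e-9)

  mid <- (a$start + a$end) / 2
  psi <- 2 * asin(0.8 / 200)
  u2 <- cos(psi) * a$direction + sin(psi) * E[, 2]
  tilt <- canonicalize_axis(list(point = mid, direction = u2), m)
  ct <- axis_mode_coordinates(tilt, a, E)
  expect_equal(unname(abs(ct["tilt_2"])), 0.8, tolerance = 1e-3)
  expect_lt(abs(ct["offset_1"]) + abs(ct["offset_2"]), 1e-6)
})
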