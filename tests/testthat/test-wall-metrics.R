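test_that("coincident meshes have zero thickness everywhere", {
  m <- cylinder_mesh(n_rings = 12, n_circ = 12)
  th <- ilt_thickness(m, m, radius = 3)
  # the expanded |a|^2+|b|^2-2a.b distance form loses ~sqrt(eps*|p|^2)
  # near zero, so "zero" is resolved only to ~1e-6 at these coordinates
  expect_equal(th$thickness, rep(0, nrow(m$nodes)), tolerance = 1e-5)
  th2 <- ilt_thickness(m, m, radius = 3, method = "nearest")
  expect_equal(th2$thickness, rep(0, nrow(m$nodes)), tolerance = 1e-12)
})

test_that("concentric cylinders recover the radial gap, never below it", {
  wall <- cylinder_mesh(radius = 13, length = 80, n_rings = 50, n_circ = 48)
  lumen <- cylinder_mesh(radius = 10, length = 80, n_rings = 50, n_circ = 48)
  th <- ilt_thickness(wall, lumen, radius = 4)
  # brute-force all-pairs check on a node subset: every in-radius distance
  # is >= 3, so the mean cannot undershoot the true gap
  sub <- seq(1, nrow(wall$nodes), by = 37)
  for (i in sub) {
    d <- sqrt(colSums((t(lumen$nodes) - wall$nodes[i, ])^2))
    keep <- d <= 4
    expect_equal(th$thickness[i], mean(d[keep]))
  }
  expect_true(all(th$thickness >= 3 - 1e-12))
  expect_lt(max(abs(th$thickness - 3)), 0.5 * mean_edge_length(wall))
  # point-to-surface variant: nearest distance is slightly under the radial
  # gap (chordal flattening of the inner cylinder), never above
  tn <- ilt_thickness(wall, lumen, radius = 4, method = "nearest")
  expect_true(all(tn$thickness <= 3 + 1e-12))
  expect_lt(max(abs(tn$thickness - 3)), 0.2)
})

test_that("widening the search radius never loses neighbors; errors are explicit", {
  wall <- cylinder_mesh(radius = 13, n_rings = 15, n_circ = 15)
  lumen <- cylinder_mesh(radius = 10, n_rings = 15, n_circ = 15)
  n1 <- ilt_thickness(wall, lumen, radius = 4)$n_neighbors
  n2 <- ilt_thickness(wall, lumen, radius = 8)$n_neighbors
  expect_true(all(n2 >= n1))
  expect_error(ilt_thickness(wall, lumen, radius = 0), "radius")
  # nodes without neighbors are missing, not zero
  far <- ilt_thickness(wall, lumen, radius = 1)
  expect_true(all(is.na(far$thickness)))
})

test_that("thickness is invariant under joint rigid motion", {
  wall <- cylinder_mesh(radius = 13, n_rings = 20, n_circ = 20)
  lumen <- cylinder_mesh(radius = 10, n_rings = 20, n_circ = 20)
  th <- ilt_thickness(wall, lumen, radius = 4)
  set.seed(3)
  rot <- random_rotation()
  tr <- c(-7, 2, 11)
  wall$nodes <- sweep(wall$nodes %*% t(rot), 2, tr, "+")
  lumen$nodes <- sweep(lumen$nodes %*% t(rot), 2, tr, "+")
  th2 <- ilt_thickness(wall, lumen, radius = 4)
  expect_equal(th2$thickness, th$thickness, tolerance = 1e-9)
})

test_that("TAWSS integrates the magnitude over one period", {
  times <- seq(0, 0.9, by = 0.1)
  const <- replicate(10, cbind(1, 0, 0), simplify = FALSE)
  expect_equal(tawss(const, times), 1)

  # alternating 0 and 2 Pa: hand trapezoid with periodic closure gives 1
  alt <- lapply(rep(c(0, 2), 5), function(m) cbind(m, 0, 0))
  expect_equal(tawss(alt, times), 1)

  # homogeneity and reduction to the arithmetic mean at uniform spacing
  set.seed(5)
  mags <- lapply(1:10, function(i) matrix(rnorm(6 * 3), 6))
  t1 <- tawss(mags, times)
  t3 <- tawss(lapply(mags, function(m) 3 * m), times)
  expect_equal(t3, 3 * t1, tolerance = 1e-12)
  mag_mat <- sapply(mags, function(m) sqrt(rowSums(m^2)))
  expect_equal(t1, rowMeans(mag_mat), tolerance = 1e-12)

  expect_error(tawss(const[1], times[1]), "2 phases")
  expect_error(tawss(const, rev(times)), "increasing")
})

test_that("deformation gradient recovers affine maps and rigid motions", {
  tri <- rbind(c(0, 0, 0), c(2, 0, 0), c(0.5, 1.5, 0))
  expect_equal(face_deformation_gradient(tri, tri), diag(2))
  expect_equal(face_deformation_gradient(tri, 1.1 * tri), 1.1 * diag(2))
  set.seed(11)
  for (i in 1:20) {
    rot <- random_rotation()
    def <- sweep(tri %*% t(rot), 2, rnorm(3), "+")
    f <- face_deformation_gradient(tri, def)
    expect_equal(crossprod(f), diag(2), tolerance = 1e-12)
  }
  expect_error(face_deformation_gradient(tri, tri[c(1, 1, 1), ]),
               "degenerate")
})

test_that("Green-Lagrange strain has its closed forms", {
  expect_equal(green_lagrange(diag(2)), matrix(0, 2, 2))
  f <- 1.1 * diag(2)
  e <- green_lagrange(f)
  expect_equal(max_principal_strain(e), (1.1^2 - 1) / 2)
  # rotations give zero strain to machine precision
  set.seed(13)
  for (i in 1:20) {
    a <- runif(1, 0, 2 * pi)
    r <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    expect_lt(abs(max_principal_strain(green_lagrange(r))), 1e-12)
  }
  expect_error(green_lagrange(matrix(c(1, 0, 0, -1), 2)), "determinant")
  expect_error(green_lagrange(matrix(c(1, 0, 0, NA), 2)), "finite")
})

test_that("strain is objective: rigid motions do not change the eigenvalues", {
  aaa <- make_aaa(small_aaa_config(n_axial_rings = 10, n_circ = 10))
  base_strain <- principal_strain(aaa$outer_wall, aaa$phase_positions)
  set.seed(17)
  rot <- random_rotation()
  tr <- c(4, -9, 2)
  moved <- lapply(aaa$phase_positions, function(p)
    sweep(p %*% t(rot), 2, tr, "+"))
  # appending a rigid motion to every phase (including the reference)
  joint <- principal_strain(aaa$outer_wall, moved)
  expect_equal(joint$max_principal, base_strain$max_principal,
               tolerance = 1e-10)
  # rigid motion of the deformed phases only: eigenvalues still unchanged
  mixed <- c(aaa$phase_positions[1], moved[-1])
  expect_equal(principal_strain(aaa$outer_wall, mixed)$max_principal,
               base_strain$max_principal, tolerance = 1e-10)
})

test_that("per-face cycle maximum matches the planted closed form on the generator", {
  aaa <- make_aaa(small_aaa_config())
  st <- principal_strain(aaa$outer_wall, aaa$phase_positions)
  expect_equal(st$max_principal, aaa$truth_max_principal_strain,
               tolerance = 1e-8)
  # per-phase principal strain equals the phase's (lambda^2-1)/2
  lam <- 1 + aaa$config$pulsatility *
    0.5 * (1 - cos(2 * pi * aaa$phase_times / aaa$config$cycle_s))
  for (k in seq_along(lam))
    expect_equal(st$per_phase[, k],
                 rep((lam[k]^2 - 1) / 2, nrow(aaa$outer_wall$faces)),
                 tolerance = 1e-10)
})
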