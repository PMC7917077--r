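test_that("centerline of a straight cylinder lies on its axis", {
  m <- cylinder_mesh(radius = 10, length = 100)
  cl <- compute_centerline(m, n_samples = 40)
  expect_lt(max(abs(cl$points[, 1:2])), 1e-6)
  expect_true(all(diff(cl$arclength) > 0))

  # translation equivariance
  m2 <- cylinder_mesh(radius = 10, length = 100, center = c(5, 5, 0))
  cl2 <- compute_centerline(m2, n_samples = 40)
  expect_lt(max(abs(cl2$points[, 1] - 5)), 1e-6)
  expect_lt(max(abs(cl2$points[, 2] - 5)), 1e-6)
})

test_that("centerline of a curved tube follows the analytic arc", {
  tt <- torus_tube_mesh()
  cl <- compute_centerline(tt$mesh, n_samples = 40)
  # distance from each centerline point to the (densely sampled) true arc
  arc <- tt$arc(seq(0, tt$arc_span, length.out = 4000))
  d <- apply(cl$points, 1L, function(p)
    sqrt(min(colSums((t(arc) - p)^2))))
  expect_lt(max(d), 0.5 * mean_edge_length(tt$mesh))
})

test_that("degenerate input is rejected", {
  flat <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(c(1, 2, 3), 1))
  expect_error(compute_centerline(flat, n_samples = 10, n_slices = 1),
               "sliceable")
})

test_that("default patching yields 24 non-empty patches partitioning the wall", {
  aaa <- make_aaa(small_aaa_config())
  cl <- compute_centerline(aaa$lumen)
  pa <- assign_patches(aaa$outer_wall, cl)
  expect_identical(nlevels(pa$patch), 24L)
  expect_true(all(table(pa$patch) > 0))
  expect_false(anyNA(pa$patch))                     # every face assigned once
  total <- sum(face_areas(aaa$outer_wall))
  expect_lt(abs(sum(pa$patches$area_mm2) - total) / total, 1e-9)
  # quadrants match the generator's ground-truth labels
  expect_identical(as.character(pa$quadrant), aaa$truth_patch_quadrant)
})

test_that("quadrant naming follows the patient axes with deterministic ties", {
  m <- cylinder_mesh(radius = 10, length = 60, n_rings = 20, n_circ = 32)
  cl <- compute_centerline(m)
  pa <- assign_patches(m, cl, n_axial = 2)
  fc <- face_centroids(m)
  # +x = left, +y = posterior; anterior (-y) with +x offset must be LA
  i <- which.max(fc[, 1] - fc[, 2])
  expect_match(as.character(pa$patch[i]), "^LA")
  i <- which.min(fc[, 1] + fc[, 2])
  expect_match(as.character(pa$patch[i]), "^RA")
  # joint rigid motion of mesh and axes leaves the assignment unchanged
  set.seed(7)
  rot <- random_rotation()
  tr <- c(12, -4, 30)
  m2 <- m
  m2$nodes <- sweep(m$nodes %*% t(rot), 2, tr, "+")
  cl2 <- compute_centerline(m2)
  pa2 <- assign_patches(m2, cl2, n_axial = 2,
                        axes = list(left = as.vector(rot %*% c(1, 0, 0)),
                                    posterior = as.vector(rot %*% c(0, 1, 0))))
  expect_identical(as.character(pa$patch), as.character(pa2$patch))
})

test_that("n_axial controls the patch count and empty patches warn", {
  m <- cylinder_mesh(n_rings = 16, n_circ = 16)
  cl <- compute_centerline(m)
  pa3 <- assign_patches(m, cl, n_axial = 3)
  expect_identical(nlevels(pa3$patch), 12L)
})

test_that("patch averages are area-weighted and conservative", {
  aaa <- make_aaa(small_aaa_config())
  cl <- compute_centerline(aaa$lumen)
  pa <- assign_patches(aaa$outer_wall, cl)
  nf <- nrow(aaa$outer_wall$faces)

  # constant preservation
  expect_equal(unname(patch_average(rep(3.5, nf), pa)), rep(3.5, 24))

  # hand-computed weighted mean: two faces with areas 1 and 3, values 0, 4
  m <- surface_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0), c(0, 3, 0),
                          c(-2, 0, 0)),
                    rbind(c(1, 2, 3), c(1, 4, 5)))
  expect_equal(face_areas(m), c(1, 3))
  fake <- structure(list(patch = factor(c("A", "A")), face_area = face_areas(m)),
                    class = "patch_assignment")
  expect_equal(unname(patch_average(c(0, 4), fake)), 3)

  # conservation: area-weighted mean of patch means = global weighted mean
  set.seed(1)
  v <- runif(nf)
  pm <- patch_average(v, pa)
  w <- pa$patches$area_mm2
  expect_equal(sum(pm * w) / sum(w),
               weighted.mean(v, face_areas(aaa$outer_wall)),
               tolerance = 1e-12)

  # affine equivariance
  expect_equal(patch_average(2 * v + 1, pa), 2 * pm + 1, tolerance = 1e-12)

  # NA values are excluded, not imputed
  v2 <- v
  v2[1:10] <- NA
  expect_false(anyNA(patch_average(v2, pa)))
  expect_error(patch_average(v[-1], pa), "length")
})
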