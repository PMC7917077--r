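test_that("generated surfaces are consistent and the lumen sits inside the wall", {
  aaa <- make_aaa(small_aaa_config())
  expect_s3_class(aaa$outer_wall, "surface_mesh")
  expect_identical(dim(aaa$outer_wall$nodes), dim(aaa$lumen$nodes))
  expect_identical(aaa$outer_wall$faces, aaa$lumen$faces)
  # lumen strictly inside wherever the planted gap is positive
  rw <- sqrt(rowSums(aaa$outer_wall$nodes[, 1:2]^2))
  rl <- sqrt(rowSums(aaa$lumen$nodes[, 1:2]^2))
  pos <- aaa$truth_ilt > 0
  expect_true(all(rl[pos] < rw[pos]))
  expect_equal(rw - rl, aaa$truth_ilt, tolerance = 1e-12)
  # truth fields sized consistently
  expect_length(aaa$truth_ilt, nrow(aaa$outer_wall$nodes))
  expect_length(aaa$truth_max_principal_strain, nrow(aaa$outer_wall$faces))
  expect_length(aaa$truth_patch_quadrant, nrow(aaa$outer_wall$faces))
  # reference phase equals the wall nodes, times span one cycle
  expect_equal(aaa$phase_positions[[1]], aaa$outer_wall$nodes,
               ignore_attr = TRUE)
  expect_true(all(diff(aaa$phase_times) > 0))
})

test_that("zero pulsatility means zero planted strain and identity motion", {
  aaa <- make_aaa(small_aaa_config(pulsatility = 0))
  expect_true(all(aaa$truth_max_principal_strain == 0))
  for (p in aaa$phase_positions)
    expect_equal(p, aaa$outer_wall$nodes, ignore_attr = TRUE)
})

test_that("a constant 2 mm gap on a straight cylinder is recovered by brute-force distances", {
  cfg <- small_aaa_config(neck_radius = 14, max_radius = 14,
                          ilt_profile = function(s, theta) 2 + 0 * s,
                          n_axial_rings = 30, n_circ = 30)
  aaa <- make_aaa(cfg)
  expect_equal(aaa$truth_ilt, rep(2, nrow(aaa$outer_wall$nodes)))
  # brute-force: nearest lumen point from every wall node is the planted gap
  # (within the chordal discretization error of the inner cylinder)
  d2 <- outer(rowSums(aaa$outer_wall$nodes^2), rowSums(aaa$lumen$nodes^2),
              "+") - 2 * aaa$outer_wall$nodes %*% t(aaa$lumen$nodes)
  nearest <- sqrt(apply(pmax(d2, 0), 1L, min))
  expect_true(all(nearest >= 2 - 1e-9))
  expect_lt(max(abs(nearest - 2)), 0.5 * mean_edge_length(aaa$lumen))
})

test_that("same seed gives identical output; config invariants are enforced", {
  cfg <- small_aaa_config(seed = 42L)
  expect_identical(make_aaa(cfg), make_aaa(cfg))
  expect_error(aaa_config(neck_radius = -1), "neck_radius")
  expect_error(aaa_config(max_radius = 5, neck_radius = 10), "max_radius")
  expect_error(aaa_config(n_circ = 2), "n_circ")
  expect_error(aaa_config(n_phases = 1), "n_phases")
  expect_error(aaa_config(pulsatility = -0.1), "pulsatility")
  expect_error(make_aaa(small_aaa_config(
    ilt_profile = function(s, theta) -1 + 0 * s)), "non-negative")
  expect_error(make_aaa(small_aaa_config(
    neck_radius = 3, max_radius = 3,
    ilt_profile = function(s, theta) 5 + 0 * s)), "lumen")
})

test_that("WSS magnitude decreases with local lumen radius and peaks at wss_peak", {
  aaa <- make_aaa(small_aaa_config(wss_peak = 2))
  mags <- sapply(aaa$wss_series, function(w) sqrt(rowSums(w^2)))
  expect_equal(max(mags), 2, tolerance = 1e-12)
  fc <- face_centroids(aaa$lumen)
  r <- sqrt(fc[, 1]^2 + fc[, 2]^2)
  peak <- mags[, which.max(colSums(mags))]
  expect_lt(cor(r, peak, method = "spearman"), -0.9)
})

test_that("synthetic curves plant the failure point and hysteresis exactly", {
  cfg <- curve_config(failure_stress = 0.5, failure_mode = "peak",
                      hysteresis_fraction = 0, noise_sd = 0)
  cv <- make_curve(cfg)
  load <- cv[cv$branch == "loading", ]
  expect_true(all(diff(load$stress_MPa) > 0))        # monotone to failure
  # brute-force scan of the emitted samples confirms the planted maximum
  expect_equal(max(cv$stress_MPa), 0.5, tolerance = 1e-12)
  expect_equal(energy_loss(cv[cv$branch == "loading", 1:2],
                           cv[cv$branch == "unloading", 1:2]), 0)

  cfg2 <- curve_config(failure_stress = 0.8, hysteresis_fraction = 0.4,
                       noise_sd = 0, failure_mode = "discontinuity")
  cv2 <- make_curve(cfg2)
  load2 <- cv2[cv2$branch == "loading", ]
  runmax <- cummax(load2$stress_MPa)
  expect_true(any(load2$stress_MPa < 0.98 * runmax))  # planted discontinuity
  expect_identical(make_curve(cfg2), make_curve(cfg2))
  expect_error(curve_config(hysteresis_fraction = 1), "hysteresis_fraction")
  expect_error(curve_config(failure_stress = 0), "failure_stress")
})
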