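# Generators: pure functions of spec + seed, exact ground-truth metadata.

test_that("rod lattice honours its spec and is deterministic", {
  spec <- rod_lattice_spec(shape = c(48, 48, 48), rod_radius = 2, spacing = 12,
                           seed = 7)
  v1 <- make_rod_lattice(spec)
  v2 <- make_rod_lattice(spec)
  expect_identical(v1$voxels, v2$voxels)
  expect_true(v1$binary)
  expect_setequal(unique(as.vector(v1$voxels)), c(0, 255))
  expect_equal(v1$meta$bvtv_exact, sum(v1$voxels == 255) / length(v1$voxels))
  expect_equal(v1$meta$true_axis, c(0, 0, 1))
  expect_equal(v1$meta$nominal_thickness_vox, 4)

  expect_error(rod_lattice_spec(rod_radius = 0.5), "rod_radius")
  expect_error(rod_lattice_spec(rod_radius = 3, spacing = 5), "spacing")
  expect_error(make_rod_lattice(rod_lattice_spec(shape = c(8, 8, 8))),
               "too small")
})

test_that("rod lattice dominant axis matches primary_axis (MIL argmax oracle)", {
  for (ax in list(c(0, 0, 1), sagittal_axis(20))) {
    v <- make_rod_lattice(rod_lattice_spec(shape = c(64, 64, 64),
                                           primary_axis = ax, seed = 11))
    # brute force: direction of maximum MIL over a dense hemisphere set
    samp <- mil_directions_3d(v, n_directions = 541L, seed = 2)
    best <- unlist(samp[which.max(samp$mil), c("nx", "ny", "nz")])
    expect_lt(axis_angle_deg(best, ax), 3)
  }
})

test_that("secondary_fill = 1 gives an isotropic lattice (DA in [1, 1.1])", {
  v <- make_rod_lattice(rod_lattice_spec(shape = c(64, 64, 64), spacing = 8,
                                         rod_radius = 1.6, secondary_fill = 1,
                                         jitter_sd = 0.9, seed = 2))
  da <- fabric_voi(v)$da
  expect_gte(da, 1)
  expect_lte(da, 1.1)
})

test_that("anisotropic field hits its BV/TV target and validates inputs", {
  v <- make_anisotropic_field(shape = c(48, 48, 48), bvtv_target = 0.30,
                              elongation = 2, seed = 3)
  expect_gte(v$meta$bvtv_exact, 0.295)
  expect_lte(v$meta$bvtv_exact, 0.305)
  expect_equal(v$meta$bvtv_exact, mean(v$voxels == 255))
  expect_error(make_anisotropic_field(bvtv_target = 0), "bvtv_target")
  expect_error(make_anisotropic_field(elongation = 0.5), "elongation")
  # determinism
  v2 <- make_anisotropic_field(shape = c(48, 48, 48), bvtv_target = 0.30,
                               elongation = 2, seed = 3)
  expect_identical(v$voxels, v2$voxels)
})

test_that("phantoms carry exact construction metadata", {
  pl <- make_phantom("plate", thickness = 5)
  expect_equal(pl$meta$thickness_vox, 5)
  expect_equal(sum(pl$voxels == 255), 32 * 32 * 5)
  ring <- make_phantom("voxel_ring")
  expect_equal(ring$meta$euler, 0)
  expect_equal(sum(ring$voxels == 255), 8)
  tc <- make_phantom("two_cubes")
  expect_equal(tc$meta$euler, 2)
  expect_error(make_phantom("plate", thickness = 0), "thickness")
})

test_that("Watson axial sampler concentrates and is deterministic", {
  mu <- c(1, 1, 1) / sqrt(3)
  tight <- sample_axes(mu, 5e4, 50, seed = 1)
  expect_lt(max(apply(tight, 1, axis_angle_deg, b = mu)), 1)
  a1 <- sample_axes(mu, 20, 100, seed = 9)
  a2 <- sample_axes(mu, 20, 100, seed = 9)
  expect_identical(a1, a2)
  # dispersion decreases with concentration; centroid consistent at n = 500
  disp <- function(k) mean(apply(sample_axes(mu, k, 300, seed = 4), 1,
                                 axis_angle_deg, b = mu))
  expect_gt(disp(5), disp(50))
  cen <- spherical_centroid(sample_axes(mu, 10, 500, seed = 5))
  expect_lt(axis_angle_deg(cen, mu), 3)
  expect_error(sample_axes(c(0, 0, 0), 10, 5), "non-zero")
})

test_that("gait generator stores analytic windowed ground truth", {
  # constant profile: windowed mean equals the constant
  tr <- make_gait_trial(gait_trial_spec(angle_profile = function(s) 85.6))
  expect_equal(tr$meta$true_mean_angle, 85.6)
  # exactly two local maxima above the trough
  g <- tr$meta$grf_clean
  locmax <- which(diff(sign(diff(g))) == -2) + 1
  expect_equal(sum(g[locmax] > 0.7 + 1e-9), 2)
  # trough above threshold: one contiguous window covering both peaks
  tr2 <- make_gait_trial(gait_trial_spec(peak1 = 1.1, peak2 = 1.1, trough = 0.8))
  w <- peak_loading_window(tr2$meta$grf_clean)
  expect_equal(attr(w, "n_intervals"), 1L)
  s <- tr2$time_force / max(tr2$time_force)
  expect_true(all(w[which.min(abs(s - 0.25))], w[which.min(abs(s - 0.75))]))
  # symmetric linear ramp: windowed mean = midstance angle
  tr3 <- make_gait_trial(gait_trial_spec(angle_profile = function(s) 70 + 20 * s))
  expect_equal(tr3$meta$true_mean_angle, 80, tolerance = 1e-3)
  expect_error(gait_trial_spec(trough = 1.2, peak1 = 1.1, peak2 = 1.1),
               "double peak")
})
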