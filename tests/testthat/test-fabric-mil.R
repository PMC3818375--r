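# MIL profiles, 2D/3D principal orientation, fabric tensor fit.

test_that("2D MIL closed form on periodic stripes; parallel lines capped", {
  # stripes along z (alpha = 0 ... stripes vary along z): lines at theta = 90
  # cross one interface per half period -> MIL = period/2 = 4 voxels
  p <- mil_profile_2d(lapply(1:5, function(i) mk_stripes(128, 0)))
  expect_equal(p$mil[p$theta_deg == 90], 4, tolerance = 0.05 * 4)
  # lines parallel to the stripes: no crossings, capped and flagged
  expect_true(p$capped[p$theta_deg == 0])
  expect_gt(p$mil[p$theta_deg == 0], 50)
  expect_error(mil_profile_2d(list(matrix(255, 10, 10))), "interface")
  expect_error(mil_profile_2d(list(mk_stripes(64, 0)), omega = 7), "omega")
})

test_that("2D MIL is isotropic on band-limited random fields", {
  sl <- lapply(1:10, function(s) smooth_noise_slice(256, 2, s))
  p <- mil_profile_2d(sl, seed = 1)
  expect_lt(max(p$mil) / min(p$mil), 1.05)
})

test_that("pto_2d recovers stripe angles and is rotation-equivariant", {
  for (al in c(80, 90, 97.7)) {
    o <- pto_2d(mil_profile_2d(lapply(1:10, function(i) mk_stripes(128, al))))
    expect_lt(abs(o$alpha - al), 0.5)
    expect_false(o$unstable)
  }
  # equivariance: rotating the pattern by +7.7 degrees shifts alpha by +7.7
  o90 <- pto_2d(mil_profile_2d(lapply(1:10, function(i) mk_stripes(128, 90))))
  o977 <- pto_2d(mil_profile_2d(lapply(1:10, function(i) mk_stripes(128, 97.7))))
  expect_equal(o977$alpha - o90$alpha, 7.7, tolerance = 0.5)
  # isotropic field: flagged unstable, no angle asserted
  oi <- pto_2d(mil_profile_2d(lapply(1:10, function(s)
    smooth_noise_slice(256, 2, s)), seed = 1))
  expect_true(oi$unstable)
})

test_that("3D MIL: rod argmax, isotropy bound, degenerate masks", {
  v <- make_rod_lattice(rod_lattice_spec(shape = c(64, 64, 64), seed = 5))
  samp <- mil_directions_3d(v, seed = 1)
  best <- unlist(samp[which.max(samp$mil), c("nx", "ny", "nz")])
  expect_lt(axis_angle_deg(best, c(0, 0, 1)), 3)

  iso <- make_anisotropic_field(elongation = 1, seed = 5)
  s2 <- mil_directions_3d(iso, seed = 1)
  expect_lte(max(s2$mil) / min(s2$mil), 1.15)

  full <- voxel_volume(array(255L, c(16, 16, 16)), 1, binary = TRUE)
  expect_error(mil_directions_3d(full), "both")
})

test_that("fit_fabric inverts exact ellipsoids and flags isotropy", {
  dirs <- fabricgait:::hemisphere_directions(120)
  # MIL semi-axes (2, 1, 1) with the long axis along z
  H <- diag(c(1, 1, 1 / 4))
  mil <- 1 / sqrt(rowSums((dirs %*% H) * dirs))
  f <- fit_fabric(data.frame(nx = dirs[, 1], ny = dirs[, 2], nz = dirs[, 3],
                             mil = mil))
  expect_equal(f$da, 2, tolerance = 1e-6)
  expect_lt(axis_angle_deg(f$pto, c(0, 0, 1)), 1e-4)
  expect_true(all(abs(crossprod(f$eigenvectors) - diag(3)) < 1e-8))

  # all MIL equal r -> H = I/r^2, DA = 1
  r <- 3.7
  fi <- fit_fabric(data.frame(nx = dirs[, 1], ny = dirs[, 2], nz = dirs[, 3],
                              mil = r))
  expect_equal(fi$da, 1, tolerance = 1e-9)
  expect_equal(fi$tensor, diag(3) / r^2, tolerance = 1e-9)

  expect_error(fit_fabric(data.frame(nx = 1, ny = 0, nz = 0, mil = 1)), ">= 6")
})

test_that("fit_fabric is robust to multiplicative noise (Monte-Carlo)", {
  dirs <- fabricgait:::hemisphere_directions(257)
  H <- diag(c(1, 1, 1 / 4))
  mil0 <- 1 / sqrt(rowSums((dirs %*% H) * dirs))
  da_err <- ang_err <- numeric(100)
  for (s in 1:100) {
    set.seed(s)
    mil <- mil0 * (1 + stats::rnorm(length(mil0), 0, 0.02))
    f <- fit_fabric(data.frame(nx = dirs[, 1], ny = dirs[, 2], nz = dirs[, 3],
                               mil = mil))
    da_err[s] <- abs(f$da - 2) / 2
    ang_err[s] <- axis_angle_deg(f$pto, c(0, 0, 1))
  }
  expect_lt(max(da_err), 0.05)
  expect_lt(max(ang_err), 2)
})

test_that("fabric is rotation-equivariant and relabeling/spacing invariant", {
  # equivariance: the PTO of the rotated lattice equals R applied to the PTO
  # of the unrotated one (same generator seed)
  ax <- sagittal_axis(25)
  mk <- function(axis) make_rod_lattice(rod_lattice_spec(
    shape = c(96, 96, 96), spacing = 8, rod_radius = 1.6, jitter_sd = 0.9,
    primary_axis = axis, seed = 6))
  voi0 <- extract_voi(mk(c(0, 0, 1)), spherical_voi(rep(47.5, 3), 40))
  voi1 <- extract_voi(mk(ax), spherical_voi(rep(47.5, 3), 40))
  f0 <- fabric_voi(voi0$volume, voi0$mask, seed = 2)
  f1 <- fabric_voi(voi1$volume, voi1$mask, seed = 2)
  R <- fabricgait:::rotation_between(c(0, 0, 1), ax)
  expect_lt(axis_angle_deg(f1$pto, as.vector(R %*% f0$pto)), 2)
  voi <- voi1; f <- f1

  # relabeling 0/255 -> 0/1 and spacing rescaling leave DA and PTO unchanged
  v01 <- voxel_volume((voi$volume$voxels > 0) * 1L, 65.6, binary = FALSE)
  v01$binary <- TRUE # bypass the {0,255} storage convention deliberately
  f01 <- fabric_voi(v01, voi$mask, seed = 2)
  expect_equal(f01$da, f$da)
  expect_equal(f01$pto, f$pto)
})

test_that("2D-PTO agrees with the sagittal projection of the 3D PTO", {
  ax <- sagittal_axis(12)
  v <- make_rod_lattice(rod_lattice_spec(shape = c(96, 96, 96),
                                         primary_axis = ax, seed = 4))
  voi <- extract_voi(v, spherical_voi(rep(47.5, 3), 40))
  f <- fabric_voi(voi$volume, voi$mask)
  o <- pto_2d(mil_profile_2d(middle_sagittal_slices(voi$volume),
                             middle_sagittal_slices(voi$mask)))
  proj <- c(f$pto[1], f$pto[3])
  alpha3d <- (atan2(proj[2], proj[1]) * 180 / pi) %% 180
  d <- abs(o$alpha - alpha3d)
  expect_lt(min(d, 180 - d), 4)
})
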