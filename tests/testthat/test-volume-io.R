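# Stack I/O, reorientation, binarization, VOI extraction.

test_that("TIFF stack round trip is bit-exact for 8- and 16-bit volumes", {
  set.seed(1)
  v <- voxel_volume(array(sample(c(0L, 255L), 8000, TRUE), c(20, 20, 20)),
                    32.8, binary = TRUE)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_stack(v, tf)
  v2 <- read_stack(tf)
  expect_identical(v2$voxels, v$voxels)
  expect_equal(v2$spacing_um, 32.8)
  expect_true(v2$binary)

  g <- voxel_volume(array(sample(0:65535, 4000, TRUE), c(20, 10, 20)), 30)
  tg <- withr::local_tempfile(fileext = ".tif")
  write_stack(g, tg)
  expect_identical(read_stack(tg)$voxels, g$voxels)
})

test_that("ragged stacks and missing spacing are errors", {
  tf <- withr::local_tempfile(fileext = ".tif")
  fabricgait:::write_tiff_pages(list(matrix(0L, 8, 8), matrix(0L, 8, 9)), tf)
  expect_error(read_stack(tf, spacing_um = 10), "ragged")
  t2 <- withr::local_tempfile(fileext = ".tif")
  fabricgait:::write_tiff_pages(list(matrix(0L, 8, 8)), t2)
  expect_error(read_stack(t2), "spacing")
})

test_that("long axis estimation: cylinder, rotated cylinder, degenerate cube", {
  cyl <- make_phantom("cylinder", shape = c(40, 40, 80), diameter = 15)
  ax <- estimate_long_axis(cyl)
  expect_lt(axis_angle_deg(ax, c(0, 0, 1)), 0.5)
  expect_false(attr(ax, "degenerate"))

  target <- sagittal_axis(30)
  rot <- reorient(cyl, c(0, 0, 1), out_dim = c(80, 80, 80))
  # rotate the (padded) cylinder so its axis lies along `target`
  R <- fabricgait:::rotation_between(c(0, 0, 1), target)
  arr <- array(fabricgait:::cpp_affine_resample(
    as.vector(rot$voxels / 255), c(80L, 80L, 80L), c(80L, 80L, 80L),
    t(R), rep(39.5, 3), rep(39.5, 3), 0) >= 0.5, rep(80, 3)) * 255
  tilted <- voxel_volume(arr, 32.8, binary = TRUE)
  ax2 <- estimate_long_axis(tilted)
  expect_lt(axis_angle_deg(ax2, target), 1)

  cube <- make_phantom("solid_cube", side = 12)
  expect_warning(ax3 <- estimate_long_axis(cube), "degenerate")
  expect_true(attr(ax3, "degenerate"))
  empty <- voxel_volume(array(0L, c(5, 5, 5)), 1, binary = TRUE)
  expect_error(estimate_long_axis(empty), "empty")
})

test_that("reorient: identity, interpolation loss bound, composition with MIL", {
  cyl <- make_phantom("cylinder", shape = c(40, 40, 40), diameter = 15)
  expect_identical(reorient(cyl, c(0, 0, 1))$voxels, cyl$voxels)

  # in-frame object: bone count change < 2 % under a 30 degree rotation
  r <- reorient(cyl, sagittal_axis(30))
  expect_lt(abs(sum(r$voxels > 0) - sum(cyl$voxels > 0)) / sum(cyl$voxels > 0),
            0.02)

  # rotate there and back: >= 98 % voxel agreement away from the frame edge
  rl <- make_rod_lattice(rod_lattice_spec(shape = c(80, 80, 80),
                                          primary_axis = sagittal_axis(30)))
  fwd <- reorient(rl, sagittal_axis(30))
  back <- reorient(fwd, sagittal_axis(-30))
  inner <- function(v) v$voxels[21:60, 21:60, 21:60] > 0
  expect_gte(mean(inner(back) == inner(rl)), 0.98)

  # after reorientation the downstream 3D PTO is along +z
  f <- fabric_voi(extract_voi(fwd, spherical_voi(rep(39.5, 3), 34))$volume)
  expect_lt(axis_angle_deg(f$pto, c(0, 0, 1)), 2)
})

test_that("gradient binarization recovers phantoms and ignores brightness", {
  ph <- make_phantom("cylinder", shape = c(40, 40, 40), diameter = 15)
  set.seed(2)
  gray <- voxel_volume(array(pmax(0, ifelse(ph$voxels > 0, 200, 20) +
                                    round(stats::rnorm(40^3, 0, 3))),
                             c(40, 40, 40)), 32.8)
  b1 <- binarize_gradient(gray)
  expect_gte(mean((b1$voxels > 0) == (ph$voxels > 0)), 0.99)
  b2 <- binarize_gradient(voxel_volume(gray$voxels + 50, 32.8))
  expect_identical(b1$voxels, b2$voxels)
  expect_error(binarize_gradient(voxel_volume(array(7, c(8, 8, 8)), 1)),
               "no edges")
})

test_that("VOI extraction: mask enumeration, background VOI, bounds", {
  vol <- voxel_volume(array(0L, c(31, 31, 31)), 32.8, binary = TRUE)
  ev <- extract_voi(vol, spherical_voi(c(15, 15, 15), 11))
  co <- expand.grid(x = 0:30, y = 0:30, z = 0:30)
  n_in <- sum((co$x - 15)^2 + (co$y - 15)^2 + (co$z - 15)^2 <= 5.5^2)
  expect_equal(sum(ev$mask), n_in)
  expect_equal(bv_tv(ev$volume, ev$mask), 0) # VOI entirely in background
  expect_error(extract_voi(vol, spherical_voi(c(0, 0, 0), 11)), "bounds")
  expect_error(spherical_voi(c(5, 5, 5), 8), "diameter")
})

test_that("middle sagittal slices: indexing contract, symmetry, n = 1", {
  arr <- array(0L, c(5, 11, 5))
  for (y in 1:11) arr[, y, ] <- y * 10L
  v <- voxel_volume(arr, 1)
  sl <- middle_sagittal_slices(v, 10)
  expect_length(sl, 10)
  expect_equal(unique(as.vector(sl[[1]])), 10)  # 0-based slice 0
  expect_equal(unique(as.vector(sl[[10]])), 100) # 0-based slice 9
  one <- middle_sagittal_slices(v, 1)
  expect_equal(unique(as.vector(one[[1]])), 60) # exact midplane
  expect_error(middle_sagittal_slices(voxel_volume(array(0, c(4, 4, 4)), 1), 10),
               "smaller")
  # mirror-symmetric phantom: slice k mirrors slice n-1-k
  pl <- make_phantom("plate", shape = c(16, 12, 16), thickness = 4)
  ms <- middle_sagittal_slices(pl, 10)
  for (k in 1:5) expect_identical(ms[[k]], ms[[10 - k + 1]])
})
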