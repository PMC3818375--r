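# Synthetic voxel volumes with known ground truth. Every generator is a pure
# function of its spec and seed; ground-truth metadata (axis, BV/TV, nominal
# thickness, Euler number) is exact by construction and stored in `meta`,
# never re-estimated.

#' Rod lattice specification
#'
#' A jittered square lattice of parallel cylindrical struts with a single
#' dominant axis, standing in for trabecular bone whose struts align with the
#' dominant compressive load direction. `secondary_fill` adds cross struts
#' perpendicular to the primary axis (1 with equal spacing along all three
#' axes gives an isotropic control).
#'
#' @param shape voxels per axis (3 integers).
#' @param rod_radius strut radius in voxels (>= 1).
#' @param spacing distance between rod centrelines in voxels (> 2 * rod_radius).
#' @param primary_axis unit 3-vector: the ground-truth principal trabecular
#'   orientation.
#' @param secondary_fill fraction in `[0, 1]` of cross rods added along each
#'   of the two axes perpendicular to `primary_axis` (1 = full lattices along
#'   x, y and z, an isotropic control).
#' @param jitter_sd per-rod centreline jitter SD in voxels; breaks aliasing
#'   between test-line grids and the rod spacing.
#' @param seed integer RNG seed.
#' @export
rod_lattice_spec <- function(shape = c(64, 64, 64), rod_radius = 2,
                             spacing = 12, primary_axis = c(0, 0, 1),
                             secondary_fill = 0, jitter_sd = 0.75, seed = 1L) {
  if (rod_radius < 1) stop("rod_radius must be >= 1")
  if (spacing <= 2 * rod_radius) stop("spacing must exceed 2 * rod_radius")
  if (secondary_fill < 0 || secondary_fill > 1)
    stop("secondary_fill must be in [0, 1]")
  structure(list(shape = as.integer(shape), rod_radius = rod_radius,
                 spacing = spacing, primary_axis = unit3(primary_axis),
                 secondary_fill = secondary_fill, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "rod_lattice_spec")
}

# 2D cross-section of a jittered rod lattice on an n1 x n2 grid
rod_cross_section <- function(n1, n2, spacing, radius, jitter_sd, keep_frac = 1) {
  c1 <- seq(spacing / 2, n1 - 1 + spacing, by = spacing)
  c2 <- seq(spacing / 2, n2 - 1 + spacing, by = spacing)
  centers <- expand.grid(a = c1, b = c2)
  if (keep_frac < 1) {
    k <- round(nrow(centers) * keep_frac)
    if (k == 0) return(matrix(FALSE, n1, n2))
    centers <- centers[sample.int(nrow(centers), k), , drop = FALSE]
  }
  centers$a <- centers$a + stats::rnorm(nrow(centers), 0, jitter_sd)
  centers$b <- centers$b + stats::rnorm(nrow(centers), 0, jitter_sd)
  x <- 0:(n1 - 1); y <- 0:(n2 - 1)
  m <- matrix(FALSE, n1, n2)
  r2 <- radius^2
  for (i in seq_len(nrow(centers))) {
    da2 <- (x - centers$a[i])^2
    db2 <- (y - centers$b[i])^2
    hit <- outer(da2, db2, "+") <= r2
    m <- m | hit
  }
  m
}

#' Generate a binary rod-lattice volume
#'
#' The lattice is built axis-aligned (rods along +z, plus optional cross rods
#' along x and y) and rotated to `primary_axis` by trilinear resampling with a
#' 0.5 re-threshold. The returned metadata records the ground-truth axis, the
#' nominal strut thickness `2 * rod_radius` and the exact achieved BV/TV.
#'
#' @param spec a [rod_lattice_spec()].
#' @param spacing_um voxel spacing in micrometres attached to the volume.
#' @return Binary [voxel_volume()].
#' @export
make_rod_lattice <- function(spec, spacing_um = 32.8) {
  stopifnot(inherits(spec, "rod_lattice_spec"))
  if (any(spec$shape < spec$spacing))
    stop("shape too small to contain one full spacing period")
  set.seed(spec$seed)
  axis <- spec$primary_axis
  R <- rotation_between(axis, c(0, 0, 1))
  needs_rot <- max(abs(R - diag(3))) > 1e-9

  d_out <- spec$shape
  if (needs_rot) {
    # input cube must cover the rotated output box
    corners <- as.matrix(expand.grid(c(0, d_out[1] - 1), c(0, d_out[2] - 1),
                                     c(0, d_out[3] - 1)))
    ctr_out <- (d_out - 1) / 2
    src <- t(R %*% (t(corners) - ctr_out))
    ext <- 2 * ceiling(apply(abs(src), 2, max)) + 4
    d_in <- pmax(d_out, ext)
  } else d_in <- d_out

  core <- array(FALSE, d_in)
  cs <- rod_cross_section(d_in[1], d_in[2], spec$spacing, spec$rod_radius,
                          spec$jitter_sd)
  core <- array(rep(cs, d_in[3]), dim = d_in)
  if (spec$secondary_fill > 0) {
    # per perpendicular axis: fill = 1 gives equal rods along x, y and z
    f <- spec$secondary_fill
    cs_x <- rod_cross_section(d_in[2], d_in[3], spec$spacing, spec$rod_radius,
                              spec$jitter_sd, keep_frac = f)
    cs_y <- rod_cross_section(d_in[1], d_in[3], spec$spacing, spec$rod_radius,
                              spec$jitter_sd, keep_frac = f)
    core <- core |
      aperm(array(rep(cs_x, d_in[1]), dim = c(d_in[2], d_in[3], d_in[1])),
            c(3, 1, 2)) |
      aperm(array(rep(cs_y, d_in[2]), dim = c(d_in[1], d_in[3], d_in[2])),
            c(1, 3, 2))
  }

  if (needs_rot) {
    # sample coords: src = R (p_out - c_out) + c_in, so rods along `axis` in
    # the output map onto the +z rods of the axis-aligned core (R axis = ez)
    res <- cpp_affine_resample(as.vector(core * 1.0), as.integer(d_in),
                               as.integer(d_out), R,
                               (d_in - 1) / 2, (d_out - 1) / 2, 0)
    bone <- array(res, dim = d_out) >= 0.5
  } else bone <- core

  voxel_volume(bone * 255L, spacing_um, binary = TRUE,
               meta = list(true_axis = axis,
                           nominal_thickness_vox = 2 * spec$rod_radius,
                           bvtv_exact = sum(bone) / length(bone),
                           generator = "rod_lattice", seed = spec$seed))
}

#' Thresholded anisotropic Gaussian random field
#'
#' White noise is smoothed in the Fourier domain with an axis-aligned
#' anisotropic Gaussian kernel (correlation length `corr_length` transverse,
#' `corr_length * elongation` longitudinal), rotated to `axis`, and
#' thresholded at the empirical quantile matching `bvtv_target`, which hits
#' the target volume fraction exactly up to voxel discreteness.
#' `elongation = 1` gives an isotropic control.
#'
#' @param shape voxels per axis.
#' @param axis ground-truth fabric axis (unit 3-vector).
#' @param elongation anisotropy ratio of the smoothing kernel (>= 1).
#' @param bvtv_target bone volume fraction in (0, 1).
#' @param corr_length transverse correlation length in voxels.
#' @param seed integer RNG seed.
#' @param spacing_um voxel spacing attached to the volume.
#' @return Binary [voxel_volume()] with exact achieved BV/TV in `meta`.
#' @export
make_anisotropic_field <- function(shape = c(64, 64, 64), axis = c(0, 0, 1),
                                   elongation = 2, bvtv_target = 0.3,
                                   corr_length = 3, seed = 1L,
                                   spacing_um = 32.8) {
  if (bvtv_target <= 0 || bvtv_target >= 1) stop("bvtv_target must be in (0, 1)")
  if (elongation < 1) stop("elongation must be >= 1")
  axis <- unit3(axis)
  set.seed(as.integer(seed))
  shape <- as.integer(shape)
  R <- rotation_between(axis, c(0, 0, 1))
  needs_rot <- elongation > 1 && max(abs(R - diag(3))) > 1e-9
  d_in <- if (needs_rot) as.integer(ceiling(shape * sqrt(2)) + 2L) else shape

  noise <- array(stats::rnorm(prod(d_in)), dim = d_in)
  freq <- function(n) { f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n; f[seq_len(n)] }
  sig <- c(corr_length, corr_length, corr_length * elongation)
  hx <- exp(-2 * pi^2 * sig[1]^2 * freq(d_in[1])^2)
  hy <- exp(-2 * pi^2 * sig[2]^2 * freq(d_in[2])^2)
  hz <- exp(-2 * pi^2 * sig[3]^2 * freq(d_in[3])^2)
  H <- outer(outer(hx, hy), hz)
  field <- Re(stats::fft(stats::fft(noise) * H, inverse = TRUE)) / prod(d_in)

  if (needs_rot) {
    res <- cpp_affine_resample(as.vector(field), d_in, shape, R,
                               (d_in - 1) / 2, (shape - 1) / 2, 0)
    field <- array(res, dim = shape)
  }
  if (stats::sd(field) < 1e-12)
    stop("degenerate field: bvtv_target unreachable on an all-equal field")
  thr <- stats::quantile(field, 1 - bvtv_target, names = FALSE)
  bone <- field > thr
  voxel_volume(bone * 255L, spacing_um, binary = TRUE,
               meta = list(true_axis = axis, bvtv_exact = sum(bone) / length(bone),
                           elongation = elongation, generator = "anisotropic_field",
                           seed = as.integer(seed)))
}

#' Analytic phantoms with exact thickness/topology metadata
#'
#' Oracles for the morphometry module: `plate` (slab of given thickness),
#' `cylinder` (solid rod along z), `solid_cube` (Euler characteristic 1),
#' `two_cubes` (two disjoint cubes, Euler characteristic 2) and `voxel_ring`
#' (closed 1-voxel-wide square loop, Euler characteristic 0).
#'
#' @param kind phantom name.
#' @param shape volume dimensions in voxels.
#' @param thickness plate thickness in voxels.
#' @param diameter cylinder diameter in voxels.
#' @param side cube side in voxels.
#' @param spacing_um voxel spacing attached to the volume.
#' @return Binary [voxel_volume()] with `meta$thickness_vox` and/or
#'   `meta$euler` set exactly.
#' @export
make_phantom <- function(kind = c("plate", "cylinder", "solid_cube",
                                  "two_cubes", "voxel_ring"),
                         shape = c(32, 32, 32), thickness = 5, diameter = 9,
                         side = 8, spacing_um = 32.8) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (any(shape < 1)) stop("shape must be >= 1 voxel per axis")
  arr <- array(FALSE, shape)
  meta <- list(generator = "phantom", kind = kind)
  mid <- (shape - 1) / 2
  switch(kind,
    plate = {
      if (thickness < 1 || thickness > shape[3]) stop("invalid plate thickness")
      z0 <- floor(mid[3] - (thickness - 1) / 2)
      arr[, , (z0 + 1):(z0 + thickness)] <- TRUE
      meta$thickness_vox <- thickness
    },
    cylinder = {
      if (diameter < 1) stop("invalid cylinder diameter")
      r <- diameter / 2
      # centre on a voxel so the rasterized width matches the nominal diameter
      c0 <- floor((shape - 1) / 2)
      dx2 <- (0:(shape[1] - 1) - c0[1])^2
      dy2 <- (0:(shape[2] - 1) - c0[2])^2
      disc <- outer(dx2, dy2, "+") <= r^2
      arr <- array(rep(disc, shape[3]), dim = shape)
      meta$thickness_vox <- diameter
    },
    solid_cube = {
      if (side < 1 || any(side > shape)) stop("invalid cube side")
      lo <- floor(mid - (side - 1) / 2)
      arr[(lo[1] + 1):(lo[1] + side), (lo[2] + 1):(lo[2] + side),
          (lo[3] + 1):(lo[3] + side)] <- TRUE
      meta$euler <- 1
    },
    two_cubes = {
      s <- max(1L, min(side, floor(min(shape) / 3)))
      arr[1:s, 1:s, 1:s] <- TRUE
      arr[(shape[1] - s + 1):shape[1], (shape[2] - s + 1):shape[2],
          (shape[3] - s + 1):shape[3]] <- TRUE
      meta$euler <- 2
    },
    voxel_ring = {
      if (any(shape < 4)) stop("voxel_ring needs shape >= 4")
      x0 <- floor(mid[1]); y0 <- floor(mid[2]); z0 <- floor(mid[3]) + 1L
      ring <- rbind(c(0,0), c(1,0), c(2,0), c(2,1), c(2,2), c(1,2), c(0,2), c(0,1))
      for (i in seq_len(nrow(ring)))
        arr[x0 + ring[i, 1], y0 + ring[i, 2], z0] <- TRUE
      meta$euler <- 0
    })
  meta$bvtv_exact <- sum(arr) / length(arr)
  voxel_volume(arr * 255L, spacing_um, binary = TRUE, meta = meta)
}

#' Sample axes from a bipolar Watson distribution
#'
#' Axial (antipodally symmetric) density proportional to
#' `exp(concentration * (mean_axis . x)^2)` on the unit sphere, sampled by
#' numeric inverse-CDF on the polar cosine. Dispersion decreases
#' monotonically with `concentration`. Returned axes are hemisphere
#' canonicalized.
#'
#' @param mean_axis non-zero 3-vector.
#' @param concentration Watson concentration parameter (> 0).
#' @param n number of axes.
#' @param seed integer RNG seed.
#' @return `n x 3` matrix of unit axes.
#' @export
sample_axes <- function(mean_axis, concentration, n, seed = 1L) {
  mean_axis <- unit3(mean_axis, "mean_axis")
  if (concentration <= 0) stop("concentration must be > 0")
  if (n < 1) stop("n must be >= 1")
  set.seed(as.integer(seed))
  # axial symmetry: polar angle theta in [0, pi/2] with density
  # ~ exp(k cos^2 theta) sin(theta); numeric inverse CDF on a grid refined
  # quadratically near the pole so high concentrations stay resolved
  th <- (pi / 2) * (seq(0, 1, length.out = 8193))^2
  dens <- exp(concentration * (cos(th)^2 - 1)) * sin(th) # scaled, no overflow
  w <- diff(th)
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * w))
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  theta <- stats::approx(cdf, th, xout = u, rule = 2, ties = "ordered")$y
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sin(theta)
  local_ax <- cbind(s * cos(phi), s * sin(phi), cos(theta))
  R <- rotation_between(c(0, 0, 1), mean_axis)
  canonicalize_axes(local_ax %*% t(R))
}
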