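# Mean-intercept-length fabric analysis. MIL(direction) = total test-line
# length within the region of interest divided by the number of bone/non-bone
# interface crossings; its directional variation defines the fabric tensor
# (n . H . n = 1/MIL(n)^2) whose eigenvector of smallest eigenvalue (largest
# MIL) is the principal trabecular orientation (PTO) and whose extreme MIL
# ratio is the degree of anisotropy (DA).

#' 2D MIL profile over sagittal slices
#'
#' Superimposes a parallel test-line grid at orientations theta = 0, omega,
#' 2*omega, ... < 180 degrees over each slice (theta measured from the
#' transverse reference line, i.e. the image x-axis, towards proximal).
#' In-mask line lengths and interface crossings are pooled across all slices
#' before division, weighting slices by information content.
#'
#' Directions at which no line crosses an interface (e.g. lines parallel to a
#' stripe pattern) get their MIL capped at the accumulated line length and
#' are flagged in the `capped` column.
#'
#' @param slices list of 2D binary matrices (x-z images), e.g. from
#'   [middle_sagittal_slices()].
#' @param masks optional list of logical matrices restricting the measurement
#'   (e.g. sphere cross-sections); defaults to the full rectangle.
#' @param line_spacing perpendicular distance between test lines (voxels).
#' @param omega angular step in degrees; must divide 180.
#' @param step marching step along each line in voxels.
#' @param seed seed for the per-angle grid-offset jitter (suppresses aliasing
#'   between the line grid and lattice-like structures).
#' @return data.frame of class `mil_profile_2d` with columns `theta_deg`,
#'   `length`, `crossings`, `mil`, `capped`.
#' @export
mil_profile_2d <- function(slices, masks = NULL, line_spacing = 2, omega = 1,
                           step = 0.5, seed = 1L) {
  if (!length(slices)) stop("need at least one slice")
  if (omega <= 0 || (180 %% omega) > 1e-9) stop("omega must divide 180")
  if (line_spacing < 1) stop("line_spacing must be >= 1 voxel")
  thetas <- seq(0, 180 - omega, by = omega)
  set.seed(as.integer(seed))
  offsets <- stats::runif(length(thetas))
  acc <- matrix(0, length(thetas), 2)
  any_bone <- FALSE; any_bg <- FALSE
  for (i in seq_along(slices)) {
    img <- slices[[i]] > 0.5 # accept 0/255, 0/1 or logical
    msk <- if (is.null(masks)) array(TRUE, dim(img)) else masks[[i]]
    b <- img & msk
    any_bone <- any_bone || any(b)
    any_bg <- any_bg || any(!img & msk)
    acc <- acc + cpp_mil_2d(as.vector(img), as.vector(msk),
                            as.integer(dim(img)), thetas * pi / 180,
                            line_spacing, step, offsets)
  }
  if (!any_bone || !any_bg)
    stop("no bone/non-bone interface: slices are all one phase")
  capped <- acc[, 2] == 0
  mil <- ifelse(capped, acc[, 1], acc[, 1] / pmax(acc[, 2], 1))
  structure(data.frame(theta_deg = thetas, length = acc[, 1],
                       crossings = acc[, 2], mil = mil, capped = capped),
            class = c("mil_profile_2d", "data.frame"))
}

#' In-plane principal orientation from a 2D MIL profile
#'
#' Fits the polar MIL profile with an ellipse by least squares on
#' `1/MIL^2 = A + B cos(2 theta) + C sin(2 theta)` and reports the major-axis
#' angle in the alpha convention: degrees in `[0, 180)` measured from the line
#' normal to the bone long axis (alpha = 90 means PTO parallel to the long
#' axis). Profiles with in-plane anisotropy below `unstable_below` are flagged
#' `unstable` and their angle should not be interpreted.
#'
#' @param profile a `mil_profile_2d`.
#' @param unstable_below in-plane MILmax/MILmin under which the orientation is
#'   flagged unstable (default 1.05).
#' @return List of class `orientation_2d`: `alpha` (degrees),
#'   `anisotropy_2d`, `unstable`.
#' @export
pto_2d <- function(profile, unstable_below = 1.05) {
  stopifnot(inherits(profile, "mil_profile_2d"))
  ok <- profile$mil > 0 & is.finite(profile$mil)
  if (sum(ok) < 3) stop("profile has fewer than 3 usable angles")
  th <- profile$theta_deg[ok] * pi / 180
  y <- 1 / profile$mil[ok]^2
  X <- cbind(1, cos(2 * th), sin(2 * th))
  cf <- stats::lm.fit(X, y)$coefficients
  A <- cf[1]; B <- cf[2]; C <- cf[3]
  R <- sqrt(B^2 + C^2)
  # 1/MIL^2 minimal (MIL maximal) where cos(2 theta - phase) = -1
  alpha <- (atan2(-C, -B) / 2 * 180 / pi) %% 180
  aniso <- if (A - R <= 0) Inf else sqrt((A + R) / (A - R))
  structure(list(alpha = as.numeric(alpha), anisotropy_2d = as.numeric(aniso),
                 unstable = aniso < unstable_below, coef = c(A = A, B = B, C = C)),
            class = "orientation_2d")
}

#' @export
print.orientation_2d <- function(x, ...) {
  cat(sprintf("2D-PTO: alpha = %.2f deg, in-plane anisotropy = %.3f%s\n",
              x$alpha, x$anisotropy_2d,
              if (x$unstable) " [orientation unstable]" else ""))
  invisible(x)
}

# quasi-uniform hemisphere direction set (Fibonacci spiral), pole included
hemisphere_directions <- function(n = 257L) {
  i <- seq_len(n)
  z <- i / n                     # upper hemisphere only, z = 1 at the pole
  phi <- i * pi * (3 - sqrt(5))  # golden angle
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Directional MIL sampling in a spherical VOI
#'
#' For each of `n_directions` quasi-uniform hemisphere directions, a parallel
#' test-line grid (seed-jittered offsets) is clipped to the spherical mask and
#' MIL = total clipped length / total interface crossings. Directions with
#' zero crossings (lines parallel to an unbroken structure) are reported, get
#' their MIL capped at the accumulated line length and are flagged in the
#' `capped` column ([fit_fabric()] excludes them); more than `max_drop_frac`
#' such directions makes the VOI unusable.
#'
#' @param voi binary [voxel_volume()] (a VOI cube from [extract_voi()]).
#' @param mask logical array restricting measurement to the sphere.
#' @param n_directions number of hemisphere directions (>= 257 recommended).
#' @param line_spacing perpendicular test-line spacing in voxels.
#' @param step marching step in voxels.
#' @param seed seed for grid-offset jitter.
#' @param max_drop_frac tolerated fraction of dropped directions.
#' @return data.frame with `nx`, `ny`, `nz`, `mil`; attribute `n_dropped`.
#' @export
mil_directions_3d <- function(voi, mask = NULL, n_directions = 257L,
                              line_spacing = 2, step = 0.5, seed = 1L,
                              max_drop_frac = 0.1) {
  bone <- bone_logical(voi)
  if (is.null(mask)) mask <- array(TRUE, dim(bone))
  if (!any(bone & mask) || !any(!bone & mask))
    stop("mask must contain both bone and background")
  dirs <- hemisphere_directions(n_directions)
  set.seed(as.integer(seed))
  offsets <- matrix(stats::runif(2 * n_directions), ncol = 2)
  res <- cpp_mil_3d(as.vector(bone), as.vector(mask), as.integer(dim(bone)),
                    dirs, line_spacing, step, offsets)
  has_len <- res[, 1] > 0
  capped <- has_len & res[, 2] == 0
  n_drop <- sum(capped) + sum(!has_len)
  if (n_drop > max_drop_frac * n_directions)
    stop(sprintf("VOI unusable: %d of %d directions had no interface crossing",
                 n_drop, n_directions))
  out <- data.frame(nx = dirs[has_len, 1], ny = dirs[has_len, 2],
                    nz = dirs[has_len, 3],
                    mil = ifelse(capped[has_len], res[has_len, 1],
                                 res[has_len, 1] / pmax(res[has_len, 2], 1)),
                    capped = capped[has_len])
  attr(out, "n_dropped") <- n_drop
  out
}

#' Fit the MIL fabric tensor
#'
#' Least-squares fit of the quadratic form `n . H . n = 1/MIL(n)^2` to
#' directional MIL samples. Returns the eigen-system (eigenvalues
#' `h1 <= h2 <= h3`, orthonormal eigenvectors), the MIL semi-axes
#' `MILi = 1/sqrt(hi)`, the PTO (eigenvector of `h1`, i.e. largest MIL,
#' hemisphere-canonicalized), `DA = MIL1/MIL3 >= 1` and the relative fit
#' residual. An indefinite fit (non-positive eigenvalue) is an error.
#'
#' @param samples data.frame with `nx`, `ny`, `nz`, `mil` (>= 6 well-spread
#'   directions), e.g. from [mil_directions_3d()].
#' @return List of class `fabric_result`.
#' @export
fit_fabric <- function(samples) {
  if (!is.null(samples$capped)) samples <- samples[!samples$capped, ]
  if (nrow(samples) < 6) stop("need >= 6 directions to fit a fabric tensor")
  n <- as.matrix(samples[, c("nx", "ny", "nz")])
  y <- 1 / samples$mil^2
  X <- cbind(n[, 1]^2, n[, 2]^2, n[, 3]^2,
             2 * n[, 1] * n[, 2], 2 * n[, 1] * n[, 3], 2 * n[, 2] * n[, 3])
  cf <- stats::lm.fit(X, y)$coefficients
  H <- matrix(c(cf[1], cf[4], cf[5],
                cf[4], cf[2], cf[6],
                cf[5], cf[6], cf[3]), 3, 3)
  eg <- eigen(H, symmetric = TRUE) # decreasing eigenvalues
  vals <- rev(eg$values)           # h1 <= h2 <= h3
  vecs <- eg$vectors[, 3:1, drop = FALSE]
  resid <- sqrt(mean((X %*% cf - y)^2)) / mean(y)
  # near-degenerate fits (extremely elongated structures: MIL along the
  # dominant axis is effectively unbounded) can dip marginally below zero
  # from sampling noise; clamp those, error on genuinely indefinite fits
  clamped <- FALSE
  floor_val <- 1e-6 * vals[3]
  small <- vals < floor_val
  if (any(small)) {
    if (any(vals < -0.01 * vals[3]))
      stop(sprintf("indefinite fabric fit (min eigenvalue %.3g, residual %.3g)",
                   vals[1], resid))
    vals[small] <- floor_val
    clamped <- TRUE
  }
  mil_axes <- 1 / sqrt(vals)
  pto <- canonicalize_axes(vecs[, 1])[1, ]
  structure(list(tensor = H, eigenvalues = vals, eigenvectors = vecs,
                 mil_axes = mil_axes, pto = pto, da = mil_axes[1] / mil_axes[3],
                 residual = resid, clamped = clamped),
            class = "fabric_result")
}

#' @export
print.fabric_result <- function(x, ...) {
  ll <- to_lonlat(x$pto)
  cat(sprintf("Fabric: DA = %.3f, PTO = (%.3f, %.3f, %.3f) [lon %.1f, lat %.1f], residual %.3g\n",
              x$da, x$pto[1], x$pto[2], x$pto[3],
              ll$longitude, ll$latitude, x$residual))
  invisible(x)
}

#' Full 3D fabric analysis of a VOI
#'
#' Convenience chain: [mil_directions_3d()] then [fit_fabric()].
#'
#' @inheritParams mil_directions_3d
#' @return A `fabric_result`.
#' @export
fabric_voi <- function(voi, mask = NULL, n_directions = 257L, line_spacing = 2,
                       step = 0.5, seed = 1L) {
  fit_fabric(mil_directions_3d(voi, mask, n_directions, line_spacing, step, seed))
}
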