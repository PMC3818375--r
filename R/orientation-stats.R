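# Spherical/axial representation and the permutation machinery used to compare
# principal trabecular orientations between groups.
#
# Conventions: axes are unit 3-vectors with antipodal equivalence, stored
# hemisphere-canonicalized (positive z = proximodistal pole; equator ties are
# broken towards anterior, i.e. x <= 0, then y >= 0). Longitude 0/90/180/270
# degrees = posterior/lateral/anterior/medial (+x = posterior, +y = lateral);
# latitude 90 degrees = the long-axis pole. Stereoplot projection is
# equal-angle (Wulff): radius = tan((90 - latitude)/2).

#' Canonicalize axes to the upper hemisphere
#'
#' Antipodal inputs map to the same representative: positive z, with equator
#' ties broken towards anterior (x <= 0), then y >= 0.
#'
#' @param axes numeric 3-vector or `n x 3` matrix; rows are normalized.
#' @return Matrix `n x 3` of canonical unit axes.
#' @export
canonicalize_axes <- function(axes) {
  if (is.null(dim(axes))) axes <- matrix(axes, nrow = 1)
  nrm <- sqrt(rowSums(axes^2))
  if (any(nrm < 1e-12)) stop("zero axis cannot be canonicalized")
  axes <- axes / nrm
  eps <- 1e-9
  flip <- axes[, 3] < -eps |
    (abs(axes[, 3]) <= eps & (axes[, 1] > eps |
                              (abs(axes[, 1]) <= eps & axes[, 2] < -eps)))
  axes[flip, ] <- -axes[flip, , drop = FALSE]
  axes
}

#' Longitude/latitude of axes
#'
#' @param axes 3-vector or `n x 3` matrix (canonicalized internally).
#' @return data.frame with `longitude` in `[0, 360)` and `latitude` in
#'   `[0, 90]` degrees.
#' @export
to_lonlat <- function(axes) {
  a <- canonicalize_axes(axes)
  lon <- (atan2(a[, 2], a[, 1]) * 180 / pi) %% 360
  lat <- asin(pmin(1, pmax(-1, a[, 3]))) * 180 / pi
  data.frame(longitude = lon, latitude = lat)
}

#' Axes from longitude/latitude
#' @param longitude,latitude degrees (latitude in `[0, 90]`).
#' @return `n x 3` matrix of unit axes.
#' @export
from_lonlat <- function(longitude, latitude) {
  lon <- longitude * pi / 180; lat <- latitude * pi / 180
  cbind(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
}

#' Equal-angle (Wulff) stereographic projection
#'
#' Projects upper-hemisphere axes onto the unit disc: radius =
#' `tan((90 - latitude)/2)`, azimuth = longitude. The pole maps to the origin
#' and the equator to the unit circle; the projection is invertible on the
#' closed hemisphere.
#'
#' @param lonlat data.frame with `longitude`/`latitude` columns (degrees), as
#'   produced by [to_lonlat()].
#' @return data.frame with `x`, `y` plot coordinates.
#' @export
stereo_project <- function(lonlat) {
  r <- tan((90 - lonlat$latitude) * pi / 360)
  th <- lonlat$longitude * pi / 180
  data.frame(x = r * cos(th), y = r * sin(th))
}

#' Invert the equal-angle projection
#' @param xy data.frame with `x`, `y` (inside the closed unit disc).
#' @return data.frame with `longitude`, `latitude` in degrees.
#' @export
stereo_unproject <- function(xy) {
  r <- sqrt(xy$x^2 + xy$y^2)
  lat <- 90 - 2 * atan(r) * 180 / pi
  lon <- (atan2(xy$y, xy$x) * 180 / pi) %% 360
  lon[r < 1e-15] <- 0
  data.frame(longitude = lon, latitude = lat)
}

#' Great-circle distance via the haversine formula
#'
#' Central angle between two points given as axes or longitude/latitude rows.
#' With `axial = TRUE` the antipodal identification is applied:
#' `min(d, 180 - d)`.
#'
#' @param a,b unit 3-vectors, `n x 3` matrices, or data.frames with
#'   `longitude`/`latitude` in degrees.
#' @param axial treat inputs as axes rather than directed vectors.
#' @return Distance(s) in degrees.
#' @export
haversine_deg <- function(a, b, axial = FALSE) {
  ll <- function(x) {
    if (is.data.frame(x)) x else to_lonlat(x)
  }
  A <- ll(a); B <- ll(b)
  la1 <- A$latitude * pi / 180; la2 <- B$latitude * pi / 180
  dlat <- la2 - la1
  dlon <- (B$longitude - A$longitude) * pi / 180
  h <- sin(dlat / 2)^2 + cos(la1) * cos(la2) * sin(dlon / 2)^2
  d <- 2 * asin(pmin(1, sqrt(h))) * 180 / pi
  if (axial) d <- pmin(d, 180 - d)
  d
}

#' Spherical centroid of a set of axes
#'
#' Hemisphere-canonicalizes the axes, takes the normalized vector mean and
#' re-projects to the sphere. A near-zero resultant (axes dispersed beyond any
#' meaningful centroid) is an error.
#'
#' @param axes `n x 3` matrix of axes.
#' @param min_resultant mean resultant length below which the centroid is
#'   declared degenerate.
#' @return Unit 3-vector (canonical).
#' @export
spherical_centroid <- function(axes, min_resultant = 1e-6) {
  a <- canonicalize_axes(axes)
  m <- colMeans(a)
  r <- sqrt(sum(m^2))
  if (r < min_resultant) stop("axes dispersed beyond centroid definition")
  canonicalize_axes(m / r)[1, ]
}

new_permutation_result <- function(statistic, p, n_alloc, mode, seed = NA,
                                   n_draws = NA, n_degenerate = 0L) {
  structure(list(statistic = statistic, p_value = p, n_allocations = n_alloc,
                 mode = mode, seed = seed, n_draws = n_draws,
                 n_degenerate = n_degenerate),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s): statistic = %.4g, p = %.4g (%s allocations%s)\n",
              x$mode, x$statistic, x$p_value, format(x$n_allocations, big.mark = ","),
              if (x$n_degenerate > 0) sprintf(", %d degenerate excluded", x$n_degenerate)
              else ""))
  invisible(x)
}

# Shared allocation engine: applies `stat_fn(idxA)` (indices into the pooled
# sample that form pseudo-group A) over every allocation preserving group
# sizes, exhaustively when C(nA+nB, nA) <= max_exhaustive, else by seeded
# Monte-Carlo. The observed allocation is counted in numerator and
# denominator, so p >= 1/N.
permutation_engine <- function(nA, nB, stat_fn, observed,
                               max_exhaustive = 1e6, n_draws = 1e4, seed = 1L,
                               stat_matrix_fn = NULL) {
  n <- nA + nB
  n_alloc <- choose(n, nA)
  if (n_alloc <= max_exhaustive) {
    alloc <- utils::combn(n, nA)
    stats <- if (is.null(stat_matrix_fn)) apply(alloc, 2, stat_fn)
             else stat_matrix_fn(alloc)
    keep <- is.finite(stats)
    p <- sum(stats[keep] >= observed - 1e-12) / sum(keep)
    new_permutation_result(observed, p, n_alloc, "exhaustive",
                           n_degenerate = sum(!keep))
  } else {
    set.seed(as.integer(seed))
    alloc <- vapply(seq_len(n_draws), function(i) sample.int(n, nA),
                    integer(nA))
    alloc <- matrix(alloc, nrow = nA)
    stats <- if (is.null(stat_matrix_fn)) apply(alloc, 2, stat_fn)
             else stat_matrix_fn(alloc)
    keep <- is.finite(stats)
    p <- (1 + sum(stats[keep] >= observed - 1e-12)) / (1 + sum(keep))
    new_permutation_result(observed, p, n_alloc, "monte_carlo", seed = seed,
                           n_draws = n_draws, n_degenerate = sum(!keep))
  }
}

#' Median permutation test for angular (2D-PTO) data
#'
#' Statistic: absolute difference of group medians. All `C(nA+nB, nA)`
#' allocations of the pooled data into pseudo-groups of the original sizes are
#' evaluated (exhaustively up to `max_exhaustive`, else seeded Monte-Carlo);
#' p is the fraction of allocations whose statistic reaches the observed one.
#'
#' @param group_a,group_b numeric vectors of angles in degrees.
#' @param max_exhaustive allocation count above which Monte-Carlo is used.
#' @param n_draws Monte-Carlo draws.
#' @param seed Monte-Carlo seed.
#' @return A `permutation_result`.
#' @export
permutation_test_median <- function(group_a, group_b, max_exhaustive = 1e6,
                                    n_draws = 1e4, seed = 1L) {
  if (!length(group_a) || !length(group_b)) stop("empty group")
  pool <- c(group_a, group_b)
  nA <- length(group_a)
  observed <- abs(stats::median(group_a) - stats::median(group_b))
  permutation_engine(nA, length(group_b), NULL, observed,
                     max_exhaustive, n_draws, seed,
                     stat_matrix_fn = function(alloc)
                       cpp_perm_median_stats(pool, alloc))
}

#' Haversine-centroid permutation test for axes (3D-PTO)
#'
#' Statistic: great-circle (haversine) distance between the spherical
#' centroids of the two groups. Allocation scheme and p definition are
#' identical to [permutation_test_median()]. Allocations with a degenerate
#' (near-zero resultant) centroid are excluded and their count reported.
#'
#' @param axes_a,axes_b `n x 3` matrices of axes (>= 2 rows each).
#' @param axial apply antipodal identification to the centroid distance.
#' @param exclude optional integer indices into `axes_a`/`axes_b` (as a list
#'   with elements `a` and/or `b`) removed before testing; mirrors an explicit
#'   outlier-exclusion sensitivity analysis.
#' @inheritParams permutation_test_median
#' @return A `permutation_result`.
#' @export
permutation_test_sphere <- function(axes_a, axes_b, axial = TRUE,
                                    exclude = NULL, max_exhaustive = 1e6,
                                    n_draws = 1e4, seed = 1L) {
  if (is.null(dim(axes_a))) axes_a <- matrix(axes_a, ncol = 3)
  if (is.null(dim(axes_b))) axes_b <- matrix(axes_b, ncol = 3)
  if (!is.null(exclude$a)) axes_a <- axes_a[-exclude$a, , drop = FALSE]
  if (!is.null(exclude$b)) axes_b <- axes_b[-exclude$b, , drop = FALSE]
  if (nrow(axes_a) < 2 || nrow(axes_b) < 2) stop("each group needs >= 2 axes")
  pool <- canonicalize_axes(rbind(axes_a, axes_b))
  nA <- nrow(axes_a)
  cen_dist <- function(idxA) {
    mA <- colMeans(pool[idxA, , drop = FALSE])
    mB <- colMeans(pool[-idxA, , drop = FALSE])
    rA <- sqrt(sum(mA^2)); rB <- sqrt(sum(mB^2))
    if (rA < 1e-6 || rB < 1e-6) return(NA_real_)
    haversine_deg(matrix(mA / rA, 1), matrix(mB / rB, 1), axial = axial)
  }
  observed <- cen_dist(seq_len(nA))
  if (!is.finite(observed)) stop("degenerate centroid in the observed groups")
  res <- permutation_engine(nA, nrow(axes_b), cen_dist, observed,
                            max_exhaustive, n_draws, seed)
  res
}

#' Exact two-sided Wilcoxon rank-sum test
#'
#' Midrank ties; the exact null distribution of the rank sum over all
#' `C(nA+nB, nA)` allocations is obtained by dynamic programming over
#' doubled midranks (no subset materialization), so exactness holds at any
#' practical sample size. Two-sided p: probability of a rank sum at least as
#' far from its allocation mean as observed.
#'
#' @param a,b numeric vectors.
#' @return Two-sided exact p-value.
#' @export
exact_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group")
  n <- length(a) + length(b)
  r2 <- as.integer(round(2 * rank(c(a, b)))) # doubled midranks are integers
  nA <- length(a)
  S <- sum(r2)
  # dp[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  dp <- matrix(0, nA + 1, S + 1)
  dp[1, 1] <- 1
  for (v in r2) {
    kmax <- nA
    for (k in kmax:1) {
      nzr <- which(dp[k, ] > 0)
      if (!length(nzr)) next
      tgt <- nzr + v
      dp[k + 1, tgt] <- dp[k + 1, tgt] + dp[k, nzr]
    }
  }
  counts <- dp[nA + 1, ]
  sums <- which(counts > 0) - 1L
  cnt <- counts[counts > 0]
  mu <- nA * S / n
  obs <- sum(r2[seq_len(nA)])
  extreme <- abs(sums - mu) >= abs(obs - mu) - 1e-9
  sum(cnt[extreme]) / sum(cnt)
}
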