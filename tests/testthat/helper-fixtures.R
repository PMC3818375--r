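# Shared fixtures and independent oracles. Everything is generated in code at
# test time; no binary fixtures.

# parallel stripes in an n x n x-z image; stripe direction at `alpha_deg` from
# the image x-axis (the transverse reference), so the 2D-PTO equals alpha_deg
mk_stripes <- function(n, alpha_deg, period = 8, width = 4) {
  a <- alpha_deg * pi / 180
  x <- matrix(0:(n - 1), n, n)
  z <- matrix(0:(n - 1), n, n, byrow = TRUE)
  (((-x * sin(a) + z * cos(a)) %% period) < width) * 255
}

# band-limited isotropic 50 % random field slice (Gaussian-smoothed noise
# thresholded at its median)
smooth_noise_slice <- function(n, sigma = 2, seed = 1) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n * n), n, n)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  H <- exp(-2 * pi^2 * sigma^2 * outer(f^2, f^2, "+"))
  s <- Re(stats::fft(stats::fft(z) * H, inverse = TRUE)) / n^2
  (s > stats::median(s)) * 255
}

# angle in degrees between two axes (antipodally symmetric)
axis_angle_deg <- function(a, b) {
  acos(pmin(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

# unit axis tilted `delta_deg` from +z within the sagittal (x-z) plane,
# towards -x so that the in-slice angle alpha = 90 + delta_deg
sagittal_axis <- function(delta_deg) {
  d <- delta_deg * pi / 180
  c(-sin(d), 0, cos(d))
}

# --- independent brute-force permutation oracles (bitmask enumeration) ------

subsets_of_size <- function(n, k) {
  masks <- 0:(2^n - 1)
  pop <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(n - 1))) > 0), numeric(1))
  lapply(masks[pop == k], function(m) which(bitwAnd(m, 2^(0:(n - 1))) > 0))
}

oracle_perm_median <- function(a, b) {
  pool <- c(a, b)
  idx <- subsets_of_size(length(pool), length(a))
  stats <- vapply(idx, function(i)
    abs(stats::median(pool[i]) - stats::median(pool[-i])), numeric(1))
  obs <- abs(stats::median(a) - stats::median(b))
  mean(stats >= obs - 1e-12)
}

# independent spherical statistic: canonical flip to z >= 0, vector-mean
# centroid, acos-dot central angle with axial identification
oracle_sphere_stat <- function(axes) {
  flip <- axes[, 3] < 0
  axes[flip, ] <- -axes[flip, , drop = FALSE]
  m <- colMeans(axes / sqrt(rowSums(axes^2)))
  m / sqrt(sum(m^2))
}

oracle_perm_sphere <- function(A, B, axial = TRUE) {
  pool <- rbind(A, B)
  idx <- subsets_of_size(nrow(pool), nrow(A))
  dist_deg <- function(u, v) {
    d <- acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
    if (axial) min(d, 180 - d) else d
  }
  stats <- vapply(idx, function(i)
    dist_deg(oracle_sphere_stat(pool[i, , drop = FALSE]),
             oracle_sphere_stat(pool[-i, , drop = FALSE])), numeric(1))
  obs <- dist_deg(oracle_sphere_stat(A), oracle_sphere_stat(B))
  mean(stats >= obs - 1e-12)
}

oracle_rank_sum <- function(a, b) {
  pool <- c(a, b)
  r <- rank(pool)
  idx <- subsets_of_size(length(pool), length(a))
  W <- vapply(idx, function(i) sum(r[i]), numeric(1))
  mu <- mean(W)
  obs <- sum(r[seq_along(a)])
  mean(abs(W - mu) >= abs(obs - mu) - 1e-9)
}
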