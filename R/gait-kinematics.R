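# Ankle-angle-at-peak-loading computation from marker trajectories and the
# body-weight-normalized vertical ground reaction force (GRFv). "Peak loading"
# is the part of stance where GRFv exceeds 75 % of body weight; walking traces
# are double-peaked, so the window may be one interval or two.

# Butterworth low-pass design via bilinear transform of the analog prototype.
butter_lowpass <- function(order, cutoff_hz, rate_hz) {
  if (cutoff_hz >= rate_hz / 2) stop("cutoff must be below the Nyquist frequency")
  if (cutoff_hz <= 0) stop("cutoff must be positive")
  k <- seq_len(order)
  # analog prototype poles on the unit circle's left half-plane
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  wc <- 2 * rate_hz * tan(pi * cutoff_hz / rate_hz) # prewarped
  p <- wc * p
  zp <- (2 * rate_hz + p) / (2 * rate_hz - p) # bilinear transform
  poly_from_roots <- function(r) {
    cf <- 1
    for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
    cf
  }
  a <- Re(poly_from_roots(zp))
  b <- Re(poly_from_roots(rep(-1 + 0i, order))) # zeros at z = -1
  b <- b * sum(a) / sum(b)                      # unit DC gain
  list(b = b, a = a)
}

#' Zero-lag Butterworth low-pass filter
#'
#' Forward-backward ("filtfilt") application of a low-pass Butterworth design,
#' giving zero phase shift. `"full-order"` applies the stated order in each
#' direction (effective magnitude response of twice the order, the common
#' reading of "zero-lag 4th order"); `"half-order"` applies half the order
#' each way so the effective order equals `order`. Edge transients are
#' suppressed with odd-reflection padding.
#'
#' @param signal numeric vector.
#' @param cutoff_hz cutoff frequency (must be below Nyquist); defaults used in
#'   this package are 12 Hz for kinematics and 200 Hz for force data.
#' @param rate_hz sampling rate.
#' @param order filter order of the stated design (default 4).
#' @param convention `"full-order"` (default) or `"half-order"`.
#' @return Filtered signal, same length.
#' @export
butterworth_zero_lag <- function(signal, cutoff_hz, rate_hz, order = 4L,
                                 convention = c("full-order", "half-order")) {
  convention <- match.arg(convention)
  ord <- if (convention == "half-order") max(1L, order %/% 2L) else order
  ba <- butter_lowpass(ord, cutoff_hz, rate_hz)
  n <- length(signal)
  pad <- min(n - 1L, 3L * (length(ba$a) + 1L))
  if (pad < 1L) return(signal)
  head_pad <- 2 * signal[1] - signal[(pad + 1):2]
  tail_pad <- 2 * signal[n] - signal[(n - 1):(n - pad)]
  x <- c(head_pad, signal, tail_pad)
  y <- cpp_iir(ba$b, ba$a, x, x[1])
  y <- rev(cpp_iir(ba$b, ba$a, rev(y), y[length(y)]))
  y[(pad + 1):(pad + n)]
}

#' Ankle angle from the four gait landmarks
#'
#' Interior angle in `[0, 180]` degrees between the shank line (lateral
#' femoral epicondyle to lateral malleolus) and the foot line (posterior tuber
#' calcaneus to 5th metatarsal head), per frame, in lateral view. The angle is
#' between the directed segments (knee-to-ankle versus heel-to-toe), so 0
#' means the two segments point the same way along their lines. Invariant to
#' translation, rotation and uniform scaling of the view.
#'
#' @param landmarks list with `n x 2` matrices `epicondyle`, `malleolus`,
#'   `calcaneus`, `metatarsal`.
#' @return Numeric vector of angles in degrees (one per frame).
#' @export
ankle_angle <- function(landmarks) {
  need <- c("epicondyle", "malleolus", "calcaneus", "metatarsal")
  if (!all(need %in% names(landmarks)))
    stop("landmarks must contain: ", paste(need, collapse = ", "))
  v1 <- landmarks$malleolus - landmarks$epicondyle
  v2 <- landmarks$metatarsal - landmarks$calcaneus
  n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
  bad <- which(n1 < 1e-12 | n2 < 1e-12)
  if (length(bad))
    stop("coincident landmark pair at frame ", bad[1])
  cosang <- rowSums(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Peak-loading window
#'
#' Boolean mask of stance samples where GRFv exceeds 0.75 body weight.
#' Contiguity is not required: double-peaked traces whose trough dips below
#' the threshold yield two disjoint intervals, both retained.
#'
#' @param grfv_bw GRFv normalized to body weight.
#' @param threshold_bw threshold (default 0.75 BW).
#' @return Logical mask with attribute `n_intervals`.
#' @export
peak_loading_window <- function(grfv_bw, threshold_bw = 0.75) {
  mask <- grfv_bw > threshold_bw
  if (!any(mask)) stop("no peak-loading window: GRFv never exceeds threshold")
  r <- rle(mask)
  attr(mask, "n_intervals") <- sum(r$values)
  mask
}

#' Mean ankle angle over the peak-loading window
#'
#' Filters both streams (zero-lag Butterworth; filtering of a stream is
#' skipped with a warning when its cutoff is not below Nyquist), resamples the
#' angle stream onto the force time base by linear interpolation, and averages
#' the angle over the GRFv > 0.75 BW mask.
#'
#' @param trial a `gait_trial` (see [make_gait_trial()] / [read_gait_csv()]).
#' @param cutoff_kin,cutoff_force Butterworth cutoffs in Hz (12/200 defaults).
#' @param order filter order.
#' @param filter apply filtering at all (disable for noiseless synthetic
#'   trials when exact recovery is wanted).
#' @return Mean angle in degrees; attribute `coverage` is the fraction of
#'   stance in the window, `n_intervals` the interval count.
#' @export
mean_angle_at_peak_loading <- function(trial, cutoff_kin = 12, cutoff_force = 200,
                                       order = 4L, filter = TRUE) {
  stopifnot(inherits(trial, "gait_trial"))
  grf <- trial$grfv_bw
  ang <- ankle_angle(trial$landmarks)
  if (filter) {
    maybe_filter <- function(x, cutoff, rate) {
      if (cutoff < rate / 2) butterworth_zero_lag(x, cutoff, rate, order)
      else { warning("cutoff >= Nyquist; stream left unfiltered"); x }
    }
    grf <- maybe_filter(grf, cutoff_force, trial$sample_rate_force)
    ang <- maybe_filter(ang, cutoff_kin, trial$sample_rate_kin)
  }
  ang_on_force <- stats::approx(trial$time_kin, ang, xout = trial$time_force,
                                rule = 2)$y
  mask <- peak_loading_window(grf)
  out <- mean(ang_on_force[mask])
  attr(out, "coverage") <- mean(mask)
  attr(out, "n_intervals") <- attr(mask, "n_intervals")
  out
}

#' Froude number
#'
#' Dimensionless speed `v^2 / (g L)` with g = 9.81 m/s^2, used to match gait
#' dynamics across body sizes.
#'
#' @param speed_mps walking speed in m/s.
#' @param limb_length_m hindlimb length in m (> 0).
#' @return Froude number.
#' @export
froude_number <- function(speed_mps, limb_length_m) {
  if (any(limb_length_m <= 0)) stop("limb length must be positive")
  speed_mps^2 / (9.81 * limb_length_m)
}
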