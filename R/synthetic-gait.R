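# Synthetic gait trials with a double-peaked vertical GRF trace and a
# prescribed ankle-angle profile; the analytic mean angle over the
# GRFv > 0.75 BW window is stored as ground truth at construction.

#' Gait trial specification
#'
#' Defaults emulate the measurement setup of the walking experiments this
#' package targets: force sampled at 1000 Hz, kinematics at 500 Hz, stance
#' ~0.6 s, a double-peaked GRFv with peaks ~1.1 body weights and a midstance
#' trough ~0.7 BW (typical of walking at moderate speed).
#'
#' @param stance_duration stance time in seconds.
#' @param sample_rate_force,sample_rate_kin sampling rates in Hz.
#' @param peak1,peak2 GRFv peak heights in body weights.
#' @param trough midstance GRFv in body weights (< both peaks).
#' @param angle_profile function of stance fraction `s` in `[0, 1]` returning
#'   the ankle angle in degrees.
#' @param noise_sd_deg,noise_sd_bw additive Gaussian noise SDs for the angle
#'   (applied to the landmark geometry) and the GRFv trace.
#' @param seed integer RNG seed.
#' @export
gait_trial_spec <- function(stance_duration = 0.6, sample_rate_force = 1000,
                            sample_rate_kin = 500, peak1 = 1.1, peak2 = 1.1,
                            trough = 0.7, angle_profile = function(s) 85.6,
                            noise_sd_deg = 0, noise_sd_bw = 0, seed = 1L) {
  if (trough < 0) stop("trough must be >= 0")
  if (peak1 <= trough || peak2 <= trough)
    stop("no double peak: peaks must exceed the trough")
  if (sample_rate_force <= 0 || sample_rate_kin <= 0)
    stop("sample rates must be positive")
  structure(list(stance_duration = stance_duration,
                 sample_rate_force = sample_rate_force,
                 sample_rate_kin = sample_rate_kin,
                 peak1 = peak1, peak2 = peak2, trough = trough,
                 angle_profile = angle_profile,
                 noise_sd_deg = noise_sd_deg, noise_sd_bw = noise_sd_bw,
                 seed = as.integer(seed)),
            class = "gait_trial_spec")
}

# double-peaked GRFv shape on stance fraction s in [0, 1]: a broad midstance
# hump at the trough level plus two cosine-squared bumps at 25 % and 75 % of
# stance whose support does not reach midstance
grf_shape <- function(s, peak1, peak2, trough) {
  base <- trough * sin(pi * pmin(pmax(s, 0), 1))^0.7
  bump <- function(s, c0, h, w = 0.2) {
    d <- abs(s - c0)
    ifelse(d < w, h * cos(pi * d / (2 * w))^2, 0)
  }
  b1 <- bump(s, 0.25, peak1 - trough * sin(pi * 0.25)^0.7)
  b2 <- bump(s, 0.75, peak2 - trough * sin(pi * 0.75)^0.7)
  base + b1 + b2
}

#' Generate a synthetic gait trial
#'
#' The GRFv trace has exactly two local maxima above the trough; the four
#' landmark trajectories (lateral femoral epicondyle, lateral malleolus,
#' tuber calcaneus, 5th metatarsal head) realize `angle_profile` exactly
#' before noise. The analytic mean angle over the noiseless
#' GRFv > 0.75 BW window is stored as `meta$true_mean_angle`.
#'
#' @param spec a [gait_trial_spec()].
#' @return Object of class `gait_trial` with fields `time_force`, `grfv_bw`,
#'   `time_kin`, `landmarks`, `sample_rate_force`, `sample_rate_kin`, `meta`.
#' @export
make_gait_trial <- function(spec) {
  stopifnot(inherits(spec, "gait_trial_spec"))
  set.seed(spec$seed)
  tf <- seq(0, spec$stance_duration, by = 1 / spec$sample_rate_force)
  tk <- seq(0, spec$stance_duration, by = 1 / spec$sample_rate_kin)
  sf <- tf / spec$stance_duration
  sk <- tk / spec$stance_duration
  grf_clean <- grf_shape(sf, spec$peak1, spec$peak2, spec$trough)
  grf <- pmax(0, grf_clean + stats::rnorm(length(sf), 0, spec$noise_sd_bw))

  ang_clean <- vapply(sk, spec$angle_profile, numeric(1))
  ang <- ang_clean + stats::rnorm(length(sk), 0, spec$noise_sd_deg)

  # lateral-view geometry realizing the (noisy) angle exactly:
  # foot horizontal, shank direction set by the angle
  L_shank <- 0.40; L_foot <- 0.25 # metres
  a_rad <- ang * pi / 180
  calcaneus <- cbind(rep(0, length(sk)), rep(0, length(sk)))
  metatarsal <- cbind(rep(L_foot, length(sk)), rep(0, length(sk)))
  malleolus <- cbind(rep(0.05, length(sk)), rep(0.08, length(sk)))
  epicondyle <- malleolus + L_shank * cbind(-cos(a_rad), sin(a_rad))

  # analytic ground truth from the noiseless trace: window on the force base,
  # mean of the prescribed profile over that window
  w <- grf_clean > 0.75
  true_mean <- if (any(w)) mean(vapply(sf[w], spec$angle_profile, numeric(1)))
               else NA_real_

  structure(list(time_force = tf, grfv_bw = grf, time_kin = tk,
                 landmarks = list(epicondyle = epicondyle, malleolus = malleolus,
                                  calcaneus = calcaneus, metatarsal = metatarsal),
                 sample_rate_force = spec$sample_rate_force,
                 sample_rate_kin = spec$sample_rate_kin,
                 meta = list(true_mean_angle = true_mean,
                             spec_seed = spec$seed,
                             angle_clean = ang_clean, grf_clean = grf_clean)),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %.3g s stance, force %g Hz, kinematics %g Hz, GRFv max %.2f BW\n",
              max(x$time_force), x$sample_rate_force, x$sample_rate_kin,
              max(x$grfv_bw)))
  invisible(x)
}

#' Write / read a gait trial as CSV
#'
#' One row per force sample: `time_s`, `grfv_bw`, then `<landmark>_x` and
#' `<landmark>_y` for the four landmarks, linearly interpolated onto the force
#' time base. Reading reconstructs a `gait_trial` with a common sampling rate.
#'
#' @param trial a `gait_trial`.
#' @param path CSV path.
#' @export
write_gait_csv <- function(trial, path) {
  stopifnot(inherits(trial, "gait_trial"))
  df <- data.frame(time_s = trial$time_force, grfv_bw = trial$grfv_bw)
  for (nm in names(trial$landmarks)) {
    m <- trial$landmarks[[nm]]
    df[[paste0(nm, "_x")]] <- stats::approx(trial$time_kin, m[, 1],
                                            trial$time_force, rule = 2)$y
    df[[paste0(nm, "_y")]] <- stats::approx(trial$time_kin, m[, 2],
                                            trial$time_force, rule = 2)$y
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gait_csv
#' @param path CSV path produced by [write_gait_csv()].
#' @export
read_gait_csv <- function(path) {
  df <- utils::read.csv(path)
  rate <- 1 / stats::median(diff(df$time_s))
  lm_names <- c("epicondyle", "malleolus", "calcaneus", "metatarsal")
  landmarks <- lapply(lm_names, function(nm)
    cbind(df[[paste0(nm, "_x")]], df[[paste0(nm, "_y")]]))
  names(landmarks) <- lm_names
  structure(list(time_force = df$time_s, grfv_bw = df$grfv_bw,
                 time_kin = df$time_s, landmarks = landmarks,
                 sample_rate_force = rate, sample_rate_kin = rate,
                 meta = list()),
            class = "gait_trial")
}

#' Trial acceptance validator
#'
#' Flags (rather than silently enforces) the trial acceptance criteria used
#' for force-plate walking data: clean single-foot contact (GRFv returns to
#' ~0 at both ends of stance) and approximately constant forward speed
#' (< 10 % fore-aft impulse asymmetry, when fore-aft force is available).
#'
#' @param trial a `gait_trial`.
#' @param grf_fa optional fore-aft GRF trace on the force time base.
#' @return Logical; attributes `reasons` lists any failures.
#' @export
validate_trial <- function(trial, grf_fa = NULL) {
  reasons <- character(0)
  g <- trial$grfv_bw
  n <- length(g)
  edge <- max(g[c(1:3, (n - 2):n)])
  if (edge > 0.2) reasons <- c(reasons, "GRFv does not return to baseline")
  if (!is.null(grf_fa)) {
    pos <- sum(pmax(grf_fa, 0)); neg <- sum(pmax(-grf_fa, 0))
    if (abs(pos - neg) > 0.1 * max(pos, neg))
      reasons <- c(reasons, "fore-aft impulse asymmetry > 10%")
  }
  structure(length(reasons) == 0L, reasons = reasons)
}
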