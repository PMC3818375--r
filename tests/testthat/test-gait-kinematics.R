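# Butterworth filtering, ankle angle, peak-loading window, Froude number.

test_that("zero-lag Butterworth meets passband/stopband/DC contracts", {
  rate <- 500
  t <- seq(0, 4, by = 1 / rate)
  s_pass <- sin(2 * pi * 1 * t)
  f_pass <- butterworth_zero_lag(s_pass, 12, rate)
  mid <- seq(rate, length(t) - rate)
  # amplitude preserved and zero phase: pointwise agreement in the passband
  expect_lt(max(abs(f_pass[mid] - s_pass[mid])), 0.01)
  expect_gte(sqrt(mean(f_pass[mid]^2)) / sqrt(mean(s_pass[mid]^2)), 0.999)

  s_stop <- sin(2 * pi * 100 * t)
  f_stop <- butterworth_zero_lag(s_stop, 12, rate)
  expect_lt(max(abs(f_stop[mid])), 0.01)

  const <- rep(3.7, 500)
  expect_equal(butterworth_zero_lag(const, 12, rate), const, tolerance = 1e-9)
  expect_error(butterworth_zero_lag(s_pass, 300, rate), "Nyquist")
  # half-order convention also runs and preserves DC
  expect_equal(butterworth_zero_lag(const, 12, rate, convention = "half-order"),
               const, tolerance = 1e-9)
})

test_that("ankle angle: orthogonal, parallel, constant trials, invariances", {
  frames <- function(epi, mal, cal, met)
    list(epicondyle = matrix(epi, 1), malleolus = matrix(mal, 1),
         calcaneus = matrix(cal, 1), metatarsal = matrix(met, 1))
  # shank vertical, foot horizontal
  expect_equal(ankle_angle(frames(c(0, 1), c(0, 0), c(-0.1, 0), c(0.2, 0))), 90)
  # shank parallel to foot (same direction): 0 by the directed convention
  expect_equal(ankle_angle(frames(c(-1, 0), c(0, 0), c(0, 0), c(1, 0))), 0)
  expect_error(ankle_angle(frames(c(0, 0), c(0, 0), c(0, 0), c(1, 0))),
               "coincident")

  tr <- make_gait_trial(gait_trial_spec(angle_profile = function(s) 75.2))
  ang <- ankle_angle(tr$landmarks)
  expect_equal(ang, rep(75.2, length(ang)), tolerance = 1e-9)

  # translation, rotation, uniform scaling of the lateral view
  lm <- tr$landmarks
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  lm2 <- lapply(lm, function(m) 3.1 * (m %*% t(R)) +
                  matrix(c(5, -2), nrow(m), 2, byrow = TRUE))
  expect_equal(ankle_angle(lm2), ang, tolerance = 1e-9)
})

test_that("peak-loading window thresholds correctly", {
  expect_true(all(peak_loading_window(rep(1, 100))))
  tr <- make_gait_trial(gait_trial_spec(trough = 0.7))
  w <- peak_loading_window(tr$meta$grf_clean)
  expect_equal(attr(w, "n_intervals"), 2L)
  # analytic crossing check: window exactly where the constructed trace > 0.75
  expect_equal(as.logical(w), tr$meta$grf_clean > 0.75)
  expect_error(peak_loading_window(rep(0.6, 50)), "no peak-loading")
})

test_that("mean angle at peak loading: exact, symmetric, noisy, invariances", {
  tr <- make_gait_trial(gait_trial_spec(angle_profile = function(s) 85.6))
  expect_equal(as.numeric(mean_angle_at_peak_loading(tr, filter = FALSE)), 85.6,
               tolerance = 1e-9)
  # linear ramp + symmetric GRFv: windowed mean = midstance angle
  tr2 <- make_gait_trial(gait_trial_spec(angle_profile = function(s) 60 + 30 * s))
  expect_equal(as.numeric(mean_angle_at_peak_loading(tr2, filter = FALSE)), 75,
               tolerance = 0.1)
  # noise on: within 0.5 degrees of stored analytic ground truth
  tr3 <- make_gait_trial(gait_trial_spec(angle_profile = function(s) 75.2,
                                         noise_sd_deg = 0.5, noise_sd_bw = 0.02,
                                         seed = 9))
  m <- mean_angle_at_peak_loading(tr3)
  expect_lt(abs(as.numeric(m) - tr3$meta$true_mean_angle), 0.5)
  expect_gt(attr(m, "coverage"), 0)
  # GRFv rescaling preserving the 0.75 crossing set leaves the window alone
  w1 <- peak_loading_window(tr$meta$grf_clean)
  g2 <- 0.75 + (tr$meta$grf_clean - 0.75) * 1.5
  expect_equal(as.logical(peak_loading_window(g2)), as.logical(w1))
})

test_that("gait CSV round trip and trial validation", {
  tr <- make_gait_trial(gait_trial_spec(angle_profile = function(s) 80 + 5 * s,
                                        noise_sd_deg = 0.2, seed = 3))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_gait_csv(tr, tf)
  tr2 <- read_gait_csv(tf)
  m1 <- as.numeric(mean_angle_at_peak_loading(tr, filter = FALSE))
  m2 <- as.numeric(mean_angle_at_peak_loading(tr2, filter = FALSE))
  expect_equal(m2, m1, tolerance = 0.05)
  expect_true(validate_trial(tr))
  bad <- tr; bad$grfv_bw[1] <- 0.9
  expect_false(validate_trial(bad))
})

test_that("Froude number closed form", {
  expect_equal(round(froude_number(1.2, 0.49), 2), 0.3)
  expect_equal(froude_number(0, 1), 0)
  expect_equal(froude_number(2.4, 0.49), 4 * froude_number(1.2, 0.49))
  expect_error(froude_number(1, 0), "positive")
})
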