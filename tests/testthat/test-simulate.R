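test_that("identical seed and configuration give bit-identical signals", {
  sch <- build_nback_block(2, 8, seed = 1)
  a <- simulate_session(sch, small_model(), seed = 42)
  b <- simulate_session(sch, small_model(), seed = 42)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$ratings, b$ratings)
  c <- simulate_session(sch, small_model(), seed = 43)
  expect_false(identical(a$recording$signal, c$recording$signal))
})

test_that("recording dimensions are consistent with schedule and rate", {
  sch <- build_nback_block(1, 6, seed = 2)
  sess <- simulate_session(sch, small_model(), seed = 1)
  rec <- sess$recording
  expect_equal(nrow(rec$signal), length(rec$channels))
  expect_equal(ncol(rec$signal),
               ceiling((schedule_duration(sch) + 1) * rec$rate))
  expect_false(anyNA(rec$signal))
})

test_that("aliasing guard rejects rates too low for modeled content", {
  expect_error(forward_model(rate = 100), "too low")
  expect_silent(forward_model(rate = 100, emg_amp = 0))
})

test_that("alpha attenuation matches the analytic power ratio (periodogram oracle)", {
  # amplitude factor 1 - k_a at W=1 vs W=0; expected %ERD = (factor^2 - 1)*100
  mod <- pure_model(alpha_depth = 0.4, theta_gain = 0)
  r1 <- simulate_constant_load(mod, W = 1, duration_s = 120, seed = 1)
  r0 <- simulate_constant_load(mod, W = 0, duration_s = 120, seed = 2)
  welch_alpha <- function(rec, ch) {
    sp <- stats::spec.pgram(stats::ts(rec$signal[ch, ], frequency = rec$rate),
                            spans = c(11, 11), taper = 0.1, plot = FALSE)
    mean(sp$spec[sp$freq >= 8 & sp$freq <= 13])
  }
  for (ch in c("Pz", "P3", "P4")) {
    erd <- (welch_alpha(r1, ch) - welch_alpha(r0, ch)) / welch_alpha(r0, ch) * 100
    expect_lt(abs(erd - (0.6^2 - 1) * 100), 8)
  }
})

test_that("zero signature strength yields load-independent band power", {
  mod <- pure_model(alpha_depth = 0, theta_gain = 0, noise_amp = 1)
  r1 <- simulate_constant_load(mod, W = 1, duration_s = 60, seed = 3)
  r0 <- simulate_constant_load(mod, W = 0, duration_s = 60, seed = 4)
  bp <- function(rec, ch, band) {
    band_power(ar_psd(burg(rec$signal[ch, ], 16), rec$rate, 4:13), band)
  }
  expect_lt(abs(bp(r1, "Pz", "alpha") / bp(r0, "Pz", "alpha") - 1), 0.2)
  expect_lt(abs(bp(r1, "Fz", "theta") / bp(r0, "Fz", "theta") - 1), 0.2)
})

test_that("signature direction: theta rises frontally, alpha falls parietally with load", {
  mod <- pure_model(noise_amp = 1)  # default gains, no artifacts
  hi <- simulate_constant_load(mod, W = 0.9, duration_s = 40, seed = 5)
  lo <- simulate_constant_load(mod, W = 0.1, duration_s = 40, seed = 6)
  bp <- function(rec, ch, band) {
    band_power(ar_psd(burg(rec$signal[ch, ], 16), rec$rate, 4:13), band)
  }
  expect_gt(bp(hi, "Fz", "theta"), bp(lo, "Fz", "theta"))
  expect_lt(bp(hi, "Pz", "alpha"), bp(lo, "Pz", "alpha"))
})

test_that("overload reversal folds the signature back above the threshold", {
  sch <- build_nback_block(3, 8, seed = 1)
  prof_hi <- workload_profile(base_load = c("nback.3" = 1), decay = 0,
                              overload = TRUE, overload_threshold = 0.6)
  prof_ref <- workload_profile(base_load = c("nback.3" = 0.2), decay = 0,
                               overload = TRUE, overload_threshold = 0.6)
  mod <- small_model(noise_amp = 0.5, blink_rate = 0, emg_amp = 0,
                     mod_depth = 0, jitter_sd = 0)
  hi <- simulate_session(sch, mod, prof_hi, seed = 7)
  ref <- simulate_session(sch, mod, prof_ref, seed = 7)
  # W=1 folds back to 0.2 under threshold 0.6, matching the W=0.2 session
  expect_equal(hi$recording$signal, ref$recording$signal, tolerance = 1e-10)
})

test_that("artifact injection is the identity when amplitudes are zero", {
  sch <- build_nback_block(2, 6, seed = 3)
  mod <- small_model(blink_rate = 0, emg_amp = 0)
  sess <- simulate_session(sch, mod, seed = 8)
  rec2 <- inject_artifacts(sess$recording, mod, seed = 9)
  expect_identical(rec2$signal, sess$recording$signal)
  expect_identical(rec2$events, sess$recording$events)
})

test_that("EMG bursts raise 20-60 Hz power around keypresses", {
  sch <- build_nback_block(2, 20, seed = 4)
  mod0 <- small_model(blink_rate = 0, emg_amp = 0)
  sess <- simulate_session(sch, mod0, seed = 10)
  mod1 <- small_model(blink_rate = 0, emg_amp = 8)
  with_emg <- inject_artifacts(sess$recording, mod1, seed = 11)
  rate <- with_emg$rate
  kp <- sess$recording$events$onset_s[sess$recording$events$kind == "keypress"]
  hf_power <- function(rec, t0, t1) {
    x <- rec$signal["Fz", (floor(t0 * rate) + 1):floor(t1 * rate)]
    sp <- ar_psd(burg(x, 16), rate, seq(22, 58, by = 4))
    mean(sp$power)
  }
  near <- mean(vapply(kp, function(k) hf_power(with_emg, k - 0.1, k + 0.1), 1))
  far <- mean(vapply(kp, function(k) hf_power(with_emg, k + 0.6, k + 1.2), 1))
  expect_gt(near, 2 * far)
})

test_that("blinks inflate VEOG variance and leak frontally", {
  sch <- build_nback_block(1, 20, seed = 5)
  mod0 <- small_model(blink_rate = 0, emg_amp = 0)
  sess <- simulate_session(sch, mod0, seed = 12)
  mod1 <- small_model(blink_rate = 0.5, blink_amp = 120, emg_amp = 0)
  blinky <- inject_artifacts(sess$recording, mod1, seed = 13)
  expect_gt(stats::var(blinky$signal["VEOG", ]),
            stats::var(sess$recording$signal["VEOG", ]))
  expect_gt(stats::var(blinky$signal["Fz", ]),
            stats::var(sess$recording$signal["Fz", ]))
})

test_that("stationary null model has time-invariant band power", {
  mod <- pure_model(alpha_depth = 0, theta_gain = 0, noise_amp = 1)
  rec <- simulate_constant_load(mod, W = 0.5, duration_s = 80, seed = 14)
  rate <- rec$rate
  thirds <- list(c(0, 25), c(27, 52), c(54, 79))
  bp <- vapply(thirds, function(tt) {
    x <- rec$signal["Pz", (floor(tt[1] * rate) + 1):floor(tt[2] * rate)]
    band_power(ar_psd(burg(x, 16), rate, 4:13), "alpha")
  }, numeric(1))
  expect_lt(max(bp) / min(bp), 1.3)
})

test_that("recordings round-trip through the plain-text container", {
  sch <- build_nback_block(1, 5, seed = 6)
  sess <- simulate_session(sch, small_model(), seed = 15)
  d <- file.path(tempdir(), "rec_container")
  write_recording(sess$recording, d)
  back <- read_recording(d)
  expect_equal(back$rate, sess$recording$rate)
  expect_equal(back$channels, sess$recording$channels)
  expect_equal(back$signal, sess$recording$signal, tolerance = 1e-6)
  expect_equal(nrow(back$events), nrow(sess$recording$events))
  unlink(d, recursive = TRUE)
})
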