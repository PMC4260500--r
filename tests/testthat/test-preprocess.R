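make_contaminated <- function(seed = 1, beta = 0.4) {
  set.seed(seed)
  n <- 2000
  veog <- stats::rnorm(n, sd = 5); veog <- veog - mean(veog)
  heog <- stats::rnorm(n, sd = 3); heog <- heog - mean(heog)
  E <- cbind(veog, heog)
  raw <- matrix(stats::rnorm(3 * n), 3, n)
  # brain signal orthogonal to the EOG channels, so the linear
  # contamination is exactly identifiable
  clean <- raw - raw %*% E %*% solve(crossprod(E)) %*% t(E)
  sig <- rbind(clean + beta * matrix(veog, 3, n, byrow = TRUE),
               veog, heog)
  list(rec = eeg_recording(sig, 200, c("C1", "C2", "C3", "VEOG", "HEOG")),
       clean = clean)
}

test_that("EOG regression removes an exactly linear contamination", {
  cc <- make_contaminated()
  out <- regress_out_eog(cc$rec)
  expect_lt(max(abs(out$signal[1:3, ] - cc$clean)), 1e-9)
  # EOG channels retained unchanged
  expect_identical(out$signal["VEOG", ], cc$rec$signal["VEOG", ])
})

test_that("corrected EEG is orthogonal to the EOG channels and the operation is idempotent", {
  cc <- make_contaminated(seed = 2)
  out <- regress_out_eog(cc$rec)
  v <- out$signal["VEOG", ] - mean(out$signal["VEOG", ])
  for (ch in 1:3) {
    x <- out$signal[ch, ] - mean(out$signal[ch, ])
    expect_lt(abs(mean(x * v)) / (stats::sd(x) * stats::sd(v)), 1e-10)
  }
  twice <- regress_out_eog(out)
  expect_equal(twice$signal, out$signal, tolerance = 1e-10)
})

test_that("zero-variance EOG channels contribute no correction", {
  set.seed(3)
  sig <- rbind(matrix(stats::rnorm(2 * 500), 2, 500), 0)
  rec <- eeg_recording(sig, 100, c("C1", "C2", "VEOG"))
  out <- regress_out_eog(rec, eog_channels = "VEOG")
  expect_equal(out$signal, rec$signal, tolerance = 1e-12)
})

test_that("recordings without EOG channels warn (or error on request)", {
  rec <- eeg_recording(matrix(stats::rnorm(200), 2, 100), 100, c("C1", "C2"))
  expect_warning(out <- regress_out_eog(rec), "no EOG")
  expect_identical(out$signal, rec$signal)
  expect_error(regress_out_eog(rec, on_missing = "error"), "no EOG")
})

test_that("n-back intervals follow the 125-ms rule on the 2000-ms grid", {
  # stimulus at 10.0 s, keypress at 10.8 s -> I_a = [10, 10.675],
  # I_r = [10.925, 12]
  ev <- rbind(
    wmload:::event_row(8, 0.5, "stimulus", "digit", "nback", 1, 1, 5),
    wmload:::event_row(8.8, 0, "keypress", "response", "nback", 1, 1),
    wmload:::event_row(10, 0.5, "stimulus", "digit", "nback", 1, 2, 3),
    wmload:::event_row(10.8, 0, "keypress", "response", "nback", 1, 2),
    wmload:::event_row(12, 0.5, "stimulus", "digit", "nback", 1, 3, 8),
    wmload:::event_row(12.8, 0, "keypress", "response", "nback", 1, 3))
  pairs <- extract_interval_pairs(ev, "nback")
  r2 <- pairs[pairs$trial_index == 2, ]
  expect_equal(r2$ia_start, 10)
  expect_equal(r2$ia_end, 10.675)
  expect_equal(r2$ir_start, 10.925)
  expect_equal(r2$ir_end, 12)
})

test_that("trials whose trimmed intervals fall below the minimum are discarded whole", {
  ev <- rbind(
    wmload:::event_row(0, 0.5, "stimulus", "digit", "nback", 1, 1, 5),
    wmload:::event_row(0.15, 0, "keypress", "response", "nback", 1, 1),  # RT 150 ms
    wmload:::event_row(2, 0.5, "stimulus", "digit", "nback", 1, 2, 3),
    wmload:::event_row(2.8, 0, "keypress", "response", "nback", 1, 2))
  pairs <- extract_interval_pairs(ev, "nback")
  expect_false(1 %in% pairs$trial_index)  # I_a would be 25 ms
  expect_true(2 %in% pairs$trial_index)
  expect_equal(attr(pairs, "n_dropped"), 1L)
})

test_that("no returned interval touches any keypress guard zone", {
  sch <- build_study2_schedule(seed = 21, config = small_cfg())
  ev <- as.data.frame(sch)
  kp <- ev$onset_s[ev$kind == "keypress"]
  for (task in c("nback", "reading_span", "subtraction", "fraction")) {
    pairs <- extract_interval_pairs(ev, task)
    for (col in list(c("ia_start", "ia_end"), c("ir_start", "ir_end"))) {
      lo <- pairs[[col[1]]]; hi <- pairs[[col[2]]]
      for (i in seq_along(lo)) {
        inside <- kp > lo[i] - 0.125 + 1e-9 & kp < hi[i] + 0.125 - 1e-9
        expect_false(any(inside))
      }
      expect_true(all(hi - lo >= 0.25))
    }
  }
})

test_that("interval extraction rejects unknown tasks and empty event sets", {
  sch <- build_nback_block(1, 6, seed = 1)
  expect_error(extract_interval_pairs(as.data.frame(sch), "sternberg"),
               "unknown task")
  expect_error(extract_interval_pairs(as.data.frame(sch), "fraction"),
               "no events")
})

test_that("study windows segment into exactly three 15-s epochs each", {
  sch <- build_study1_schedule(seed = 31)
  mod <- forward_model(rate = 64, emg_amp = 0, blink_rate = 0)
  sess <- simulate_session(sch, mod, seed = 32)
  ep <- segment_study_windows(sess$recording)
  expect_equal(sum(ep$task_id == "study1_theorem"), 45)
  expect_equal(sum(ep$task_id == "study1_comic"), 45)
  expect_true(all(ep$end_s - ep$start_s == 15))
  expect_equal(attr(ep, "n_dropped"), 0L)
  # provenance round-trip: every epoch maps to exactly one window
  expect_equal(nrow(unique(ep[, c("task_id", "trial_index")])), 30)
  expect_error(segment_study_windows(sess$recording, 45, 20), "multiple")
})

test_that("artifact-contaminated windows are dropped whole", {
  sch <- build_study1_schedule(seed = 33)
  mod <- forward_model(rate = 64, emg_amp = 0, blink_rate = 0)
  sess <- simulate_session(sch, mod, seed = 34)
  rec <- sess$recording
  ev <- rec$events
  win <- ev[ev$kind == "stimulus" & ev$code == "study_window" &
              ev$task_id == "study1_theorem", ][1, ]
  i0 <- floor((win$onset_s + 5) * rec$rate)
  rec$signal["Fz", i0:(i0 + 10)] <- 500  # gross artifact inside one window
  ep <- segment_study_windows(rec)
  expect_equal(sum(ep$task_id == "study1_theorem"), 42)
  expect_equal(sum(ep$task_id == "study1_comic"), 45)
  expect_equal(attr(ep, "n_dropped"), 1L)
})

test_that("sample slicing is half-open and length-exact", {
  rec <- eeg_recording(matrix(seq_len(1000), 1, 1000), 100, "C1")
  sl <- epoch_signal(rec, 1, 2.5)
  expect_equal(ncol(sl), 150)
  expect_equal(unname(sl[1, 1]), 101)
  a <- epoch_signal(rec, 0, 1)
  b <- epoch_signal(rec, 1, 2)
  expect_equal(c(ncol(a), ncol(b)), c(100, 100))
  expect_equal(a[1, 100] + 1, b[1, 1])  # adjacent windows share no sample
  expect_error(epoch_signal(rec, 2, 1), "exceed")
})
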