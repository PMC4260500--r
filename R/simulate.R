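# Synthetic-EEG forward model. Two narrowband oscillators (amplitude
# modulated sinusoids with small frequency jitter) are mixed into the montage
# through fixed spatial weights: a frontal-midline theta source whose
# amplitude grows with latent load W (theta ERS) and a parietal alpha source
# whose amplitude shrinks with W (alpha ERD), on top of 1/f background
# noise, a slow multiplicative session drift, ocular and keypress-EMG
# artifacts.

DEFAULT_EEG <- c("F3", "Fz", "F4", "FC1", "FC2", "CP1", "CP2", "P3", "Pz", "P4")
DEFAULT_CHANNELS <- c(DEFAULT_EEG, "VEOG", "HEOG")

default_theta_weights <- function() {
  c(F3 = 0.6, Fz = 1, F4 = 0.6, FC1 = 0.8, FC2 = 0.8,
    CP1 = 0.25, CP2 = 0.25, P3 = 0.15, Pz = 0.15, P4 = 0.15,
    VEOG = 0, HEOG = 0)
}

default_alpha_weights <- function() {
  c(F3 = 0.15, Fz = 0.15, F4 = 0.15, FC1 = 0.3, FC2 = 0.3,
    CP1 = 0.8, CP2 = 0.8, P3 = 1, Pz = 1, P4 = 1,
    VEOG = 0, HEOG = 0)
}

default_blink_leak <- function() {
  c(F3 = 0.18, Fz = 0.2, F4 = 0.18, FC1 = 0.1, FC2 = 0.1,
    CP1 = 0.05, CP2 = 0.05, P3 = 0.03, Pz = 0.03, P4 = 0.03,
    VEOG = 1, HEOG = 0.1)
}

#' Forward model for synthetic EEG sessions
#'
#' @param channels channel labels; non-EOG labels are treated as EEG
#' @param rate sampling rate in Hz; must exceed twice the highest modeled
#'   frequency (EMG reaches 60 Hz when its amplitude is positive)
#' @param theta_freq,theta_amp,theta_gain frontal-midline theta source:
#'   center frequency (4-7 Hz), base amplitude in microvolts, and load gain
#'   k_t >= 0 (amplitude factor `1 + k_t W`)
#' @param alpha_freq,alpha_amp,alpha_depth parietal alpha source: center
#'   frequency (8-13 Hz), base amplitude, and load attenuation k_a in
#'   \[0, 1\] (amplitude factor `1 - k_a W`)
#' @param theta_weights,alpha_weights named non-negative spatial weights
#' @param noise_amp 1/f background noise standard deviation (microvolts)
#' @param drift_amp,drift_period_s multiplicative slow gain
#'   `g(t) = 1 + drift_amp * sin(2 pi t / period)` scaling the whole channel
#'   (oscillators and background noise; electrode/impedance drift)
#' @param blink_rate,blink_amp ocular artifacts: Poisson rate (per second)
#'   and template amplitude; propagated into EEG channels by `blink_leak`
#' @param blink_leak named per-channel blink propagation weights
#' @param emg_amp keypress EMG burst amplitude (20-60 Hz, 200 ms)
#' @param jitter_sd slow frequency jitter of the oscillators (Hz)
#' @param mod_depth depth of the slow random amplitude modulation
#' @param eog_noise baseline EOG channel noise (microvolts)
#' @export
forward_model <- function(channels = DEFAULT_CHANNELS, rate = 500,
                          theta_freq = 6, theta_amp = 4, theta_gain = 1.5,
                          alpha_freq = 10, alpha_amp = 6, alpha_depth = 0.8,
                          theta_weights = default_theta_weights(),
                          alpha_weights = default_alpha_weights(),
                          noise_amp = 2, drift_amp = 0.1,
                          drift_period_s = 300, blink_rate = 0.08,
                          blink_amp = 120, blink_leak = default_blink_leak(),
                          emg_amp = 4, jitter_sd = 0.15, mod_depth = 0.1,
                          eog_noise = 1) {
  stopifnot(theta_freq >= 4, theta_freq <= 7, alpha_freq >= 8, alpha_freq <= 13,
            theta_gain >= 0, alpha_depth >= 0, alpha_depth <= 1,
            all(theta_weights >= 0), all(alpha_weights >= 0),
            drift_amp >= 0, drift_amp < 1, blink_rate >= 0, emg_amp >= 0)
  f_max <- max(theta_freq, alpha_freq, if (emg_amp > 0) 60 else 0)
  if (rate <= 2 * f_max)
    stopf("sampling rate %g Hz too low for modeled frequencies (max %g Hz)",
          rate, f_max)
  m <- list(channels = channels, rate = rate,
            theta = list(freq = theta_freq, amp = theta_amp, gain = theta_gain,
                         weights = theta_weights),
            alpha = list(freq = alpha_freq, amp = alpha_amp, depth = alpha_depth,
                         weights = alpha_weights),
            noise_amp = noise_amp,
            drift = list(amp = drift_amp, period_s = drift_period_s),
            blink = list(rate = blink_rate, amp = blink_amp, leak = blink_leak),
            emg = list(amp = emg_amp, lo = 20, hi = 60, dur_s = 0.2),
            jitter_sd = jitter_sd, mod_depth = mod_depth, eog_noise = eog_noise)
  structure(m, class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat("<forward_model>", length(x$channels), "channels @", x$rate, "Hz;",
      sprintf("theta %g Hz (gain %g), alpha %g Hz (depth %g)\n",
              x$theta$freq, x$theta$gain, x$alpha$freq, x$alpha$depth))
  invisible(x)
}

is_eog <- function(channels) grepl("EOG$", channels)

#' Multichannel EEG recording container
#'
#' @param signal channels x samples matrix, microvolts
#' @param rate sampling rate, Hz
#' @param channels channel labels (length = nrow(signal))
#' @param events event data frame (see schedulers)
#' @export
eeg_recording <- function(signal, rate, channels, events = NULL) {
  if (nrow(signal) != length(channels))
    stopf("channel count (%d) != label count (%d)", nrow(signal), length(channels))
  rownames(signal) <- channels
  structure(list(signal = signal, rate = rate, channels = channels,
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording>", length(x$channels), "channels x", ncol(x$signal),
      "samples @", x$rate, "Hz",
      sprintf("(%.1f s)\n", ncol(x$signal) / x$rate))
  invisible(x)
}

# 1/f (pink) background noise via spectral shaping, unit variance
pink_noise <- function(n) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  f <- c(1, seq_len(m - 1))
  f <- pmin(f, m - f + 1)  # mirrored frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

# slow random modulation: Gaussian knots interpolated onto the sample grid
slow_noise <- function(n, rate, knot_spacing_s = 2) {
  k <- max(3L, ceiling(n / rate / knot_spacing_s) + 2L)
  kt <- seq(0, n / rate, length.out = k)
  kv <- stats::rnorm(k)
  stats::approx(kt, kv, xout = (seq_len(n) - 1) / rate, rule = 2)$y
}

# per-sample latent load from trial activation spans
sample_load <- function(n, rate, spans, workload, rest) {
  w <- rep(rest, n)
  if (nrow(spans) == 0L) return(w)
  key_sp <- paste(spans$task_id, spans$level, spans$trial_index)
  key_wl <- paste(workload$task_id, workload$level, workload$trial_index)
  Wv <- workload$W[match(key_sp, key_wl)]
  for (i in seq_len(nrow(spans))) {
    i1 <- max(1L, floor(spans$start[i] * rate) + 1L)
    i2 <- min(n, floor(spans$end[i] * rate))
    if (i2 >= i1 && !is.na(Wv[i])) w[i1:i2] <- Wv[i]
  }
  w
}

# NB: every stochastic component below consumes the RNG stream
# unconditionally, so runs that differ only in an amplitude setting (drift,
# modulation, jitter) stay sample-paired under the same seed
oscillator <- function(n, rate, freq, jitter_sd) {
  dfreq <- slow_noise(n, rate, 1) * jitter_sd
  phase <- 2 * pi * cumsum(rep(freq, n) + dfreq) / rate + stats::runif(1, 0, 2 * pi)
  sin(phase)
}

# core signal synthesis shared by simulate_session() and
# simulate_constant_load(); w is the per-sample latent load
synth_signal <- function(model, n, w) {
  rate <- model$rate
  th <- model$theta; al <- model$alpha
  osc_t <- oscillator(n, rate, th$freq, model$jitter_sd)
  osc_a <- oscillator(n, rate, al$freq, model$jitter_sd)
  mod_t <- pmax(1 + model$mod_depth * slow_noise(n, rate), 0)
  mod_a <- pmax(1 + model$mod_depth * slow_noise(n, rate), 0)
  env_t <- th$amp * (1 + th$gain * w) * mod_t
  env_a <- al$amp * pmax(1 - al$depth * w, 0) * mod_a
  # multiplicative slow gain: models electrode/impedance drift, so it scales
  # the whole channel (oscillators and background noise alike) — this is
  # what the within-trial power ratio cancels
  g <- 1 + model$drift$amp * sin(2 * pi * (seq_len(n) - 1) / rate / model$drift$period_s +
                                   stats::runif(1, 0, 2 * pi))
  src_t <- env_t * osc_t
  src_a <- env_a * osc_a
  chans <- model$channels
  sig <- matrix(0, nrow = length(chans), ncol = n, dimnames = list(chans, NULL))
  wt <- model$theta$weights; wa <- model$alpha$weights
  for (c in seq_along(chans)) {
    ch <- chans[c]
    w1 <- unname(wt[ch]); if (is.na(w1)) w1 <- 0
    w2 <- unname(wa[ch]); if (is.na(w2)) w2 <- 0
    x <- w1 * src_t + w2 * src_a
    noise_sd <- if (is_eog(ch)) model$eog_noise else model$noise_amp
    if (noise_sd > 0) x <- x + noise_sd * pink_noise(n)
    sig[c, ] <- g * x
  }
  sig
}

#' Simulate a full EEG session for a schedule
#'
#' Per channel c the signal is
#' `x_c(t) = g(t) * [w_theta_c A_theta (1 + k_t W(t)) osc_theta(t) +
#'                   w_alpha_c A_alpha (1 - k_a W(t)) osc_alpha(t)]
#'           + pink noise + artifacts`,
#' where the latent load W(t) equals the trial's workload during that
#' trial's engagement span (stimulus/letter/problem processing) and a low
#' rest level otherwise. Under the overload regime, load above the threshold
#' folds back (theta desynchronises, alpha synchronises again). Subjective
#' ratings are drawn per learning-task trial and per working-memory block.
#' Fully reproducible from `seed`.
#'
#' @param schedule a `session_schedule`
#' @param model a [forward_model()]
#' @param profile a [workload_profile()]
#' @param rmodel a [rating_model()]
#' @param seed integer seed
#' @return object of class `wml_session`: list with `recording`
#'   ([eeg_recording()]), `ratings` (one row per rating prompt: task_id,
#'   level, trial_index — NA for block ratings — rating, W), `error_rates`
#'   (per task x level), and `workload` (per-trial W)
#' @export
simulate_session <- function(schedule, model = forward_model(),
                             profile = workload_profile(),
                             rmodel = rating_model(), seed = 1) {
  set.seed(child_seed(seed, 101))
  ev <- as.data.frame(schedule)
  rate <- model$rate
  n <- ceiling((schedule_duration(schedule) + 1) * rate)

  workload <- simulate_latent_workload(schedule, profile)
  spans <- activation_spans(ev)
  w_raw <- sample_load(n, rate, spans, workload, profile$rest)
  w <- if (profile$overload) {
    thr <- profile$overload_threshold
    ifelse(w_raw <= thr, w_raw, pmax(0, 2 * thr - w_raw))
  } else w_raw

  sig <- synth_signal(model, n, w)
  rec <- eeg_recording(sig, rate, model$channels, events = ev)
  rec <- inject_artifacts(rec, model, seed = child_seed(seed, 102))

  # subjective ratings: trial-level prompts read the trial's W, block-level
  # prompts the mean W of their block's trials
  prompts <- which(ev$kind == "rating_prompt")
  ratings <- NULL
  if (length(prompts) > 0L) {
    key_wl <- paste(workload$task_id, workload$level, workload$trial_index)
    rW <- numeric(length(prompts))
    for (j in seq_along(prompts)) {
      p <- ev[prompts[j], ]
      if (!is.na(p$trial_index)) {
        rW[j] <- workload$W[match(paste(p$task_id, p$level, p$trial_index), key_wl)]
      } else {
        sel <- workload$task_id == p$task_id &
          (is.na(p$level) | workload$level == p$level)
        rW[j] <- mean(workload$W[sel])
      }
    }
    ratings <- data.frame(task_id = ev$task_id[prompts],
                          level = ev$level[prompts],
                          trial_index = ev$trial_index[prompts],
                          W = rW,
                          rating = draw_ratings(rW, rmodel),
                          stringsAsFactors = FALSE)
    rec$events$value[prompts] <- ratings$rating
  }

  # block error rates: error probability rises with latent load
  p_err <- pmin(pmax(0.02 + 0.35 * workload$W, 0), 1)
  err <- stats::rbinom(nrow(workload), 1, p_err)
  error_rates <- stats::aggregate(err, by = list(task_id = workload$task_id,
                                                 level = workload$level),
                                  FUN = mean)
  names(error_rates)[3] <- "error_rate"

  structure(list(recording = rec, ratings = ratings, error_rates = error_rates,
                 workload = workload, subject_id = attr(schedule, "subject_id")),
            class = "wml_session")
}

#' @export
print.wml_session <- function(x, ...) {
  cat("<wml_session> subject", x$subject_id %||% "?", "\n")
  print(x$recording)
  if (!is.null(x$ratings)) cat(" ", nrow(x$ratings), "rating records\n")
  invisible(x)
}

#' Simulate a stationary constant-load segment
#'
#' Generates a segment with the latent load held fixed at `W` everywhere, no
#' drift and no artifacts — the direct route to analytic band-power
#' expectations (the alpha amplitude factor is `1 - k_a W`, so the expected
#' alpha-power ratio between two load levels is the squared amplitude
#' ratio).
#'
#' @param model a [forward_model()]
#' @param W latent load in \[0, 1\]
#' @param duration_s segment length in seconds
#' @param seed integer seed
#' @return an [eeg_recording()]
#' @export
simulate_constant_load <- function(model = forward_model(), W = 0.5,
                                   duration_s = 60, seed = 1) {
  stopifnot(W >= 0, W <= 1, duration_s > 0)
  set.seed(child_seed(seed, 103))
  model$drift$amp <- 0
  n <- ceiling(duration_s * model$rate)
  sig <- synth_signal(model, n, rep(W, n))
  eeg_recording(sig, model$rate, model$channels)
}

#' Add ocular and keypress-EMG artifacts to a recording
#'
#' Blink templates (400-ms raised cosine) are placed at Poisson-distributed
#' times on the VEOG channel and propagated into the EEG channels by the
#' model's frontal-weighted leak coefficients; 200-ms band-limited 20-60 Hz
#' EMG bursts are centered on every keypress event. Events are preserved.
#' With blink rate 0 and EMG amplitude 0 the recording is returned
#' unchanged.
#'
#' @param recording an [eeg_recording()]
#' @param model a [forward_model()]
#' @param seed integer seed
#' @export
inject_artifacts <- function(recording, model = forward_model(), seed = 1) {
  rate <- recording$rate
  n <- ncol(recording$signal)
  do_blink <- model$blink$rate > 0 && model$blink$amp > 0
  do_emg <- model$emg$amp > 0
  if (!do_blink && !do_emg) return(recording)
  set.seed(child_seed(seed, 104))
  sig <- recording$signal

  if (do_blink) {
    dur <- n / rate
    n_blinks <- stats::rpois(1, model$blink$rate * dur)
    if (n_blinks > 0) {
      t_blink <- sort(stats::runif(n_blinks, 0, dur))
      w_len <- round(0.4 * rate)
      template <- model$blink$amp * 0.5 * (1 - cos(2 * pi * seq_len(w_len) / (w_len + 1)))
      leak <- model$blink$leak
      for (tb in t_blink) {
        i1 <- floor(tb * rate) + 1L
        i2 <- min(n, i1 + w_len - 1L)
        seg <- seq_len(i2 - i1 + 1L)
        for (c in seq_along(recording$channels)) {
          lw <- leak[recording$channels[c]] %||% 0
          if (is.na(lw)) lw <- 0
          if (lw > 0) sig[c, i1:i2] <- sig[c, i1:i2] + lw * template[seg]
        }
      }
    }
  }

  if (do_emg && !is.null(recording$events)) {
    kp <- recording$events$onset_s[recording$events$kind == "keypress"]
    half <- round(model$emg$dur_s / 2 * rate)
    for (tk in kp) {
      ic <- floor(tk * rate) + 1L
      i1 <- max(1L, ic - half)
      i2 <- min(n, ic + half - 1L)
      len <- i2 - i1 + 1L
      if (len < 8L) next
      burst <- band_limited_noise(len, rate, model$emg$lo, model$emg$hi) * model$emg$amp
      eeg <- !is_eog(recording$channels)
      sig[eeg, i1:i2] <- sweep(sig[eeg, i1:i2, drop = FALSE], 2, burst, `+`)
    }
  }

  recording$signal <- sig
  recording
}

# band-limited Gaussian noise via FFT masking, unit variance in the band
band_limited_noise <- function(n, rate, lo, hi) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)
  W[f < lo | f > hi] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Write / read a recording as a plain-text container
#'
#' The container is a directory holding `signal.csv` (samples x channels,
#' header row of channel labels), `header.json` (rate, channels, duration)
#' and `events.tsv`.
#'
#' @param recording an [eeg_recording()]
#' @param dir output directory (created if missing)
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(t(recording$signal), file.path(dir, "signal.csv"),
                     sep = ",", row.names = FALSE,
                     col.names = recording$channels, quote = FALSE)
  jsonlite::write_json(list(rate = recording$rate,
                            channels = recording$channels,
                            n_samples = ncol(recording$signal)),
                       file.path(dir, "header.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(recording$events)) {
    utils::write.table(recording$events, file.path(dir, "events.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "header.json"),
                             simplifyVector = TRUE)
  sig <- as.matrix(utils::read.csv(file.path(dir, "signal.csv"),
                                   check.names = FALSE))
  ev_path <- file.path(dir, "events.tsv")
  ev <- if (file.exists(ev_path)) utils::read.delim(ev_path) else NULL
  eeg_recording(t(sig), hdr$rate, hdr$channels, events = ev)
}
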