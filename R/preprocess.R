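# Preprocessing: EOG regression, keypress-safe activation/resting interval
# extraction for the cross-task paradigms, and fixed-epoch segmentation of
# study windows for the alternating-materials design.
#
# Time-to-sample conversion is half-open throughout: a window [a, b) maps to
# samples floor(a * rate) + 1 .. floor(b * rate), so adjacent windows never
# share a sample and counts are exact.

#' Slice a recording between two time points
#'
#' @param recording an [eeg_recording()]
#' @param start_s,end_s window in seconds, half-open `[start, end)`
#' @param channels channel subset (default all)
#' @return channels x samples matrix
#' @export
epoch_signal <- function(recording, start_s, end_s, channels = NULL) {
  if (end_s <= start_s) stopf("end_s must exceed start_s")
  rate <- recording$rate
  i1 <- floor(start_s * rate) + 1L
  i2 <- floor(end_s * rate)
  i2 <- min(i2, ncol(recording$signal))
  sel <- if (is.null(channels)) seq_along(recording$channels)
         else match(channels, recording$channels)
  if (anyNA(sel)) stopf("unknown channel(s): %s",
                        paste(channels[is.na(sel)], collapse = ", "))
  recording$signal[sel, i1:i2, drop = FALSE]
}

#' Regress eye activity out of the EEG channels
#'
#' Least-squares regression of every EEG channel onto the EOG channels
#' (coefficients from the full-recording covariance, Schloegl-style); the
#' EOG channels themselves are retained unchanged. A zero-variance EOG
#' channel contributes nothing (its coefficient is zero). The operation is
#' idempotent up to numerical precision.
#'
#' @param recording an [eeg_recording()]
#' @param eog_channels labels of the EOG channels
#' @param on_missing "warn" returns the recording unchanged with a warning
#'   when no EOG channel is present; "error" stops
#' @export
regress_out_eog <- function(recording, eog_channels = c("VEOG", "HEOG"),
                            on_missing = c("warn", "error")) {
  on_missing <- match.arg(on_missing)
  present <- intersect(eog_channels, recording$channels)
  if (length(present) == 0L) {
    if (on_missing == "error") stopf("no EOG channel present in recording")
    warning("no EOG channel present; recording returned unchanged")
    return(recording)
  }
  eog_idx <- match(present, recording$channels)
  eeg_idx <- setdiff(seq_along(recording$channels), eog_idx)
  E <- t(recording$signal[eog_idx, , drop = FALSE])
  X <- t(recording$signal[eeg_idx, , drop = FALSE])
  Ec <- sweep(E, 2, colMeans(E))
  fit <- stats::lm.fit(Ec, X)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0  # rank-deficient / zero-variance regressors
  cleaned <- X - Ec %*% beta
  out <- recording
  out$signal[eeg_idx, ] <- t(cleaned)
  out
}

# engagement spans per trial: the periods during which the task imposes its
# load (used by the forward model's load gating and mirrored by the
# activation intervals)
activation_spans <- function(events) {
  ev <- as.data.frame(events)
  out <- list()
  grab <- function(df) if (nrow(df)) out[[length(out) + 1L]] <<- df

  # n-back: digit onset until the trial's keypress
  st <- ev[ev$kind == "stimulus" & ev$code == "digit", ]
  if (nrow(st)) {
    kp <- ev[ev$kind == "keypress" & ev$task_id == "nback", ]
    key <- paste(st$level, st$trial_index)
    kp_t <- kp$onset_s[match(key, paste(kp$level, kp$trial_index))]
    grab(data.frame(task_id = "nback", level = st$level,
                    trial_index = st$trial_index,
                    start = st$onset_s, end = kp_t))
  }
  # reading span: the letter presentation
  st <- ev[ev$kind == "stimulus" & ev$code == "letter", ]
  if (nrow(st)) {
    grab(data.frame(task_id = "reading_span", level = st$level,
                    trial_index = st$trial_index,
                    start = st$onset_s, end = st$onset_s + st$duration_s))
  }
  # word problems: the problem statement (self-paced, ends with keypress)
  st <- ev[ev$kind == "stimulus" & ev$code == "problem", ]
  if (nrow(st)) {
    grab(data.frame(task_id = st$task_id, level = st$level,
                    trial_index = st$trial_index,
                    start = st$onset_s, end = st$onset_s + st$duration_s))
  }
  # alternating-materials design: the whole study window
  st <- ev[ev$kind == "stimulus" & ev$code == "study_window", ]
  if (nrow(st)) {
    grab(data.frame(task_id = st$task_id, level = st$level,
                    trial_index = st$trial_index,
                    start = st$onset_s, end = st$onset_s + st$duration_s))
  }
  if (length(out) == 0L)
    return(data.frame(task_id = character(), level = integer(),
                      trial_index = integer(), start = numeric(),
                      end = numeric()))
  do.call(rbind, out)
}

# largest sub-interval of [a, b] that avoids every keypress guard zone
# [kp - g, kp + g]; NULL if none at least min_len long
free_subinterval <- function(a, b, kp, g, min_len) {
  z <- kp[kp > a - g & kp < b + g]
  if (length(z) == 0L) {
    return(if (b - a >= min_len) c(a, b) else NULL)
  }
  z <- sort(z)
  cuts_lo <- c(a, z + g)
  cuts_hi <- c(z - g, b)
  len <- cuts_hi - cuts_lo
  best <- which.max(len)
  if (len[best] >= min_len) c(cuts_lo[best], cuts_hi[best]) else NULL
}

#' Extract per-trial activation/resting interval pairs
#'
#' For every trial of a cross-task paradigm, cuts the activation interval
#' I_a (the period imposing the task-specific load) and the resting interval
#' I_r (low load). All returned intervals end at least `guard` seconds
#' before any keypress and start at least `guard` seconds after any keypress
#' (default 125 ms, excluding motor planning and motor execution artifacts);
#' a trial whose I_a or I_r would be shorter than `min_duration` after
#' trimming is discarded whole.
#'
#' Interval definitions: n-back — I_a from digit onset to keypress, I_r from
#' keypress to the next digit onset; reading span — I_a the 1000-ms letter
#' presentation, I_r from the sentence-verification keypress to the letter
#' onset; word problems — I_a from problem-statement onset to the answer
#' keypress, I_r from the choice keypress to the next fact page.
#'
#' @param x an [eeg_recording()] or an event data frame / `session_schedule`
#' @param task_id one of nback, reading_span, subtraction, fraction
#' @param min_duration minimum interval length in seconds
#' @param guard keypress exclusion half-width in seconds
#' @return data frame of class `interval_pairs`: task_id, level,
#'   trial_index, ia_start, ia_end, ir_start, ir_end; the number of
#'   discarded trials is in `attr(, "n_dropped")`
#' @export
extract_interval_pairs <- function(x, task_id, min_duration = 0.25,
                                   guard = 0.125) {
  ev <- if (inherits(x, "eeg_recording")) x$events else as.data.frame(x)
  if (is.null(ev)) stopf("no events available")
  if (!task_id %in% c(WM_TASKS, LEARNING_TASKS))
    stopf("unknown task_id '%s'", task_id)
  kp_all <- ev$onset_s[ev$kind == "keypress"]

  te <- ev[!is.na(ev$task_id) & ev$task_id == task_id, ]
  if (nrow(te) == 0L) stopf("no events for task '%s'", task_id)

  raw <- list()
  if (task_id == "nback") {
    st <- te[te$kind == "stimulus" & te$code == "digit", ]
    kp <- te[te$kind == "keypress", ]
    for (lev in unique(st$level)) {
      sl <- st[st$level == lev, ]
      sl <- sl[order(sl$trial_index), ]
      isi <- if (nrow(sl) > 1) stats::median(diff(sl$onset_s)) else 2
      kp_t <- kp$onset_s[match(paste(lev, sl$trial_index),
                               paste(kp$level, kp$trial_index))]
      nxt <- c(sl$onset_s[-1], sl$onset_s[nrow(sl)] + isi)
      raw[[length(raw) + 1L]] <-
        data.frame(level = lev, trial_index = sl$trial_index,
                   ia_lo = sl$onset_s, ia_hi = kp_t, ir_lo = kp_t, ir_hi = nxt)
    }
  } else if (task_id == "reading_span") {
    st <- te[te$kind == "stimulus" & te$code == "letter", ]
    kp <- te[te$kind == "keypress", ]
    kp_t <- kp$onset_s[match(paste(st$level, st$trial_index),
                             paste(kp$level, kp$trial_index))]
    raw[[1L]] <- data.frame(level = st$level, trial_index = st$trial_index,
                            ia_lo = st$onset_s,
                            ia_hi = st$onset_s + st$duration_s,
                            ir_lo = kp_t, ir_hi = st$onset_s)
  } else {
    pr <- te[te$kind == "stimulus" & te$code == "problem", ]
    fa <- te[te$kind == "stimulus" & te$code == "facts", ]
    ch <- te[te$kind == "keypress" & te$code == "choice", ]
    for (lev in unique(pr$level)) {
      pl <- pr[pr$level == lev, ]
      pl <- pl[order(pl$trial_index), ]
      fl <- fa[fa$level == lev, ]
      chl_t <- ch$onset_s[match(paste(lev, pl$trial_index),
                                paste(ch$level, ch$trial_index))]
      nxt_facts <- fl$onset_s[match(pl$trial_index + 1L, fl$trial_index)]
      # last problem of a level: rest until the block ends (fixation+rating)
      be <- te[te$kind == "block_end" & te$level == lev, ]
      nxt_facts[is.na(nxt_facts)] <- if (nrow(be)) be$onset_s[1] else
        chl_t[is.na(nxt_facts)] + 2.5
      raw[[length(raw) + 1L]] <-
        data.frame(level = lev, trial_index = pl$trial_index,
                   ia_lo = pl$onset_s, ia_hi = pl$onset_s + pl$duration_s,
                   ir_lo = chl_t, ir_hi = nxt_facts)
    }
  }
  raw <- do.call(rbind, raw)

  keep <- logical(nrow(raw))
  ia <- matrix(NA_real_, nrow(raw), 2)
  ir <- matrix(NA_real_, nrow(raw), 2)
  for (i in seq_len(nrow(raw))) {
    a <- free_subinterval(raw$ia_lo[i], raw$ia_hi[i], kp_all, guard, min_duration)
    r <- free_subinterval(raw$ir_lo[i], raw$ir_hi[i], kp_all, guard, min_duration)
    if (!is.null(a) && !is.null(r)) {
      keep[i] <- TRUE
      ia[i, ] <- a
      ir[i, ] <- r
    }
  }
  if (!any(keep)) stopf("no valid trials for task '%s'", task_id)
  out <- data.frame(task_id = task_id, level = raw$level[keep],
                    trial_index = raw$trial_index[keep],
                    ia_start = ia[keep, 1], ia_end = ia[keep, 2],
                    ir_start = ir[keep, 1], ir_end = ir[keep, 2])
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("interval_pairs", "data.frame")
  out
}

#' Segment study windows into fixed-length epochs
#'
#' Splits every artifact-free 45-s study window into non-overlapping 15-s
#' epochs tagged with the window's material type. Windows whose EEG
#' peak-to-peak amplitude exceeds `amp_threshold` anywhere are dropped
#' whole.
#'
#' @param recording an [eeg_recording()] with study-window events
#' @param window_len_s study-window length; must be a multiple of
#'   `epoch_len_s`
#' @param epoch_len_s epoch length
#' @param amp_threshold peak-to-peak artifact threshold in microvolts
#' @return data frame of class `wml_epochs`: task_id, trial_index (window),
#'   epoch_index, start_s, end_s; dropped window count in
#'   `attr(, "n_dropped")`
#' @export
segment_study_windows <- function(recording, window_len_s = 45,
                                  epoch_len_s = 15, amp_threshold = 150) {
  if (window_len_s %% epoch_len_s != 0)
    stopf("window length (%g s) is not a multiple of epoch length (%g s)",
          window_len_s, epoch_len_s)
  ev <- recording$events
  win <- ev[ev$kind == "stimulus" & ev$code == "study_window", ]
  if (nrow(win) == 0L) stopf("no study-window events in recording")
  k <- window_len_s %/% epoch_len_s
  eeg <- recording$channels[!is_eog(recording$channels)]
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(win))) {
    sl <- epoch_signal(recording, win$onset_s[i], win$onset_s[i] + window_len_s,
                       channels = eeg)
    ptp <- max(apply(sl, 1, function(v) diff(range(v))))
    if (ptp > amp_threshold) {
      dropped <- dropped + 1L
      next
    }
    for (j in seq_len(k)) {
      rows[[length(rows) + 1L]] <-
        data.frame(task_id = win$task_id[i], trial_index = win$trial_index[i],
                   epoch_index = j,
                   start_s = win$onset_s[i] + (j - 1) * epoch_len_s,
                   end_s = win$onset_s[i] + j * epoch_len_s)
    }
  }
  if (length(rows) == 0L) stopf("all study windows were rejected as artifacts")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  class(out) <- c("wml_epochs", "data.frame")
  out
}
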