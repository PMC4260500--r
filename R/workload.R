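# Latent workload model: every (task, level) carries a base load in [0, 1]
# that decays exponentially over trials within the level (learning: the
# subjectively experienced load of a fixed objective difficulty drops as
# expertise builds), down to a floor. Subjective 7-point ratings are a noisy
# monotone readout of the latent load.

default_base_load <- function() {
  c("nback.1" = 0.25, "nback.2" = 0.55, "nback.3" = 0.88,
    "reading_span.1" = 0.22, "reading_span.2" = 0.52, "reading_span.3" = 0.85,
    "subtraction.1" = 0.08, "subtraction.2" = 0.30, "subtraction.3" = 0.65,
    "fraction.1" = 0.32, "fraction.2" = 0.62, "fraction.3" = 0.95,
    "study1_theorem" = 0.75, "study1_comic" = 0.25)
}

#' Latent workload profile
#'
#' Maps each task x difficulty level to a base latent working-memory load W
#' in \[0, 1\] and controls its exponential decay over trials within a level
#' (the expertise effect), the floor it decays towards, the low load level
#' assumed outside task-engagement periods, and an optional overload regime
#' in which the oscillatory signature inverts above a threshold
#' (disengagement under extreme load).
#'
#' @param base_load named numeric vector, names "task.level" (or "task" for
#'   the alternating-materials session), values in \[0, 1\]
#' @param decay per-trial exponential decay rate (>= 0)
#' @param floor minimum load the decay approaches
#' @param rest latent load during non-engagement (resting) periods
#' @param overload enable signature reversal above `overload_threshold`
#' @param overload_threshold load above which the theta/alpha modulation
#'   folds back (in (0, 1\])
#' @export
workload_profile <- function(base_load = default_base_load(), decay = 0.05,
                             floor = 0.05, rest = 0.1, overload = FALSE,
                             overload_threshold = 0.85) {
  stopifnot(all(base_load >= 0), all(base_load <= 1), decay >= 0, floor >= 0,
            rest >= 0, overload_threshold > 0, overload_threshold <= 1)
  structure(list(base_load = base_load, decay = decay, floor = floor,
                 rest = rest, overload = overload,
                 overload_threshold = overload_threshold),
            class = "workload_profile")
}

#' @export
print.workload_profile <- function(x, ...) {
  cat("<workload_profile>", length(x$base_load), "task/level entries, decay",
      x$decay, "floor", x$floor, "\n")
  invisible(x)
}

profile_key <- function(task_id, level) {
  ifelse(is.na(level), task_id, paste(task_id, level, sep = "."))
}

#' Per-trial latent workload for a schedule
#'
#' W for trial i (0-based within its task x level) is
#' `floor + (base - floor) * exp(-decay * i)`, clamped to \[0, 1\]. The
#' trajectory is deterministic given the profile.
#'
#' @param schedule a `session_schedule`
#' @param profile a [workload_profile()]
#' @param seed unused placeholder for interface symmetry with the other
#'   simulators (the trajectory is noise-free)
#' @return data frame: task_id, level, trial_index, W
#' @export
simulate_latent_workload <- function(schedule, profile = workload_profile(),
                                     seed = 1) {
  ev <- as.data.frame(schedule)
  tr <- unique(ev[ev$kind == "stimulus" & !is.na(ev$trial_index),
                  c("task_id", "level", "trial_index")])
  tr <- tr[order(tr$task_id, tr$level, tr$trial_index, method = "radix"), ]
  rownames(tr) <- NULL
  key <- profile_key(tr$task_id, tr$level)
  unknown <- setdiff(unique(key), names(profile$base_load))
  if (length(unknown) > 0L)
    stopf("no base load for task/level: %s", paste(unknown, collapse = ", "))
  base <- profile$base_load[key]
  idx0 <- tr$trial_index - 1L
  W <- profile$floor + (base - profile$floor) * exp(-profile$decay * idx0)
  tr$W <- pmin(pmax(as.numeric(W), 0), 1)
  tr
}

#' Subjective rating model
#'
#' Ratings on the 7-point scale are generated as
#' `clip(round(1 + 6 W + eps), 1, 7)` with Gaussian noise eps -- the simplest
#' monotone link from latent load to the scale.
#'
#' @param noise_sd standard deviation of the rating noise
#' @export
rating_model <- function(noise_sd = 0.5) {
  stopifnot(noise_sd >= 0)
  structure(list(noise_sd = noise_sd), class = "rating_model")
}

draw_ratings <- function(W, rmodel) {
  r <- round(1 + 6 * W + stats::rnorm(length(W), 0, rmodel$noise_sd))
  as.integer(pmin(pmax(r, 1), 7))
}
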