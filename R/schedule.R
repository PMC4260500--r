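# Paradigm schedulers: event timelines for the alternating theorem/comic
# learning design and for the four cross-task paradigms (numerical n-back,
# reading span, subtraction problems, fraction problems).
#
# Schedules are data frames of timed events with columns
#   onset_s, duration_s, kind, code, task_id, level, trial_index, value
# kind is one of stimulus, keypress, fixation, rating_prompt, block_start,
# block_end; code refines the stimulus type (digit, sentence, letter, facts,
# problem, options, study_window, question, block_rating, trial_rating).

WM_TASKS <- c("nback", "reading_span")
LEARNING_TASKS <- c("subtraction", "fraction")
STUDY1_TASKS <- c("study1_theorem", "study1_comic")

# letters used in the reading-span task
RSPAN_LETTERS <- c("B", "F", "H", "J", "L", "M", "Q", "R", "X")
# single-digit n-back alphabet; 7 is excluded (only two-syllable digit)
NBACK_DIGITS <- c(0:6, 8, 9)

event_row <- function(onset, duration, kind, code, task_id, level = NA_integer_,
                      trial_index = NA_integer_, value = NA_real_) {
  data.frame(onset_s = onset, duration_s = duration, kind = kind, code = code,
             task_id = task_id, level = as.integer(level),
             trial_index = as.integer(trial_index), value = value,
             stringsAsFactors = FALSE)
}

new_schedule <- function(events, subject_id = "S01", problems = NULL) {
  events <- events[order(events$onset_s, method = "radix"), , drop = FALSE]
  rownames(events) <- NULL
  structure(events,
            subject_id = subject_id,
            problems = problems,
            class = c("session_schedule", "data.frame"))
}

#' @export
print.session_schedule <- function(x, ...) {
  cat("<session_schedule> subject", attr(x, "subject_id") %||% "?",
      "-", nrow(x), "events,",
      sprintf("%.1f s", schedule_duration(x)), "\n")
  tasks <- unique(x$task_id[!is.na(x$task_id)])
  cat("  tasks:", paste(tasks, collapse = ", "), "\n")
  invisible(x)
}

#' Total duration of a schedule in seconds
#' @param schedule a `session_schedule`
#' @export
schedule_duration <- function(schedule) {
  if (nrow(schedule) == 0L) return(0)
  max(schedule$onset_s + ifelse(is.na(schedule$duration_s), 0, schedule$duration_s))
}

#' Word problems attached to a schedule
#'
#' Each generated algebra word problem carries exactly four numerical pieces
#' of information (numbers or fractions, including distractors) and a ground
#' truth answer computed from its difficulty level's formula.
#' @param schedule a `session_schedule`
#' @return data frame with task_id, level, trial_index, the four pieces
#'   (character, fractions as "a/b") and the answer, or NULL
#' @export
schedule_problems <- function(schedule) attr(schedule, "problems")

# positively skewed simulated reaction times (log-normal), clamped
rt_lognormal <- function(n, median_s, sdlog = 0.25, lo = 0.25, hi = Inf) {
  pmin(pmax(stats::rlnorm(n, meanlog = log(median_s), sdlog = sdlog), lo), hi)
}

#' Timing and composition defaults for the alternating-materials learning session
#'
#' Three learning episodes of five theorem and five comic study windows each
#' (45 s per window, alternating materials), every window followed by a 10-s
#' four-option question and a 10-s 7-point load rating.
#'
#' @param n_episodes number of learning episodes
#' @param windows_per_material windows per material per episode
#' @param study_window_s study-window duration in seconds
#' @param question_s question-screen duration
#' @param rating_s rating-screen duration
#' @param first_material material shown first within every episode
#' @param episode_gap_s pause between episodes
#' @export
study1_config <- function(n_episodes = 3, windows_per_material = 5,
                          study_window_s = 45, question_s = 10, rating_s = 10,
                          first_material = "study1_comic", episode_gap_s = 5) {
  stopifnot(n_episodes > 0, windows_per_material > 0, study_window_s > 0,
            question_s > 0, rating_s > 0, episode_gap_s >= 0)
  if (!first_material %in% STUDY1_TASKS)
    stopf("first_material must be one of %s", paste(STUDY1_TASKS, collapse = ", "))
  list(n_episodes = n_episodes, windows_per_material = windows_per_material,
       study_window_s = study_window_s, question_s = question_s,
       rating_s = rating_s, first_material = first_material,
       episode_gap_s = episode_gap_s)
}

#' Build the alternating theorem/comic learning schedule
#'
#' Constructs the within-subject learning design: episodes of alternating
#' 45-s study windows on angle theorems (high load) and comic strips (low
#' load), each followed by a multiple-choice question and a subjective load
#' rating. With defaults this yields 15 theorem and 15 comic study windows.
#'
#' @param subject_id subject identifier
#' @param seed RNG seed (question response times)
#' @param config see [study1_config()]
#' @return a `session_schedule`
#' @export
build_study1_schedule <- function(subject_id = "S01", seed = 1,
                                  config = study1_config()) {
  set.seed(child_seed(seed, 11))
  cfg <- config
  other <- setdiff(STUDY1_TASKS, cfg$first_material)
  t <- 0
  rows <- list()
  counters <- c(study1_theorem = 0L, study1_comic = 0L)
  for (ep in seq_len(cfg$n_episodes)) {
    rows[[length(rows) + 1L]] <- event_row(t, 0, "block_start", "episode", "study1")
    for (w in seq_len(2L * cfg$windows_per_material)) {
      mat <- if (w %% 2L == 1L) cfg$first_material else other
      counters[mat] <- counters[mat] + 1L
      idx <- counters[mat]
      rows[[length(rows) + 1L]] <-
        event_row(t, cfg$study_window_s, "stimulus", "study_window", mat,
                  trial_index = idx)
      t <- t + cfg$study_window_s
      rows[[length(rows) + 1L]] <-
        event_row(t, cfg$question_s, "stimulus", "question", mat, trial_index = idx)
      kp <- t + rt_lognormal(1, median_s = 0.6 * cfg$question_s, sdlog = 0.2,
                             lo = 1, hi = cfg$question_s - 0.25)
      rows[[length(rows) + 1L]] <-
        event_row(kp, 0, "keypress", "choice", mat, trial_index = idx)
      t <- t + cfg$question_s
      rows[[length(rows) + 1L]] <-
        event_row(t, cfg$rating_s, "rating_prompt", "trial_rating", mat,
                  trial_index = idx)
      t <- t + cfg$rating_s
    }
    rows[[length(rows) + 1L]] <- event_row(t, 0, "block_end", "episode", "study1")
    t <- t + cfg$episode_gap_s
  }
  new_schedule(do.call(rbind, rows), subject_id = subject_id)
}

#' Build one n-back block
#'
#' Digits (excluding 7) are presented every 2000 ms for identity matching
#' against the digit n positions back; simulated keypresses fall inside each
#' inter-stimulus interval. The visual event structure is identical across
#' the three load levels.
#'
#' @param level_n n-back level, 1, 2 or 3
#' @param n_trials number of digit presentations (must exceed level_n)
#' @param seed RNG seed
#' @param start_s block onset in seconds
#' @param subject_id subject identifier
#' @param isi_s inter-stimulus interval (2 s)
#' @param stim_s digit display duration
#' @param rt_median_s median simulated reaction time
#' @param target_p probability that a digit repeats the one n back
#' @return a `session_schedule` fragment
#' @export
build_nback_block <- function(level_n, n_trials, seed = 1, start_s = 0,
                              subject_id = "S01", isi_s = 2, stim_s = 0.5,
                              rt_median_s = 1.1, target_p = 0.3) {
  if (!level_n %in% 1:3) stopf("level_n must be 1, 2 or 3 (got %s)", level_n)
  if (n_trials < level_n + 1L)
    stopf("n_trials must be at least level_n + 1 (got %d)", n_trials)
  set.seed(child_seed(seed, 20 + level_n))
  digits <- integer(n_trials)
  for (i in seq_len(n_trials)) {
    if (i > level_n && stats::runif(1) < target_p) {
      digits[i] <- digits[i - level_n]
    } else {
      digits[i] <- sample(NBACK_DIGITS, 1L)
    }
  }
  rt <- rt_lognormal(n_trials, rt_median_s, lo = 0.3, hi = isi_s - 0.3)
  onset <- start_s + (seq_len(n_trials) - 1L) * isi_s
  rows <- list(event_row(start_s, 0, "block_start", "block", "nback", level_n))
  for (i in seq_len(n_trials)) {
    rows[[length(rows) + 1L]] <-
      event_row(onset[i], stim_s, "stimulus", "digit", "nback", level_n, i,
                value = digits[i])
    rows[[length(rows) + 1L]] <-
      event_row(onset[i] + rt[i], 0, "keypress", "response", "nback", level_n, i)
  }
  t_end <- start_s + n_trials * isi_s
  rows[[length(rows) + 1L]] <-
    event_row(t_end, 2, "rating_prompt", "block_rating", "nback", level_n)
  rows[[length(rows) + 1L]] <-
    event_row(t_end + 2, 0, "block_end", "block", "nback", level_n)
  new_schedule(do.call(rbind, rows), subject_id = subject_id)
}

#' Build one reading-span block
#'
#' Each span cycles sentence verification (self-paced, ends with a keypress),
#' a 500-ms fixation cross and a 1000-ms letter to memorise; letters are
#' drawn without replacement from the nine-letter set B F H J L M Q R X
#' within a span.
#'
#' @param span_length letters/sentences per span: 2, 4 or 6
#' @param n_spans number of spans in the block
#' @param seed RNG seed
#' @param start_s block onset
#' @param subject_id subject identifier
#' @param fixation_s fixation-cross duration (0.5 s)
#' @param letter_s letter display duration (1 s)
#' @param sentence_rt_median_s median self-paced sentence verification time
#' @return a `session_schedule` fragment; stimulus `value` indexes
#   the letter set
#' @export
build_readingspan_block <- function(span_length, n_spans, seed = 1, start_s = 0,
                                    subject_id = "S01", fixation_s = 0.5,
                                    letter_s = 1, sentence_rt_median_s = 3) {
  if (!span_length %in% c(2, 4, 6))
    stopf("span_length must be 2, 4 or 6 (got %s)", span_length)
  if (n_spans < 1L) stopf("n_spans must be >= 1")
  level <- match(span_length, c(2, 4, 6))
  set.seed(child_seed(seed, 30 + level))
  t <- start_s
  rows <- list(event_row(t, 0, "block_start", "block", "reading_span", level))
  trial <- 0L
  for (s in seq_len(n_spans)) {
    letters_idx <- sample(seq_along(RSPAN_LETTERS), span_length)
    for (j in seq_len(span_length)) {
      trial <- trial + 1L
      rt <- rt_lognormal(1, sentence_rt_median_s, lo = 1.2, hi = 8)
      rows[[length(rows) + 1L]] <-
        event_row(t, rt, "stimulus", "sentence", "reading_span", level, trial)
      t <- t + rt
      rows[[length(rows) + 1L]] <-
        event_row(t, 0, "keypress", "response", "reading_span", level, trial)
      rows[[length(rows) + 1L]] <-
        event_row(t, fixation_s, "fixation", "fixation", "reading_span", level, trial)
      t <- t + fixation_s
      rows[[length(rows) + 1L]] <-
        event_row(t, letter_s, "stimulus", "letter", "reading_span", level, trial,
                  value = letters_idx[j])
      t <- t + letter_s
    }
  }
  rows[[length(rows) + 1L]] <-
    event_row(t, 2, "rating_prompt", "block_rating", "reading_span", level)
  rows[[length(rows) + 1L]] <-
    event_row(t + 2, 0, "block_end", "block", "reading_span", level)
  new_schedule(do.call(rbind, rows), subject_id = subject_id)
}

#' Ground-truth answer of a generated word problem
#'
#' Subtraction problems: level 1 `x = a`, level 2 `x = a - b`, level 3
#' `x = (a - b) - (c - d)`. Fraction problems: level 1 `x = c*a/b`, level 2
#' `x = c*a/b + d*a/b`, level 3 `x = c*a/b + d*e/f`.
#'
#' @param task_id "subtraction" or "fraction"
#' @param level difficulty level 1-3
#' @param givens named list with the required numbers (a, b, c, d, e, f)
#' @export
wordproblem_answer <- function(task_id, level, givens) {
  if (!task_id %in% LEARNING_TASKS) stopf("unknown word-problem task '%s'", task_id)
  if (!level %in% 1:3) stopf("level must be 1, 2 or 3")
  g <- givens
  if (task_id == "subtraction") {
    switch(level, g$a, g$a - g$b, (g$a - g$b) - (g$c - g$d))
  } else {
    switch(level,
           g$c * g$a / g$b,
           g$c * g$a / g$b + g$d * g$a / g$b,
           g$c * g$a / g$b + g$d * g$e / g$f)
  }
}

# draw the numeric material of one word problem; always exactly four pieces
# of information (numbers or fractions), distractors included at low levels
draw_problem <- function(task_id, level) {
  if (task_id == "subtraction") {
    a <- sample(5:9, 1); b <- sample(1:(a - 1), 1)
    c_ <- sample(5:9, 1); d <- sample(1:(c_ - 1), 1)
    g <- list(a = a, b = b, c = c_, d = d)
    pieces <- as.character(c(a, b, c_, d))
  } else {
    b <- sample(2:4, 1); a <- sample(setdiff(1:9, b), 1)
    f <- sample(2:4, 1); e <- sample(setdiff(1:9, f), 1)
    c_ <- sample(1:9, 1); d <- sample(1:9, 1)
    g <- list(a = a, b = b, c = c_, d = d, e = e, f = f)
    pieces <- switch(level,
                     c(as.character(c_), paste0(a, "/", b), as.character(d),
                       paste0(e, "/", f)),                       # d, e/f distractors
                     c(as.character(c_), paste0(a, "/", b), as.character(d),
                       paste0(e, "/", f)),                       # e/f distractor
                     c(as.character(c_), paste0(a, "/", b), as.character(d),
                       paste0(e, "/", f)))
  }
  list(givens = g, pieces = pieces, answer = wordproblem_answer(task_id, level, g))
}

#' Build one algebra word-problem block
#'
#' Every problem presents a self-paced fact page, a self-paced problem
#' statement, a four-option multiple-choice screen (each phase ended by a
#' keypress), a 500-ms fixation and a trial-level load rating. All problems
#' carry exactly four numerical pieces of information regardless of level,
#' and no feedback is ever given.
#'
#' @param task_id "subtraction" or "fraction"
#' @param level difficulty level 1-3
#' @param n_problems problems in the block
#' @param seed RNG seed
#' @param start_s block onset
#' @param subject_id subject identifier
#' @param facts_rt_median_s,problem_rt_median_s,choice_rt_median_s median
#'   self-paced phase durations
#' @param fixation_s fixation duration
#' @param rating_s rating-screen duration
#' @return a `session_schedule` fragment; problem material is available via
#'   [schedule_problems()]
#' @export
build_wordproblem_block <- function(task_id, level, n_problems, seed = 1,
                                    start_s = 0, subject_id = "S01",
                                    facts_rt_median_s = 4,
                                    problem_rt_median_s = 6,
                                    choice_rt_median_s = 3,
                                    fixation_s = 0.5, rating_s = 2) {
  if (!task_id %in% LEARNING_TASKS) stopf("unknown word-problem task '%s'", task_id)
  if (!level %in% 1:3) stopf("level must be 1, 2 or 3 (got %s)", level)
  if (n_problems < 1L) stopf("n_problems must be >= 1")
  set.seed(child_seed(seed, 40 + level + 3 * (task_id == "fraction")))
  t <- start_s
  rows <- list(event_row(t, 0, "block_start", "block", task_id, level))
  probs <- vector("list", n_problems)
  for (i in seq_len(n_problems)) {
    pr <- draw_problem(task_id, level)
    probs[[i]] <- data.frame(task_id = task_id, level = level, trial_index = i,
                             piece1 = pr$pieces[1], piece2 = pr$pieces[2],
                             piece3 = pr$pieces[3], piece4 = pr$pieces[4],
                             answer = pr$answer, stringsAsFactors = FALSE)
    rt_f <- rt_lognormal(1, facts_rt_median_s, lo = 1.5, hi = 12)
    rows[[length(rows) + 1L]] <-
      event_row(t, rt_f, "stimulus", "facts", task_id, level, i)
    t <- t + rt_f
    rows[[length(rows) + 1L]] <-
      event_row(t, 0, "keypress", "response", task_id, level, i)
    rt_p <- rt_lognormal(1, problem_rt_median_s, lo = 2, hi = 18)
    rows[[length(rows) + 1L]] <-
      event_row(t, rt_p, "stimulus", "problem", task_id, level, i,
                value = pr$answer)
    t <- t + rt_p
    rows[[length(rows) + 1L]] <-
      event_row(t, 0, "keypress", "response", task_id, level, i)
    rt_c <- rt_lognormal(1, choice_rt_median_s, lo = 1, hi = 8)
    rows[[length(rows) + 1L]] <-
      event_row(t, rt_c, "stimulus", "options", task_id, level, i)
    t <- t + rt_c
    rows[[length(rows) + 1L]] <-
      event_row(t, 0, "keypress", "choice", task_id, level, i)
    rows[[length(rows) + 1L]] <-
      event_row(t, fixation_s, "fixation", "fixation", task_id, level, i)
    t <- t + fixation_s
    rows[[length(rows) + 1L]] <-
      event_row(t, rating_s, "rating_prompt", "trial_rating", task_id, level, i)
    t <- t + rating_s
  }
  rows[[length(rows) + 1L]] <- event_row(t, 0, "block_end", "block", task_id, level)
  new_schedule(do.call(rbind, rows), subject_id = subject_id,
               problems = do.call(rbind, probs))
}

#' Composition defaults for a cross-task session
#'
#' The session presents the two working-memory training tasks and then the
#' two learning tasks; within each task the three difficulty levels run in a
#' fixed simple-to-complex order (no randomised level order: realistic
#' learning material cannot be reordered arbitrarily).
#'
#' @param n_nback_trials digit presentations per n-back block
#' @param spans reading-span lengths, one block per span
#' @param n_spans spans per reading-span block (one entry per span length;
#'   defaults keep the trial count per block equal at 12)
#' @param n_problems word problems per difficulty level
#' @param gap_s pause between blocks
#' @export
study2_config <- function(n_nback_trials = 48, spans = c(2, 4, 6),
                          n_spans = c(6, 3, 2), n_problems = 10, gap_s = 2) {
  stopifnot(length(spans) == length(n_spans), all(spans %in% c(2, 4, 6)),
            n_nback_trials >= 4, all(n_spans >= 1), n_problems >= 1, gap_s >= 0)
  list(n_nback_trials = n_nback_trials, spans = spans, n_spans = n_spans,
       n_problems = n_problems, gap_s = gap_s)
}

#' Build a full cross-task session schedule
#'
#' n-back blocks (levels 1-3), reading-span blocks (spans 2, 4, 6), then
#' subtraction and fraction word-problem blocks (levels 1-3), all in
#' simple-to-complex order within task.
#'
#' @param subject_id subject identifier
#' @param seed RNG seed
#' @param config see [study2_config()]
#' @return a `session_schedule`
#' @export
build_study2_schedule <- function(subject_id = "S01", seed = 1,
                                  config = study2_config()) {
  cfg <- config
  frags <- list()
  t <- 0
  add <- function(frag) {
    frags[[length(frags) + 1L]] <<- frag
    t <<- schedule_duration(frag) + cfg$gap_s
  }
  for (lev in 1:3) {
    add(build_nback_block(lev, cfg$n_nback_trials, seed = child_seed(seed, lev),
                          start_s = t, subject_id = subject_id))
  }
  for (i in seq_along(cfg$spans)) {
    add(build_readingspan_block(cfg$spans[i], cfg$n_spans[i],
                                seed = child_seed(seed, 3 + i), start_s = t,
                                subject_id = subject_id))
  }
  for (task in LEARNING_TASKS) {
    for (lev in 1:3) {
      add(build_wordproblem_block(task, lev, cfg$n_problems,
                                  seed = child_seed(seed, 10 * match(task, LEARNING_TASKS) + lev),
                                  start_s = t, subject_id = subject_id))
    }
  }
  events <- do.call(rbind, lapply(frags, function(f) {
    class(f) <- "data.frame"
    attr(f, "problems") <- NULL
    f
  }))
  problems <- do.call(rbind, lapply(frags, schedule_problems))
  new_schedule(events, subject_id = subject_id, problems = problems)
}

#' Write / read a schedule's event stream as tab-separated text
#'
#' The TSV (columns onset_s, duration_s, kind, code, task_id, level,
#' trial_index, value) plus a small JSON header is the on-disk container the
#' simulator and preprocessing consume.
#'
#' @param schedule a `session_schedule`
#' @param path TSV file path
#' @export
write_events_tsv <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  header <- list(subject_id = attr(schedule, "subject_id"),
                 total_duration_s = schedule_duration(schedule),
                 n_events = nrow(schedule))
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  hdr_path <- paste0(path, ".json")
  sid <- if (file.exists(hdr_path)) jsonlite::read_json(hdr_path)$subject_id else "S01"
  new_schedule(ev, subject_id = sid)
}
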