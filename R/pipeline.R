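# End-to-end drivers. run_study1(): within-task decoding of alternating
# learning materials (alpha power, stratified 10-fold CV). run_study2():
# cross-task decoding — train on n-back + reading span, test per-trial on
# the two algebra word-problem tasks, with rating-based labels, 2-of-3
# difficulty-level calibration, train-statistics z-scoring and permutation
# significance.

# per-row rating lookup: trial-level ratings where present, block-level
# (working-memory tasks) otherwise
lookup_ratings <- function(info, ratings) {
  r <- rep(NA_real_, nrow(info))
  rt <- ratings[!is.na(ratings$trial_index), ]
  if (nrow(rt)) {
    r <- rt$rating[match(paste(info$task_id, info$level, info$trial_index),
                         paste(rt$task_id, rt$level, rt$trial_index))]
  }
  rb <- ratings[is.na(ratings$trial_index), ]
  miss <- is.na(r)
  if (nrow(rb) && any(miss)) {
    r[miss] <- rb$rating[match(paste(info$task_id[miss], info$level[miss]),
                               paste(rb$task_id, rb$level))]
  }
  if (anyNA(r)) stopf("missing rating for some trials")
  r
}

#' Run the within-task decoding study on one simulated subject
#'
#' Simulates the alternating theorem/comic learning session, regresses out
#' eye activity, segments artifact-free 45-s study windows into 15-s
#' epochs, computes alpha band-power features and reports stratified
#' 10-fold cross-validated accuracy for theorem vs comic epochs.
#'
#' @param subject_id subject identifier
#' @param seed integer seed
#' @param config see [study1_config()]
#' @param model a [forward_model()]
#' @param profile a [workload_profile()]
#' @param rmodel a [rating_model()]
#' @param electrodes feature electrodes
#' @param folds CV folds
#' @return object of class `wml_study1`: `accuracy`, `cv`, `n_epochs`,
#'   `features`
#' @export
run_study1 <- function(subject_id = "S01", seed = 1, config = study1_config(),
                       model = forward_model(), profile = workload_profile(),
                       rmodel = rating_model(),
                       electrodes = c("F3", "Fz", "F4", "P3", "Pz", "P4"),
                       folds = 10) {
  schedule <- build_study1_schedule(subject_id, seed = seed, config = config)
  sess <- simulate_session(schedule, model, profile, rmodel,
                           seed = child_seed(seed, 701))
  rec <- regress_out_eog(sess$recording)
  epochs <- segment_study_windows(rec, config$study_window_s,
                                  epoch_len_s = 15)
  feats <- study1_features(rec, epochs, electrodes = electrodes)
  cv <- crossval_10fold(feats, seed = child_seed(seed, 702), folds = folds)
  structure(list(subject_id = subject_id, accuracy = cv$accuracy, cv = cv,
                 n_epochs = table(feats$labels), features = feats,
                 ratings = sess$ratings),
            class = "wml_study1")
}

#' @export
print.wml_study1 <- function(x, ...) {
  cat(sprintf("<wml_study1> subject %s: CV accuracy %.1f%% (%s epochs)\n",
              x$subject_id, 100 * x$accuracy,
              paste(names(x$n_epochs), x$n_epochs, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Run the cross-task decoding study on one simulated subject
#'
#' Simulates the full cross-task session, regresses out eye activity,
#' selects two of three difficulty levels per task from the subjective
#' ratings, derives the personal rating cutoff from the retained
#' working-memory blocks, extracts keypress-safe interval pairs, builds
#' %ERD/ERS features, and evaluates an SVM-RBF trained on the pooled
#' working-memory trials on every learning-task trial.
#'
#' @param subject_id subject identifier
#' @param seed integer seed
#' @param config see [study2_config()]
#' @param model a [forward_model()]
#' @param profile a [workload_profile()]
#' @param rmodel a [rating_model()]
#' @param balance_min minimum minority-class fraction per task
#' @param B permutation draws
#' @return object of class `wml_study2`: `results` (per-task accuracy and
#'   permutation p), `selection`, `cutoff`, `eval`
#' @export
run_study2 <- function(subject_id = "S01", seed = 1, config = study2_config(),
                       model = forward_model(), profile = workload_profile(),
                       rmodel = rating_model(), balance_min = 0.4, B = 1000) {
  schedule <- build_study2_schedule(subject_id, seed = seed, config = config)
  sess <- simulate_session(schedule, model, profile, rmodel,
                           seed = child_seed(seed, 801))
  rec <- regress_out_eog(sess$recording)

  records <- sess$ratings[, c("task_id", "level", "trial_index", "rating")]
  sel <- select_difficulty_levels(records, balance_min = balance_min)
  keep_key <- paste(sel$keep$task_id, sel$keep$level)

  feats <- list()
  for (task in c(WM_TASKS, LEARNING_TASKS)) {
    pairs <- extract_interval_pairs(rec, task)
    pairs <- pairs[paste(pairs$task_id, pairs$level) %in% keep_key, , drop = FALSE]
    if (nrow(pairs) == 0L) stopf("no retained trials for task '%s'", task)
    f <- crosstask_features(rec, pairs)
    f$labels <- assign_classes(lookup_ratings(f$info, sess$ratings), sel$cutoff)
    feats[[task]] <- f
  }

  train <- list(x = rbind(feats$nback$x, feats$reading_span$x),
                y = factor(c(as.character(feats$nback$labels),
                             as.character(feats$reading_span$labels)),
                           levels = c("low", "high")))
  ev <- cross_task_evaluate(train,
                            tests = list(subtraction = feats$subtraction,
                                         fraction = feats$fraction),
                            seed = child_seed(seed, 802), B = B)
  structure(list(subject_id = subject_id, results = ev$results, eval = ev,
                 selection = sel, cutoff = sel$cutoff, features = feats,
                 ratings = sess$ratings),
            class = "wml_study2")
}

#' @export
print.wml_study2 <- function(x, ...) {
  cat("<wml_study2> subject", x$subject_id, "| cutoff",
      round(x$cutoff, 2), "\n")
  df <- x$results
  df$accuracy <- sprintf("%.1f%%", 100 * df$accuracy)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Cross-task decoding over a simulated cohort
#'
#' Runs [run_study2()] for `n_subjects` independently seeded subjects and
#' summarises per-(subject, task) accuracies and permutation significance.
#'
#' Subjects whose ratings admit no balanced 2-of-3 level selection are
#' dropped from the cohort with a message (mirroring subject exclusion in
#' real cohorts); their count is attached to the report as
#' `attr(, "n_failed")`.
#'
#' @param n_subjects cohort size
#' @param seed integer seed
#' @param ... passed to [run_study2()]
#' @return a `wml_report`
#' @export
study2_cohort <- function(n_subjects = 16, seed = 1, ...) {
  rows <- list()
  n_failed <- 0L
  for (i in seq_len(n_subjects)) {
    res <- tryCatch(run_study2(subject_id = sprintf("S%02d", i),
                               seed = child_seed(seed, 900 + i), ...),
                    error = function(e) {
                      message("subject ", i, " excluded: ", conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    df <- res$results
    df$subject <- res$subject_id
    rows[[length(rows) + 1L]] <- df[, c("subject", "task", "n_test",
                                        "accuracy", "p_value")]
  }
  if (length(rows) == 0L) stopf("every subject failed calibration")
  rep <- report(do.call(rbind, rows))
  attr(rep, "n_failed") <- n_failed
  rep
}

#' Mean cross-task accuracy as a function of signature strength
#'
#' Sweeps the workload signature strength s: the alpha attenuation is set to
#' s and the theta gain is scaled proportionally from the model defaults.
#' Accuracy is averaged over `n_subjects` per strength.
#'
#' @param strengths numeric vector of signature strengths (alpha-depth
#'   values)
#' @param n_subjects subjects per strength
#' @param seed integer seed
#' @param model base [forward_model()] supplying all other parameters
#' @param B permutation draws per subject (accuracy only needs few)
#' @param ... passed to [run_study2()]
#' @return data frame: strength, mean_accuracy
#' @export
signature_sweep <- function(strengths = c(0, 0.2, 0.4, 0.6), n_subjects = 8,
                            seed = 1, model = forward_model(), B = 19, ...) {
  ratio <- model$theta$gain / max(model$alpha$depth, 1e-9)
  out <- data.frame(strength = strengths, mean_accuracy = NA_real_)
  for (i in seq_along(strengths)) {
    s <- strengths[i]
    m <- model
    m$alpha$depth <- s
    m$theta$gain <- ratio * s
    accs <- c()
    for (j in seq_len(n_subjects)) {
      res <- tryCatch(run_study2(subject_id = sprintf("S%02d", j),
                                 seed = child_seed(seed, 950 + 37 * i + j),
                                 model = m, B = B, ...),
                      error = function(e) NULL)
      if (!is.null(res)) accs <- c(accs, mean(res$results$accuracy))
    }
    out$mean_accuracy[i] <- mean(accs)
  }
  out
}
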