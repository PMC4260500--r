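# Labeling and calibration. Classes are defined from subjective load
# ratings, not objective difficulty: the experienced load of a fixed
# difficulty drops as expertise builds, so the subject's mean working-memory
# task rating serves as a personal cutoff. Difficulty levels are pruned
# 2-of-3 per task so all tasks cover a comparable load range, and features
# are z-scored with training-set statistics only.

#' Personal class cutoff from working-memory task ratings
#'
#' Arithmetic mean of all n-back and reading-span ratings of one subject;
#' the same cutoff is applied unchanged to the learning tasks.
#'
#' @param ratings numeric vector of 7-point ratings
#' @export
personal_cutoff <- function(ratings) {
  ratings <- ratings[!is.na(ratings)]
  if (length(ratings) == 0L) stopf("no ratings supplied")
  mean(ratings)
}

#' Assign low/high load classes by a rating cutoff
#'
#' Ratings above the cutoff are "high", below are "low"; ties go to the
#' configured side (default high — conservative toward detecting overload).
#' The rule is applied identically to working-memory and learning tasks.
#'
#' @param ratings numeric vector of trial ratings
#' @param cutoff personal cutoff ([personal_cutoff()])
#' @param tie class assigned at `rating == cutoff`
#' @return factor with levels low, high
#' @export
assign_classes <- function(ratings, cutoff, tie = c("high", "low")) {
  tie <- match.arg(tie)
  if (!is.finite(cutoff)) stopf("cutoff must be finite")
  cls <- ifelse(ratings > cutoff, "high",
                ifelse(ratings < cutoff, "low", tie))
  cls <- factor(cls, levels = c("low", "high"))
  if (any(table(cls) == 0L))
    stopf("class assignment is degenerate (one class empty); re-select difficulty levels")
  cls
}

#' Select two of three difficulty levels per task
#'
#' Drops, per task, the level whose mean rating deviates most from the
#' cross-task grand mean rating (mean over all task x level means), so the
#' retained levels of every task span a comparable load range. A candidate
#' selection must leave both rating classes represented with a minority
#' fraction of at least `balance_min` in every task (labels from the
#' retained working-memory ratings' cutoff); if the greedy choice violates
#' this, alternative drop combinations are tried in decreasing order of
#' summed dropped deviation. Deterministic; ties drop the lower level.
#'
#' @param records data frame with columns task_id, level, rating (one row
#'   per rating record: block ratings for WM tasks, trial ratings for
#'   learning tasks)
#' @param balance_min minimum minority-class fraction per task
#' @param wm_tasks tasks whose ratings define the personal cutoff
#' @param tie tie rule passed to [assign_classes()]
#' @param grand_mean externally supplied cross-task grand mean rating
#'   (default: mean of all task x level mean ratings)
#' @return object of class `wml_selection`: list with `keep` (data frame
#'   task_id, level), `dropped`, `cutoff`, `grand_mean`, `level_means`
#' @export
select_difficulty_levels <- function(records, balance_min = 0.4,
                                     wm_tasks = WM_TASKS, tie = "high",
                                     grand_mean = NULL) {
  stopifnot(all(c("task_id", "level", "rating") %in% names(records)))
  lm <- stats::aggregate(rating ~ task_id + level, data = records, FUN = mean)
  tasks <- unique(records$task_id)
  for (tk in tasks) {
    if (nrow(lm[lm$task_id == tk, ]) != 3L)
      stopf("task '%s' does not have ratings for exactly 3 levels", tk)
  }
  grand <- grand_mean %||% mean(lm$rating)
  lm$deviation <- abs(lm$rating - grand)

  # candidate = one dropped level per task; order by total dropped deviation
  # (descending), tie-broken toward dropping lower levels
  per_task <- split(lm, lm$task_id)
  per_task <- per_task[tasks]
  lev_sorted <- lapply(per_task, function(d) sort(d$level))
  dev_sorted <- lapply(per_task, function(d) d$deviation[order(d$level)])
  combos <- as.matrix(expand.grid(rep(list(1:3), length(tasks))))
  devs <- rowSums(vapply(seq_along(tasks),
                         function(i) dev_sorted[[i]][combos[, i]],
                         numeric(nrow(combos))))
  lowsum <- rowSums(vapply(seq_along(tasks),
                           function(i) lev_sorted[[i]][combos[, i]],
                           numeric(nrow(combos))))
  ord <- order(-devs, lowsum)

  for (ci in ord) {
    drop_lev <- vapply(seq_along(tasks),
                       function(i) lev_sorted[[i]][combos[ci, i]], numeric(1))
    names(drop_lev) <- tasks
    keep <- lm[mapply(function(tk, lv) drop_lev[[tk]] != lv, lm$task_id, lm$level),
               c("task_id", "level")]
    sel_rec <- records[mapply(function(tk, lv) drop_lev[[tk]] != lv,
                              records$task_id, records$level), ]
    wm_ratings <- sel_rec$rating[sel_rec$task_id %in% wm_tasks]
    if (length(wm_ratings) == 0L) next
    cutoff <- personal_cutoff(wm_ratings)
    ok <- TRUE
    for (tk in tasks) {
      r <- sel_rec$rating[sel_rec$task_id == tk]
      cls <- tryCatch(assign_classes(r, cutoff, tie), error = function(e) NULL)
      if (is.null(cls) || min(table(cls)) / length(cls) < balance_min) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      dropped <- lm[mapply(function(tk, lv) drop_lev[[tk]] == lv,
                           lm$task_id, lm$level), c("task_id", "level", "rating",
                                                    "deviation")]
      keep <- keep[order(keep$task_id, keep$level), ]
      rownames(keep) <- rownames(dropped) <- NULL
      return(structure(list(keep = keep, dropped = dropped, cutoff = cutoff,
                            grand_mean = grand, level_means = lm,
                            greedy = ci == ord[1]),
                       class = "wml_selection"))
    }
  }
  stopf(paste0("no 2-of-3 level selection yields class balance >= %.0f%%; ",
               "level mean ratings: %s"), 100 * balance_min,
        paste(sprintf("%s L%d=%.2f", lm$task_id, lm$level, lm$rating),
              collapse = ", "))
}

#' @export
print.wml_selection <- function(x, ...) {
  cat("<wml_selection> cutoff", round(x$cutoff, 3), "| kept levels:\n")
  for (tk in unique(x$keep$task_id)) {
    cat(sprintf("  %-13s %s\n", tk,
                paste(x$keep$level[x$keep$task_id == tk], collapse = ", ")))
  }
  invisible(x)
}

#' Fit / apply train-statistics z-scoring
#'
#' `zscore_fit()` computes per-column mean and population standard deviation
#' on the training rows only; `zscore_apply()` standardises any matrix with
#' those statistics (test data is never allowed to influence them). A
#' zero-variance column gets unit scale with a warning.
#'
#' @param x numeric matrix (trials x features) or `wml_features`
#' @return `zscore_fit`: object of class `zscore_stats` (fields `mean`,
#'   `sd`); `zscore_apply`: matrix of the same shape as `x`
#' @export
zscore_fit <- function(x) {
  x <- if (inherits(x, "wml_features")) x$x else as.matrix(x)
  if (nrow(x) == 0L) stopf("empty training matrix")
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))  # population sd
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " zero-variance feature column(s); scale set to 1")
    sdv[sdv == 0] <- 1
  }
  structure(list(mean = mu, sd = sdv), class = "zscore_stats")
}

#' @rdname zscore_fit
#' @param stats a `zscore_stats` object
#' @export
zscore_apply <- function(x, stats) {
  x <- if (inherits(x, "wml_features")) x$x else as.matrix(x)
  sweep(sweep(x, 2, stats$mean), 2, stats$sd, `/`)
}

#' Serialize calibration objects to JSON
#'
#' Works for `zscore_stats` (per-feature training means and standard
#' deviations) and `wml_selection` (retained levels, cutoff, diagnostics).
#'
#' @param x a `zscore_stats` or `wml_selection` object
#' @param path output path
#' @export
write_calibration_json <- function(x, path) {
  payload <- if (inherits(x, "zscore_stats")) {
    list(type = "zscore_stats", feature = names(x$mean),
         mean = unname(x$mean), sd = unname(x$sd))
  } else if (inherits(x, "wml_selection")) {
    list(type = "level_selection", keep = x$keep, dropped = x$dropped,
         cutoff = x$cutoff, grand_mean = x$grand_mean)
  } else {
    stopf("cannot serialize object of class '%s'", class(x)[1])
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
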