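# SVM-RBF classification. Within-task mode: stratified 10-fold
# cross-validation with z-scoring and hyperparameter search refit inside
# every training fold (no leakage). Cross-task mode: one model per subject
# trained on the pooled working-memory tasks, applied trial-by-trial to each
# learning task, with permutation significance.

# stratified fold assignment, deterministic given seed
make_folds <- function(y, k, seed) {
  set.seed(child_seed(seed, 301))
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

default_C_grid <- function() 2^seq(-5, 15, by = 5)
default_gamma_grid <- function() 2^seq(-15, 1, by = 4)

#' Train an SVM with RBF kernel, hyperparameters by inner grid search
#'
#' (C, gamma) are chosen on log-2 grids by stratified inner cross-validation
#' on the training data only, then the model is refit on all training rows.
#' Features are expected to be z-scored already ([zscore_fit()]); no scaling
#' happens here. Deterministic given `seed`.
#'
#' @param x numeric matrix, trials x features (z-scored)
#' @param y factor with two levels
#' @param seed integer seed (inner fold assignment)
#' @param C_grid,gamma_grid hyperparameter grids
#' @param inner_folds folds of the inner search
#' @return object of class `wml_svm`
#' @export
train_svm_rbf <- function(x, y, seed = 1, C_grid = default_C_grid(),
                          gamma_grid = default_gamma_grid(), inner_folds = 3) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stopf("training data contains a single class")
  if (min(table(y)) < 2L) stopf("need at least 2 trials per class")
  k <- min(inner_folds, min(table(y)))
  fold <- make_folds(y, k, seed)
  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "C-classification",
                      kernel = "radial", cost = grid$C[g], gamma = grid$gamma[g],
                      scale = FALSE)
      p <- predict(m, x[!tr, , drop = FALSE])
      correct <- correct + sum(p == y[!tr])
    }
    acc[g] <- correct / length(y)
  }
  # tie-break among equally good grid cells toward moderate regularization
  # (C = 1, gamma = 1/p): extreme corners behave degenerately downstream
  best_set <- which(acc == max(acc))
  if (length(best_set) > 1L) {
    d2 <- log2(grid$C[best_set])^2 +
      (log2(grid$gamma[best_set]) - log2(1 / ncol(x)))^2
    best <- best_set[which.min(d2)]
  } else {
    best <- best_set
  }
  model <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                      cost = grid$C[best], gamma = grid$gamma[best],
                      scale = FALSE)
  structure(list(model = model, C = grid$C[best], gamma = grid$gamma[best],
                 inner_accuracy = acc[best], grid_accuracy = acc, grid = grid,
                 levels = levels(y), n_train = length(y)),
            class = "wml_svm")
}

#' @export
print.wml_svm <- function(x, ...) {
  cat("<wml_svm> RBF kernel, C =", x$C, ", gamma =", signif(x$gamma, 3),
      sprintf("| inner CV accuracy %.1f%% on %d trials\n",
              100 * x$inner_accuracy, x$n_train))
  invisible(x)
}

#' @export
predict.wml_svm <- function(object, newdata, ...) {
  predict(object$model, as.matrix(newdata))
}

#' Stratified k-fold cross-validated accuracy
#'
#' Within each fold, z-scoring statistics and SVM hyperparameters are refit
#' on the training portion only. When a class has fewer trials than `folds`
#' the fold count is reduced with a warning.
#'
#' @param x feature matrix or `wml_features` (raw, not yet z-scored)
#' @param y factor labels (taken from `x$labels` when omitted)
#' @param seed integer seed
#' @param folds number of folds
#' @return object of class `wml_cv` (fields `accuracy`, `fold_accuracy`,
#'   `folds`)
#' @export
crossval_10fold <- function(x, y = NULL, seed = 1, folds = 10) {
  if (inherits(x, "wml_features")) {
    y <- y %||% x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L || min(table(y)) < 2L)
    stopf("need at least 2 trials in each of 2 classes")
  k <- folds
  if (min(table(y)) < k) {
    k <- min(table(y))
    warning(sprintf("reducing folds from %d to %d (smallest class size)",
                    folds, k))
  }
  fold <- make_folds(y, k, seed)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    zs <- zscore_fit(x[tr, , drop = FALSE])
    fit <- train_svm_rbf(zscore_apply(x[tr, , drop = FALSE], zs), y[tr],
                         seed = child_seed(seed, 400 + f))
    p <- predict(fit, zscore_apply(x[!tr, , drop = FALSE], zs))
    fold_acc[f] <- mean(p == y[!tr])
  }
  structure(list(accuracy = mean(fold_acc), fold_accuracy = fold_acc,
                 folds = k), class = "wml_cv")
}

#' @export
print.wml_cv <- function(x, ...) {
  cat(sprintf("<wml_cv> %d-fold accuracy %.1f%%\n", x$folds, 100 * x$accuracy))
  invisible(x)
}

# permutation accuracies: training labels uniformly shuffled, model refit at
# fixed (C, gamma), evaluated on each test set; one shuffle serves all tasks
perm_accuracies <- function(train_x, train_y, tests, C, gamma, B, seed) {
  set.seed(child_seed(seed, 500))
  out <- matrix(NA_real_, B, length(tests))
  for (b in seq_len(B)) {
    yp <- sample(train_y)
    m <- e1071::svm(train_x, yp, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
    for (j in seq_along(tests)) {
      out[b, j] <- mean(predict(m, tests[[j]]$x) == tests[[j]]$y)
    }
  }
  out
}

#' Permutation test of classifier accuracy
#'
#' Refits the classifier `B` times with uniformly shuffled training labels
#' at the fixed hyperparameters and recomputes test accuracy;
#' `p = (1 + #\{permuted >= observed\}) / (B + 1)`. With
#' `exhaustive = TRUE`, all distinct label arrangements are enumerated
#' instead and `p` is the exact proportion of arrangements (the observed one
#' included) reaching the observed accuracy.
#'
#' @param train_x,train_y training features (z-scored) and labels
#' @param test_x,test_y test features (z-scored with training stats) and
#'   labels
#' @param C,gamma fixed SVM hyperparameters
#' @param B number of permutation draws (>= 1)
#' @param seed integer seed
#' @param exhaustive enumerate all distinct label arrangements (small n)
#' @return list: `p`, `observed`, `permuted` (accuracies), `B`
#' @export
permutation_test <- function(train_x, train_y, test_x, test_y, C = 1,
                             gamma = NULL, B = 1000, seed = 1,
                             exhaustive = FALSE) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  train_y <- droplevels(as.factor(train_y))
  gamma <- gamma %||% (1 / ncol(train_x))
  obs_model <- e1071::svm(train_x, train_y, type = "C-classification",
                          kernel = "radial", cost = C, gamma = gamma,
                          scale = FALSE)
  observed <- mean(predict(obs_model, test_x) == test_y)
  if (exhaustive) {
    lv <- levels(train_y)
    n <- length(train_y)
    n1 <- sum(train_y == lv[1])
    pos <- utils::combn(n, n1)
    acc <- numeric(ncol(pos))
    for (i in seq_len(ncol(pos))) {
      yp <- factor(rep(lv[2], n), levels = lv)
      yp[pos[, i]] <- lv[1]
      m <- e1071::svm(train_x, yp, type = "C-classification", kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE)
      acc[i] <- mean(predict(m, test_x) == test_y)
    }
    p <- mean(acc >= observed - 1e-12)
    return(list(p = p, observed = observed, permuted = acc, B = ncol(pos)))
  }
  if (B < 1) stopf("B must be >= 1")
  perm <- perm_accuracies(train_x, train_y, list(list(x = test_x, y = test_y)),
                          C, gamma, B, seed)[, 1]
  p <- (1 + sum(perm >= observed - 1e-12)) / (B + 1)
  list(p = p, observed = observed, permuted = perm, B = B)
}

#' Cross-task evaluation: train on working-memory tasks, test on learning tasks
#'
#' Z-scoring statistics and hyperparameters are fit on the pooled training
#' trials only; the model then classifies every trial of each held-out
#' learning task, and a permutation test (shared shuffles across tasks)
#' yields a per-task p-value.
#'
#' @param train a `wml_features` with labels, or list(x, y)
#' @param tests named list of test sets (each a `wml_features` with labels
#'   or list(x, y)); feature names must match the training set
#' @param seed integer seed
#' @param B permutation draws
#' @return object of class `wml_eval`: data frame `results` (task, n_test,
#'   accuracy, p_value) plus the fitted model and calibration stats
#' @export
cross_task_evaluate <- function(train, tests, seed = 1, B = 1000) {
  as_xy <- function(s) {
    if (inherits(s, "wml_features")) list(x = s$x, y = s$labels) else s
  }
  tr <- as_xy(train)
  if (is.null(tr$y)) stopf("training set has no labels")
  tests <- lapply(tests, as_xy)
  for (s in tests) {
    if (!identical(colnames(tr$x), colnames(s$x)))
      stopf("feature names differ between training and test sets")
  }
  zs <- zscore_fit(tr$x)
  xtr <- zscore_apply(tr$x, zs)
  fit <- train_svm_rbf(xtr, tr$y, seed = child_seed(seed, 600))
  tests_z <- lapply(tests, function(s) list(x = zscore_apply(s$x, zs), y = s$y))
  observed <- vapply(tests_z, function(s) {
    mean(predict(fit, s$x) == s$y)
  }, numeric(1))
  perm <- perm_accuracies(xtr, droplevels(as.factor(tr$y)), tests_z,
                          fit$C, fit$gamma, B, seed)
  pvals <- vapply(seq_along(tests_z), function(j) {
    (1 + sum(perm[, j] >= observed[j] - 1e-12)) / (B + 1)
  }, numeric(1))
  results <- data.frame(task = names(tests) %||% seq_along(tests),
                        n_test = vapply(tests_z, function(s) length(s$y), 1L),
                        accuracy = unname(observed), p_value = pvals,
                        stringsAsFactors = FALSE)
  structure(list(results = results, model = fit, zscore = zs, B = B),
            class = "wml_eval")
}

#' @export
print.wml_eval <- function(x, ...) {
  cat("<wml_eval> trained on", x$model$n_train, "trials;",
      "per-trial test decisions:\n")
  df <- x$results
  df$accuracy <- sprintf("%.1f%%", 100 * df$accuracy)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Cohort summary of cross-task classification results
#'
#' @param results data frame with columns subject, task, n_test, accuracy,
#'   p_value (e.g. rbind of per-subject `wml_eval$results`)
#' @param alpha significance level for the permutation tests
#' @return object of class `wml_report`: the per-cell table plus mean
#'   accuracy and the significant/total count
#' @export
report <- function(results, alpha = 0.05) {
  if (is.null(results) || nrow(results) == 0L) stopf("no results to report")
  stopifnot(all(c("subject", "task", "accuracy", "p_value") %in% names(results)))
  structure(list(table = results,
                 mean_accuracy = mean(results$accuracy),
                 n_significant = sum(results$p_value < alpha),
                 n_total = nrow(results),
                 alpha = alpha),
            class = "wml_report")
}

#' @export
print.wml_report <- function(x, ...) {
  cat(sprintf("<wml_report> %d classifications, mean accuracy %.1f%%, %d/%d significant (p < %g)\n",
              x$n_total, 100 * x$mean_accuracy, x$n_significant, x$n_total,
              x$alpha))
  df <- x$table
  df$accuracy <- sprintf("%.1f%%", 100 * df$accuracy)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize a cohort report to JSON
#' @param x a `wml_report`
#' @param path output path
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(list(table = x$table, mean_accuracy = x$mean_accuracy,
                            n_significant = x$n_significant,
                            n_total = x$n_total, alpha = x$alpha),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
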