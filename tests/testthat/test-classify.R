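make_clouds <- function(n_per = 20, d = 4, p = 5, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per * p), n_per, p),
             matrix(stats::rnorm(n_per * p, mean = d), n_per, p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = factor(rep(c("low", "high"), each = n_per),
                         levels = c("low", "high")))
}

test_that("well-separated clouds are fit perfectly and deterministically", {
  cl <- make_clouds()
  fit <- train_svm_rbf(cl$x, cl$y, seed = 1)
  expect_equal(mean(predict(fit, cl$x) == cl$y), 1)
  fit2 <- train_svm_rbf(cl$x, cl$y, seed = 1)
  expect_identical(c(fit$C, fit$gamma), c(fit2$C, fit2$gamma))
  expect_error(train_svm_rbf(cl$x, factor(rep("low", 40))), "single class")
})

test_that("permuted labels give chance-level inner-CV accuracy", {
  cl <- make_clouds(n_per = 20, d = 0.3)
  set.seed(9)
  # mean inner-CV accuracy across the hyperparameter grid: the maximised
  # (selected) accuracy is optimistically biased by construction, the grid
  # mean is the unbiased chance-level readout
  accs <- vapply(1:100, function(i) {
    yp <- sample(cl$y)
    mean(train_svm_rbf(cl$x, yp, seed = i)$grid_accuracy)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.03)
})

test_that("stratified 10-fold CV separates separable data and not shuffled data", {
  cl <- make_clouds(n_per = 30, d = 3, seed = 2)
  cv <- crossval_10fold(cl$x, cl$y, seed = 1)
  expect_gte(cv$accuracy, 0.95)
  expect_equal(cv$folds, 10)
  accs <- vapply(1:5, function(i) {
    set.seed(100 + i)
    crossval_10fold(cl$x, sample(cl$y), seed = i)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("fold count shrinks with a warning for small classes", {
  cl <- make_clouds(n_per = 6, d = 3, seed = 3)
  expect_warning(cv <- crossval_10fold(cl$x, cl$y, seed = 1), "reducing folds")
  expect_equal(cv$folds, 6)
  expect_error(crossval_10fold(cl$x[1:7, ], factor(c(rep("a", 6), "b")), seed = 1),
               "at least 2")
})

test_that("permutation p-values hit their boundary conventions", {
  cl <- make_clouds(n_per = 10, d = 4, seed = 4)
  te <- make_clouds(n_per = 10, d = 4, seed = 5)
  # strongly separable: observed accuracy above every permuted draw
  pt <- permutation_test(cl$x, cl$y, te$x, te$y, C = 1, gamma = 0.2,
                         B = 49, seed = 1)
  expect_equal(pt$p, 1 / 50)
  expect_equal(pt$observed, 1)
  # anti-learnable test labels: observed at or below the permuted draws
  te_bad <- te
  te_bad$y <- factor(rev(as.character(te$y)), levels = levels(te$y))
  pt2 <- permutation_test(cl$x, cl$y, te_bad$x, te_bad$y, C = 1, gamma = 0.2,
                          B = 49, seed = 2)
  expect_gt(pt2$p, 0.9)
  expect_error(permutation_test(cl$x, cl$y, te$x, te$y, B = 0), "B must be")
})

test_that("sampled permutation p matches exhaustive enumeration on small sets", {
  set.seed(6)
  n <- 8
  x <- matrix(stats::rnorm(n * 3), n, 3)
  x[5:8, ] <- x[5:8, ] + 1.2
  y <- factor(rep(c("low", "high"), each = 4), levels = c("low", "high"))
  xt <- matrix(stats::rnorm(12 * 3), 12, 3)
  xt[7:12, ] <- xt[7:12, ] + 1.2
  yt <- factor(rep(c("low", "high"), each = 6), levels = c("low", "high"))

  ex <- permutation_test(x, y, xt, yt, C = 2, gamma = 0.3, exhaustive = TRUE)
  expect_equal(ex$B, choose(8, 4))

  # independent oracle: enumerate all label arrangements directly
  pos <- utils::combn(n, 4)
  obs_fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                        cost = 2, gamma = 0.3, scale = FALSE)
  obs <- mean(predict(obs_fit, xt) == yt)
  acc <- apply(pos, 2, function(idx) {
    yp <- factor(ifelse(seq_len(n) %in% idx, "low", "high"),
                 levels = c("low", "high"))
    m <- e1071::svm(x, yp, type = "C-classification", kernel = "radial",
                    cost = 2, gamma = 0.3, scale = FALSE)
    mean(predict(m, xt) == yt)
  })
  expect_equal(ex$p, mean(acc >= obs - 1e-12))
  expect_equal(sort(ex$permuted), sort(acc))

  # the sampled estimator converges to the same p
  sam <- permutation_test(x, y, xt, yt, C = 2, gamma = 0.3, B = 2000, seed = 3)
  expect_lt(abs(sam$p - ex$p), 0.05)
})

test_that("cross-task evaluation trains once and scores each task per trial", {
  tr <- make_clouds(n_per = 15, d = 2.5, seed = 7)
  t1 <- make_clouds(n_per = 12, d = 2.5, seed = 8)
  t2 <- make_clouds(n_per = 9, d = 2.5, seed = 9)
  ev <- cross_task_evaluate(tr, list(taskA = t1, taskB = t2), seed = 1, B = 99)
  expect_equal(ev$results$task, c("taskA", "taskB"))
  expect_equal(ev$results$n_test, c(24L, 18L))
  expect_true(all(ev$results$accuracy > 0.8))
  # permutation p on tiny two-cluster toys is heavy-tailed by construction
  # (a permuted majority can tip a whole cluster), so only its range is
  # asserted here; calibration of p under the null is tested on full
  # pipeline simulations in the acceptance suite
  expect_true(all(ev$results$p_value > 0 & ev$results$p_value <= 1))
  bad <- t1
  colnames(bad$x) <- paste0("g", 1:5)
  expect_error(cross_task_evaluate(tr, list(bad = bad)), "feature names")
})

test_that("calibration statistics never depend on test trials", {
  tr <- make_clouds(n_per = 12, d = 2, seed = 10)
  t1 <- make_clouds(n_per = 10, d = 2, seed = 11)
  ev_full <- cross_task_evaluate(tr, list(a = t1), seed = 1, B = 9)
  t1_less <- list(x = t1$x[-1, , drop = FALSE], y = t1$y[-1])
  ev_less <- cross_task_evaluate(tr, list(a = t1_less), seed = 1, B = 9)
  expect_identical(ev_full$zscore, ev_less$zscore)
  expect_identical(c(ev_full$model$C, ev_full$model$gamma),
                   c(ev_less$model$C, ev_less$model$gamma))
})

test_that("cohort reports count cells and significance", {
  df <- data.frame(subject = rep(sprintf("S%02d", 1:16), each = 2),
                   task = rep(c("subtraction", "fraction"), 16),
                   n_test = 20,
                   accuracy = seq(0.5, 0.95, length.out = 32),
                   p_value = rep(c(0.01, 0.2), 16))
  rp <- report(df)
  expect_equal(rp$n_total, 32)
  expect_equal(rp$n_significant, 16)
  expect_equal(rp$mean_accuracy, mean(df$accuracy))
  expect_error(report(df[0, ]), "no results")
  path <- file.path(tempdir(), "report.json")
  write_report_json(rp, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
  unlink(path)
})
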