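quick_sae <- function(X, y, seed) {
  sae_fit(X, y, hidden_sizes = c(3), pretrain_epochs = 5, head_epochs = 40,
          finetune_epochs = 40, seed = seed)
}

test_that("confusion counts match hand-tallied toy cases", {
  cm <- confusion_matrix(c("W", "W", "S1"), c("W", "S1", "S1"))
  expect_equal(sum(cm), 3)
  expect_equal(cm["W", "W"], 1L)
  expect_equal(cm["W", "S1"], 1L)
  expect_equal(cm["S1", "S1"], 1L)
  expect_equal(sum(diag(cm)) / sum(cm), 2 / 3)

  y <- sample(c("W", "S2", "REM"), 30, replace = TRUE)
  cmd <- confusion_matrix(y, y)
  expect_equal(sum(diag(cmd)), 30L)
  expect_true(all(cmd[upper.tri(cmd) | lower.tri(cmd)] == 0))

  expect_error(confusion_matrix(character(0), character(0)), "empty")
  expect_error(confusion_matrix("W", "NREM9"), "outside")
  expect_error(confusion_matrix(c("W", "W"), "W"), "length")
})

test_that("every reported accuracy is recomputable from the confusion matrix", {
  set.seed(77)
  y_true <- sample(c("W", "S1", "S2", "S3", "S4", "REM"), 200, replace = TRUE)
  y_pred <- ifelse(runif(200) < 0.7, y_true,
                   sample(c("W", "S1", "S2", "S3", "S4", "REM"), 200, replace = TRUE))
  r <- eval_report(y_true, y_pred)
  cm <- r$confusion
  expect_identical(r$average_accuracy, sum(diag(cm)) / sum(cm))
  expect_identical(r$n, sum(cm))
  rs <- rowSums(cm)
  for (c in seq_len(6)) {
    if (rs[c] > 0) expect_identical(r$per_class_accuracy[[c]],
                                    unname(cm[c, c] / rs[c]))
    else expect_identical(r$per_class_accuracy[[c]], 0)
    # one-vs-rest (TP + TN) / total
    tp <- cm[c, c]; fn <- unname(rs[c] - tp); fp <- sum(cm[, c]) - tp
    expect_identical(r$ovr_accuracy[[c]],
                     unname((tp + (sum(cm) - tp - fn - fp)) / sum(cm)))
  }
  # empty true classes are reported and flagged
  r2 <- eval_report(rep("W", 5), rep("W", 5))
  expect_equal(unname(r2$per_class_accuracy["S1"]), 0)
  expect_true("S1" %in% r2$empty_classes)
})

test_that("stratified k-fold partitions the data exactly once per sample", {
  set.seed(30)
  X <- matrix(runif(100 * 4), 100, 4)
  y <- rep(c("A", "B"), 50)
  cv <- kfold_cv(X, y, k = 10, train_fn = quick_sae, seed = 6,
                 levels = c("A", "B"))
  expect_equal(cv$k, 10L)
  expect_length(cv$fold_reports, 10L)
  # every fold tests exactly 10 samples, 5 per class (perfect stratification)
  expect_true(all(table(cv$fold) == 10))
  expect_true(all(table(cv$fold, y) == 5))
  expect_equal(sum(vapply(cv$fold_reports, `[[`, integer(1), "n")), 100L)

  cv2 <- kfold_cv(X, y, k = 10, train_fn = quick_sae, seed = 6,
                  levels = c("A", "B"))
  expect_identical(cv$fold, cv2$fold)
  expect_equal(cv$mean_accuracy, cv2$mean_accuracy)

  expect_error(kfold_cv(X[1:5, ], y[1:5], k = 10, seed = 1), "fewer samples")
  expect_warning(emdsleep:::stratified_folds(c(rep("A", 30), "B"), 10, 1),
                 "fewer than k")
})

test_that("baseline comparison evaluates all four classifiers consistently", {
  set.seed(55)
  n <- 60
  X <- rbind(matrix(rnorm(n * 5, 0), n, 5),
             matrix(rnorm(n * 5, 8), n, 5),
             matrix(rnorm(n * 5, -8), n, 5))
  y <- rep(c("A", "B", "C"), each = n)
  tr <- sort(c(sample(1:n, 40), sample(n + 1:n, 40), sample(2 * n + 1:n, 40)))
  te <- setdiff(seq_len(3 * n), tr)
  sae_args <- list(hidden_sizes = c(4, 2), pretrain_epochs = 10,
                   head_epochs = 50, finetune_epochs = 50)
  cmp <- compare_baselines(X[tr, ], y[tr], X[te, ], y[te], seed = 2,
                           sae_args = sae_args)
  expect_equal(nrow(cmp), 4L)
  expect_setequal(cmp$classifier, c("SAE", "FFNN", "SVM", "DT"))
  expect_true(all(cmp$accuracy >= 0.95))   # trivially separable data

  # SAE row equals an independent fit + predict with the same seed
  m <- do.call(sae_fit, c(list(x = X[tr, ], y = factor(y[tr]), seed = 2), sae_args))
  acc <- mean(predict(m, X[te, ]) == y[te])
  expect_equal(cmp$accuracy[cmp$classifier == "SAE"], acc)
  expect_named(attr(cmp, "hyperparameters"), c("SAE", "FFNN", "SVM", "DT"))
})

test_that("evaluation reports serialize losslessly to JSON", {
  set.seed(5)
  y_true <- sample(c("W", "S2", "REM"), 50, replace = TRUE)
  y_pred <- sample(c("W", "S2", "REM"), 50, replace = TRUE)
  r <- eval_report(y_true, y_pred)
  d <- file.path(tempdir(), "report_out")
  write_report(r, d)
  back <- read_report(file.path(d, "report.json"))
  expect_equal(back$average_accuracy, r$average_accuracy)
  expect_equal(back$n, r$n)
  cm_back <- unname(as.matrix(back$confusion))   # rows = true class
  expect_equal(cm_back, unname(unclass(r$confusion)))
  expect_equal(unlist(back$per_class_accuracy),
               unlist(as.list(r$per_class_accuracy)))
})
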