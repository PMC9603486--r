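#' Confusion matrix over the six sleep stages
#'
#' Counts with rows = true class and columns = predicted class, in the fixed
#' order `W, S1, S2, S3, S4, REM`.
#'
#' @param y_true,y_pred equal-length label vectors (valid stage labels).
#' @param levels class order; defaults to the canonical six stages. Pass a
#'   different factor level set for non-sleep data.
#' @return integer matrix with class dimnames.
#' @export
confusion_matrix <- function(y_true, y_pred, levels = STAGE_LEVELS) {
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred differ in length")
  if (!length(y_true)) stop("empty input")
  t_f <- factor(as.character(y_true), levels = levels)
  p_f <- factor(as.character(y_pred), levels = levels)
  if (anyNA(t_f) || anyNA(p_f)) stop("labels outside the class set: ",
                                     paste(levels, collapse = ", "))
  m <- table(true = t_f, predicted = p_f)
  matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
}

#' Evaluation report for one set of predictions
#'
#' Computes the confusion matrix, per-class accuracy (diagonal over row sum,
#' i.e. recall; 0 with a flag for classes absent from `y_true`), the
#' one-vs-rest binary accuracy `(TP + TN) / n` per class, and the multiclass
#' average accuracy `trace / n`.
#'
#' @inheritParams confusion_matrix
#' @param fold_id optional fold identifier carried into the report.
#' @return object of class `eval_report`.
#' @export
eval_report <- function(y_true, y_pred, levels = STAGE_LEVELS, fold_id = NULL) {
  cm <- confusion_matrix(y_true, y_pred, levels)
  n <- sum(cm)
  rs <- rowSums(cm); cs <- colSums(cm); tp <- diag(cm)
  per_class <- ifelse(rs > 0, tp / rs, 0)
  ovr <- (tp + (n - rs - cs + tp)) / n          # (TP + TN) / total, one-vs-rest
  structure(
    list(confusion = cm,
         per_class_accuracy = per_class,
         empty_classes = names(rs)[rs == 0],
         ovr_accuracy = ovr,
         average_accuracy = sum(tp) / n,
         n = n, fold_id = fold_id),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report>%s n = %d, average accuracy = %.4f\n",
              if (!is.null(x$fold_id)) sprintf(" fold %s:", x$fold_id) else "",
              x$n, x$average_accuracy))
  print(x$confusion)
  cat("per-class accuracy:",
      paste(sprintf("%s %.3f", names(x$per_class_accuracy), x$per_class_accuracy),
            collapse = ", "), "\n")
  invisible(x)
}

# deterministic stratified fold assignment
stratified_folds <- function(y, k, seed) {
  y <- factor(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  if (any(table(y) < k))
    warning("class(es) with fewer than k members: stratification is non-strict")
  fold
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into `k` stratified folds (seed-deterministic), trains an
#' independent model on each training fold with a fresh derived seed, and
#' evaluates on the held-out fold, so every sample is tested exactly once.
#'
#' @param X feature matrix.
#' @param y labels.
#' @param k number of folds (default 10).
#' @param train_fn `function(X, y, seed)` returning a model usable with
#'   [predict()]; defaults to [sae_fit()] with its default configuration.
#' @param seed master integer seed.
#' @param levels class order for the reports.
#' @return object of class `cv_report`: per-fold [eval_report()]s, the fold
#'   assignment, and mean/sd of the fold average accuracies.
#' @export
kfold_cv <- function(X, y, k = 10,
                     train_fn = function(X, y, seed) sae_fit(X, y, seed = seed),
                     seed = 1, levels = STAGE_LEVELS) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) stop("fewer samples than folds")
  fold <- stratified_folds(y, k, seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    model <- train_fn(X[tr, , drop = FALSE], y[tr], derive_seed(seed, 1000 + f))
    pred <- predict(model, X[te, , drop = FALSE])
    reports[[f]] <- eval_report(y[te], pred, levels = levels, fold_id = f)
  }
  acc <- vapply(reports, `[[`, numeric(1), "average_accuracy")
  structure(list(fold_reports = reports, fold = fold, k = k, seed = seed,
                 mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  acc <- vapply(x$fold_reports, `[[`, numeric(1), "average_accuracy")
  cat(sprintf("<cv_report> %d-fold CV (seed %d): accuracy %.4f +/- %.4f\n",
              x$k, x$seed, x$mean_accuracy, x$sd_accuracy))
  cat("fold accuracies:", paste(sprintf("%.3f", acc), collapse = " "), "\n")
  invisible(x)
}

#' Compare the stacked autoencoder against standard baselines
#'
#' Trains the SAE, a single-hidden-layer feed-forward network
#' (`nnet`, 32 units, softmax output), an RBF-kernel support vector machine
#' (`e1071` defaults) and an unpruned decision tree (`rpart`, `cp = 0`) on
#' the same feature matrices, with fixed documented hyperparameters and no
#' tuning, and reports each classifier's test average accuracy.
#'
#' @param train_X,y_train,test_X,y_test disjoint train/test features and labels.
#' @param seed integer seed shared across classifiers.
#' @param sae_args named list of extra arguments to [sae_fit()].
#' @return `data.frame(classifier, accuracy)` with 4 rows (SAE, FFNN, SVM,
#'   DT), with the hyperparameter record as attribute `"hyperparameters"`
#'   and the per-classifier [eval_report()]s as attribute `"reports"`.
#' @export
compare_baselines <- function(train_X, y_train, test_X, y_test, seed = 1,
                              sae_args = list()) {
  train_X <- as.matrix(train_X); test_X <- as.matrix(test_X)
  lv <- if (all(as.character(y_train) %in% STAGE_LEVELS)) STAGE_LEVELS
        else levels(factor(y_train))
  y_tr <- factor(as.character(y_train), levels = lv)
  y_te <- factor(as.character(y_test), levels = lv)

  sae <- do.call(sae_fit, c(list(x = train_X, y = y_tr, seed = seed), sae_args))
  pred_sae <- predict(sae, test_X)

  nf <- normalize_features(train_X, test_X)
  ffnn <- with_seed(derive_seed(seed, 1),
    nnet::nnet(nf$train, diag(length(lv))[as.integer(y_tr), , drop = FALSE],
               size = 32, softmax = TRUE, maxit = 300, decay = 1e-4,
               MaxNWts = 100000, trace = FALSE))
  pred_ffnn <- lv[apply(predict(ffnn, nf$test), 1, which.max)]

  svm_fit <- with_seed(derive_seed(seed, 2),
    e1071::svm(nf$train, y_tr, kernel = "radial"))
  pred_svm <- predict(svm_fit, nf$test)

  dt_df <- data.frame(y = y_tr, nf$train, check.names = TRUE)
  dt_fit <- with_seed(derive_seed(seed, 3),
    rpart::rpart(y ~ ., data = dt_df, method = "class",
                 control = rpart::rpart.control(cp = 0, xval = 0)))
  pred_dt <- predict(dt_fit, data.frame(nf$test, check.names = TRUE), type = "class")

  reports <- list(
    SAE = eval_report(y_te, pred_sae, levels = lv),
    FFNN = eval_report(y_te, pred_ffnn, levels = lv),
    SVM = eval_report(y_te, pred_svm, levels = lv),
    DT = eval_report(y_te, pred_dt, levels = lv))
  out <- data.frame(
    classifier = names(reports),
    accuracy = vapply(reports, `[[`, numeric(1), "average_accuracy"),
    row.names = NULL)
  attr(out, "reports") <- reports
  attr(out, "hyperparameters") <- list(
    SAE = sae$train_meta[c("hidden_sizes", "pretrain_epochs", "head_epochs",
                           "finetune_epochs", "learning_rate", "l2_weight",
                           "batch_size")],
    FFNN = list(size = 32, maxit = 300, decay = 1e-4, softmax = TRUE),
    SVM = list(kernel = "radial", cost = 1, gamma = "1/ncol"),
    DT = list(cp = 0, xval = 0, method = "class"))
  out
}

#' Write an evaluation report to JSON (+ CSV confusion matrix)
#'
#' @param report an [eval_report()] or `cv_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as_list <- function(r) list(
    n = r$n, average_accuracy = r$average_accuracy,
    per_class_accuracy = as.list(r$per_class_accuracy),
    ovr_accuracy = as.list(r$ovr_accuracy),
    confusion = unname(apply(r$confusion, 1, as.list)))
  if (inherits(report, "eval_report")) {
    jsonlite::write_json(as_list(report), file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(report$confusion, file.path(dir, "confusion.csv"))
  } else {
    jsonlite::write_json(
      list(k = report$k, seed = report$seed,
           mean_accuracy = report$mean_accuracy, sd_accuracy = report$sd_accuracy,
           folds = lapply(report$fold_reports, as_list)),
      file.path(dir, "cv_report.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read back a JSON evaluation report
#' @param path path to a `report.json` written by [write_report()].
#' @return list mirroring the report fields.
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
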