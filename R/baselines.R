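## Conventional regression baselines fitted on the same windows as the
## network — linear regression, RBF support-vector regression, k-nearest
## neighbours and a decision tree — each as three independent
## single-output regressors, plus a shared-fold comparison harness.

#' Feature representation of a window array
#'
#' `"flat"` unrolls each 60 x 32 window to a 1920-vector (the same
#' information the network sees); `"channel_mean"` reduces each window
#' to its 32 per-channel mean envelope values.
#'
#' @param X n x 60 x 32 window array (or `emg_dataset`).
#' @param feature_mode `"flat"` or `"channel_mean"`.
#' @return n x p numeric feature matrix.
#' @export
window_features <- function(X, feature_mode = c("flat", "channel_mean")) {
  feature_mode <- match.arg(feature_mode)
  if (inherits(X, "emg_dataset")) X <- X$X
  d <- dim(X)
  if (feature_mode == "flat") {
    out <- X
    dim(out) <- c(d[1], d[2] * d[3])
    out
  } else {
    apply(X, c(1, 3), mean)
  }
}

#' Fit one conventional baseline regressor
#'
#' One single-output model per joint: `lr` = ordinary least squares
#' (`stats::lm.fit`), `svr` = epsilon-SVR with RBF kernel
#' (`e1071::svm`), `knn` = k-nearest-neighbour regression
#' (`caret::knnreg`, k = 5 by default), `dt` = CART regression tree
#' (`rpart::rpart`).  Hyperparameters are library defaults unless
#' overridden through `params`.
#'
#' @param kind One of `"lr"`, `"svr"`, `"knn"`, `"dt"`.
#' @param X Window array or `emg_dataset`.
#' @param y n x 3 target matrix (taken from the dataset if omitted).
#' @param feature_mode Passed to [window_features()].
#' @param params Named list of hyperparameter overrides (e.g.
#'   `list(k = 3)` for knn, `list(cost = 10)` for svr).
#' @param seed Seed for any stochastic fitting step.
#' @return An object of class `emg_baseline` with a [predict][
#'   predict.emg_baseline] method returning an n x 3 matrix.
#' @export
fit_baseline <- function(kind = c("lr", "svr", "knn", "dt"), X, y = NULL,
                         feature_mode = c("flat", "channel_mean"),
                         params = list(), seed = 1L) {
  kind <- match.arg(kind)
  feature_mode <- match.arg(feature_mode)
  if (inherits(X, "emg_dataset")) {
    if (is.null(y)) y <- X$y
  }
  Fe <- window_features(X, feature_mode)
  y <- as.matrix(y)
  if (nrow(Fe) < 2) stop_data("need at least 2 training samples")
  if (kind == "knn" && nrow(Fe) < (params$k %||% 5))
    stop_data("knn requires at least k = ", params$k %||% 5, " samples")
  fits <- with_seed(seed, lapply(seq_len(ncol(y)), function(j) {
    yy <- y[, j]
    switch(kind,
      lr = stats::lm.fit(cbind(1, Fe), yy)$coefficients,
      svr = do.call(e1071::svm,
                    c(list(x = Fe, y = yy, kernel = "radial", scale = FALSE),
                      params)),
      knn = do.call(caret::knnreg, c(list(x = Fe, y = yy), params)),
      dt = {
        df <- as.data.frame(Fe)
        do.call(rpart::rpart,
                c(list(formula = yy ~ ., data = cbind(yy = yy, df),
                       method = "anova"), params))
      })
  }))
  structure(list(kind = kind, fits = fits, feature_mode = feature_mode,
                 n_features = ncol(Fe)),
            class = "emg_baseline")
}

#' @export
predict.emg_baseline <- function(object, newdata, ...) {
  Fe <- window_features(newdata, object$feature_mode)
  pred <- vapply(object$fits, function(f) {
    if (object$kind == "lr") {
      beta <- f
      beta[is.na(beta)] <- 0
      drop(cbind(1, Fe) %*% beta)
    } else if (object$kind == "dt") {
      unname(stats::predict(f, as.data.frame(Fe)))
    } else {
      unname(stats::predict(f, Fe))
    }
  }, numeric(nrow(Fe)))
  colnames(pred) <- JOINT_NAMES[seq_len(ncol(pred))]
  pred
}

#' @export
print.emg_baseline <- function(x, ...) {
  cat(sprintf("<emg_baseline> %s, %d features (%s), %d outputs\n",
              toupper(x$kind), x$n_features, x$feature_mode, length(x$fits)))
  invisible(x)
}

#' Evaluate the network and all baselines under shared folds
#'
#' Every model is trained and tested on the identical trial-wise splits
#' and scored with the same per-joint correlation coefficient, so the
#' comparison isolates the model class.
#'
#' @param dataset An `emg_dataset`.
#' @param folds A `fold_split`.
#' @param models Character subset of `c("cnn", "lr", "svr", "knn", "dt")`.
#' @param cnn_args List of arguments forwarded to [cross_validate()] for
#'   the network.
#' @param baseline_params Named list (by model kind) of hyperparameter
#'   overrides.
#' @param feature_mode Baseline feature representation.
#' @param seed Base seed.
#' @return An object of class `model_comparison`: `per_fold_cc` (list of
#'   k x 3 matrices by model), `mean_cc` (named vector of joint-averaged
#'   mean CC per model), `summary` data frame.
#' @export
evaluate_all_models <- function(dataset, folds,
                                models = c("cnn", "lr", "svr", "knn", "dt"),
                                cnn_args = list(), baseline_params = list(),
                                feature_mode = c("flat", "channel_mean"),
                                seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  models <- match.arg(models, several.ok = TRUE)
  if (!setequal(unique(dataset$trial), as.integer(names(folds$group_of_trial))))
    stop_config("fold trial ids do not match the dataset's trials")
  k <- folds$k
  all_trials <- unique(dataset$trial)
  per_fold <- lapply(models, function(m)
    matrix(NA_real_, k, ncol(dataset$y),
           dimnames = list(NULL, colnames(dataset$y))))
  names(per_fold) <- models
  if ("cnn" %in% models) {
    cv <- do.call(cross_validate,
                  c(list(dataset = dataset, folds = folds, seed = seed,
                         keep_models = FALSE), cnn_args))
    per_fold[["cnn"]] <- cv$per_fold_cc
  }
  for (g in seq_len(k)) {
    test_trials <- fold_test_trials(folds, g)
    train <- subset_trials(dataset, setdiff(all_trials, test_trials))
    test <- subset_trials(dataset, test_trials)
    for (m in setdiff(models, "cnn")) {
      fit <- fit_baseline(m, train$X, train$y, feature_mode = feature_mode,
                          params = baseline_params[[m]] %||% list(),
                          seed = seed + g)
      per_fold[[m]][g, ] <- per_joint_cc(predict(fit, test$X), test$y)
    }
  }
  mean_cc <- vapply(per_fold, function(m) mean(m, na.rm = TRUE), 0)
  summary <- data.frame(
    model = models,
    mean_cc = mean_cc,
    sd_cc = vapply(per_fold, function(m)
      stats::sd(rowMeans(m, na.rm = TRUE), na.rm = TRUE), 0),
    row.names = NULL)
  structure(list(per_fold_cc = per_fold, mean_cc = mean_cc,
                 summary = summary, folds = folds),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison under shared folds (CC averaged over joints)\n")
  df <- x$summary
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-4s: %.4f +/- %.4f\n", toupper(df$model[i]),
                df$mean_cc[i], df$sd_cc[i]))
  invisible(x)
}
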