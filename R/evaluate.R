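## Correlation scoring and trial-wise five-fold cross-validation.

#' Pearson correlation between an estimated and a measured series
#'
#' Direct two-pass evaluation of the product-moment formula
#' `sum((x - mean(x)) * (y - mean(y))) / sqrt(sum((x - mean(x))^2) *
#' sum((y - mean(y))^2))`.  A constant series leaves the coefficient
#' undefined; `NA` is returned with a warning so callers can exclude it.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation coefficient in \[-1, 1\], or `NA` if either
#'   series is constant.
#' @export
correlation_coefficient <- function(x, y) {
  if (length(x) != length(y)) stop_data("series lengths differ")
  if (length(x) < 2) stop_data("need at least 2 samples")
  if (anyNA(x) || anyNA(y)) stop_data("series contain missing values")
  dx <- x - mean(x)
  dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) {
    warning("constant series: correlation coefficient undefined")
    return(NA_real_)
  }
  sum(dx * dy) / den
}

## Per-joint CC between prediction and target matrices.
per_joint_cc <- function(pred, y) {
  vapply(seq_len(ncol(y)), function(j)
    suppressWarnings(correlation_coefficient(pred[, j], y[, j])), 0)
}

#' Five-fold cross-validation of the force-pattern network
#'
#' For each fold the model is trained from a fresh initialization (seed
#' lineage `seed + fold`) on the other k-1 trial groups and scored on the
#' held-out group by per-joint Pearson correlation between the predicted
#' and measured window-target series.  The final score per joint is the
#' arithmetic mean of the k fold correlations.
#'
#' @param dataset An `emg_dataset`.
#' @param folds A `fold_split` over the dataset's trials.
#' @param epochs,learning_rate,batch_size Training protocol (defaults:
#'   15 epochs, lr 0.001, batch 64).
#' @param seed Base seed for the per-fold initialization lineage.
#' @param init Optional warm-start parameters applied to every fold
#'   (used by transfer-learning recalibration).
#' @param freeze_conv Freeze the convolutional layer in every fold.
#' @param keep_models Retain the k fitted models in the result.
#' @return An object of class `fpcnn_cv`: `per_fold_cc` (k x 3 matrix),
#'   `mean_cc` and `sd_cc` (3-vectors), `loss_histories`, `folds`,
#'   optionally `models`, and `predictions` (per fold: `y`, `pred`,
#'   `trial`).
#' @export
cross_validate <- function(dataset, folds, epochs = 15,
                           learning_rate = 0.001, batch_size = 64,
                           seed = 1L, init = NULL, freeze_conv = FALSE,
                           keep_models = TRUE) {
  if (!inherits(dataset, "emg_dataset")) stop_data("dataset must be an emg_dataset")
  if (!inherits(folds, "fold_split")) stop_config("folds must be a fold_split")
  if (!setequal(unique(dataset$trial), as.integer(names(folds$group_of_trial))))
    stop_config("fold trial ids do not match the dataset's trials")
  k <- folds$k
  per_fold <- matrix(NA_real_, k, ncol(dataset$y),
                     dimnames = list(NULL, colnames(dataset$y)))
  models <- vector("list", k)
  histories <- vector("list", k)
  predictions <- vector("list", k)
  for (g in seq_len(k)) {
    test_trials <- fold_test_trials(folds, g)
    train <- subset_trials(dataset, setdiff(unique(dataset$trial), test_trials))
    test <- subset_trials(dataset, test_trials)
    if (nrow(test$y) < 2)
      stop_data("fold ", g, " has fewer than 2 test windows")
    fit <- fpcnn(train$X, train$y, epochs = epochs,
                 learning_rate = learning_rate, batch_size = batch_size,
                 init = init, freeze_conv = freeze_conv, seed = seed + g)
    pred <- predict(fit, test$X)
    per_fold[g, ] <- per_joint_cc(pred, test$y)
    histories[[g]] <- fit$loss_history
    predictions[[g]] <- list(y = test$y, pred = pred, trial = test$trial)
    if (keep_models) models[[g]] <- fit
  }
  structure(list(per_fold_cc = per_fold,
                 mean_cc = colMeans(per_fold),
                 sd_cc = apply(per_fold, 2, stats::sd),
                 loss_histories = histories,
                 predictions = predictions,
                 models = if (keep_models) models,
                 folds = folds,
                 config = list(epochs = epochs, learning_rate = learning_rate,
                               batch_size = batch_size, seed = seed,
                               freeze_conv = freeze_conv)),
            class = "fpcnn_cv")
}

#' @export
print.fpcnn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (CC, mean +/- sd over folds)\n",
              nrow(x$per_fold_cc)))
  for (j in seq_along(x$mean_cc)) {
    cat(sprintf("  %-5s: %.4f +/- %.4f\n", names(x$mean_cc)[j],
                x$mean_cc[j], x$sd_cc[j]))
  }
  invisible(x)
}
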