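## New-session evaluation and freeze-convolution recalibration.
##
## Signal amplitude and electrode placement drift between sessions, so a
## model trained on one day degrades when applied directly to another.
## Direct testing quantifies that drop; fine-tuning freezes the temporal
## (force-pattern) filters — which capture subject-specific activation
## dynamics — and retrains only the fully connected spatial readout on
## the small new-day dataset.

#' Direct model testing on a new dataset
#'
#' Applies a previously trained model to new windows with no parameter
#' updates and reports the per-joint correlation coefficient.
#'
#' @param model A fitted `fpcnn`.
#' @param dataset An `emg_dataset` (typically a new-day session
#'   preprocessed with the *stored* training-day normalization
#'   statistics).
#' @return Named 3-vector of per-joint CC values.
#' @export
direct_test <- function(model, dataset) {
  if (!inherits(model, "fpcnn")) stop_config("model must be a fitted fpcnn")
  pred <- predict(model, dataset)
  y <- if (inherits(dataset, "emg_dataset")) dataset$y else
    stop_data("dataset must be an emg_dataset")
  cc <- per_joint_cc(pred, y)
  names(cc) <- colnames(y)
  cc
}

#' Fine-tune the FC layer on a new session (transfer learning)
#'
#' Warm-starts every fold from the trained model, freezes the
#' convolutional layer (bit-identical before and after, asserted), and
#' retrains only the FC weights and biases — 5 epochs by default — under
#' the same five-fold protocol as [cross_validate()].  Also returns a
#' model fine-tuned on the full new session for deployment.
#'
#' @param model A fitted `fpcnn` from the original session.
#' @param dataset An `emg_dataset` of the new session (normalization
#'   statistics recomputed on the new session).
#' @param folds A `fold_split`; the reduced design uses `"second"` mode
#'   (five singleton trial groups).
#' @param epochs Fine-tuning epochs.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param freeze_conv Keep the convolutional layer fixed (default TRUE).
#' @param seed Base seed for fold lineage and shuffling.
#' @return An object of class `fpcnn_transfer`: list with `cv`
#'   (`fpcnn_cv` of the fine-tuned folds) and `model` (fine-tuned on all
#'   new trials).
#' @export
fine_tune_fc <- function(model, dataset, folds, epochs = 5,
                         learning_rate = 0.001, batch_size = 64,
                         freeze_conv = TRUE, seed = 1L) {
  if (!inherits(model, "fpcnn")) stop_config("model must be a fitted fpcnn")
  cv <- cross_validate(dataset, folds, epochs = epochs,
                       learning_rate = learning_rate,
                       batch_size = batch_size, seed = seed,
                       init = model$params, freeze_conv = freeze_conv)
  full <- fpcnn(dataset, epochs = epochs, learning_rate = learning_rate,
                batch_size = batch_size, init = model$params,
                freeze_conv = freeze_conv, seed = seed)
  if (freeze_conv) {
    frozen_ok <- identical(model$params$conv_filters, full$params$conv_filters) &&
      identical(model$params$conv_bias, full$params$conv_bias) &&
      all(vapply(cv$models, function(m)
        identical(model$params$conv_filters, m$params$conv_filters) &&
          identical(model$params$conv_bias, m$params$conv_bias), TRUE))
    if (!frozen_ok)
      stop("internal invariant violated: frozen convolutional layer changed")
  }
  structure(list(cv = cv, model = full), class = "fpcnn_transfer")
}

#' @export
print.fpcnn_transfer <- function(x, ...) {
  cat("Transfer-learning recalibration (FC-only fine-tuning)\n")
  print(x$cv)
  invisible(x)
}
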