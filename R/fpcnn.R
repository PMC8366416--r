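#' Fit the channel-wise force-pattern network
#'
#' Trains the two-layer regression network — six 60 x 1 channel-wise
#' temporal filters with tanh, then a linear map from the flattened
#' 192-feature vector to three joint angles — by minibatch Adam on mean
#' squared error.  Defaults follow the reference protocol: learning rate
#' 0.001, 15 epochs (5 for transfer fine-tuning), Adam moments
#' 0.9/0.999/1e-8.
#'
#' @param X Training windows: an n x 60 x 32 array, or an `emg_dataset`
#'   (in which case `y` is taken from it).
#' @param y n x 3 matrix of target joint angles in degrees.
#' @param epochs Training epochs (>= 1).
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param n_filters Number of temporal filters.
#' @param conv_bias Include per-filter biases?
#' @param freeze_conv If `TRUE`, the convolutional layer is not updated
#'   (transfer-learning recalibration trains the FC layer only).
#' @param init Optional `fpcnn_params` or fitted `fpcnn` to warm-start
#'   from; `NULL` initializes randomly from `seed`.
#' @param shuffle Reshuffle samples every epoch (seed-controlled).
#' @param seed Integer seed for initialization and shuffling.
#' @return An object of class `fpcnn`: list with `params`
#'   (`fpcnn_params`), `loss_history` (per-epoch mean training MSE),
#'   `config`, `n_train`, and `call`.  Methods: [predict.fpcnn()],
#'   [coef.fpcnn()], [plot.fpcnn()], `print`, `summary`, `fitted`,
#'   `residuals`.
#' @examples
#' sess <- generate_session(n_trials = 2, seed = 1,
#'                          paradigm = paradigm_spec(
#'                            motion_order = c("WF", "WE", "P", "S", "HG", "HO"),
#'                            hold_duration = 1, rest_duration = 0.5))
#' ds <- build_dataset(sess)
#' fit <- fpcnn(ds, epochs = 2, seed = 1)
#' cor(predict(fit, ds)[, 1], ds$y[, 1])
#' @export
fpcnn <- function(X, y = NULL, epochs = 15, learning_rate = 0.001,
                  batch_size = 64, n_filters = 6, conv_bias = TRUE,
                  freeze_conv = FALSE, init = NULL, shuffle = TRUE,
                  seed = 1L) {
  cl <- match.call()
  if (inherits(X, "emg_dataset")) {
    y <- X$y
    X <- X$X
  }
  if (is.null(y)) stop_config("y is required when X is an array")
  d <- dim(X)
  if (length(d) != 3) stop_data("X must be an n x win x channels array")
  y <- as.matrix(y)
  if (nrow(y) != d[1]) stop_data("X and y disagree on sample count")
  if (d[1] < 1) stop_data("at least one training sample is required")
  p <- if (is.null(init)) {
    init_fpcnn_params(seed = seed, n_filters = n_filters, win_len = d[2],
                      n_channels = d[3], n_out = ncol(y),
                      conv_bias = conv_bias)
  } else as_fpcnn_params(init)
  if (freeze_conv && is.null(init))
    warning("freeze_conv with random initialization freezes untrained filters")
  fit <- fit_adam(p, X, y, epochs = epochs, learning_rate = learning_rate,
                  batch_size = batch_size, freeze_conv = freeze_conv,
                  shuffle = shuffle, seed = seed)
  obj <- structure(list(params = fit$params,
                        loss_history = fit$history,
                        config = list(epochs = epochs,
                                      learning_rate = learning_rate,
                                      batch_size = batch_size,
                                      freeze_conv = freeze_conv,
                                      shuffle = shuffle, seed = seed),
                        n_train = d[1],
                        call = cl),
                   class = "fpcnn")
  obj$fitted.values <- predict(obj, X)
  obj$residuals <- y - obj$fitted.values
  obj
}

#' @export
fitted.fpcnn <- function(object, ...) object$fitted.values

#' @export
residuals.fpcnn <- function(object, ...) object$residuals

#' Predict joint angles for new windows
#'
#' @param object A fitted `fpcnn`.
#' @param newdata An n x 60 x 32 window array, a single 60 x 32 window,
#'   or an `emg_dataset`.
#' @param ... Unused.
#' @return n x 3 matrix of predicted joint angles in degrees (columns
#'   WFWE, PS, HGHO), rows in input order.
#' @export
predict.fpcnn <- function(object, newdata, ...) {
  if (inherits(newdata, "emg_dataset")) newdata <- newdata$X
  p <- object$params
  X <- as_window_array(newdata, p$win_len, p$n_channels)
  pred <- forward_batch(p, X)$pred
  colnames(pred) <- JOINT_NAMES[seq_len(ncol(pred))]
  pred
}

#' @export
coef.fpcnn <- function(object, ...) {
  p <- object$params
  list(conv_filters = p$conv_filters, conv_bias = p$conv_bias,
       W = p$W, b = p$b)
}

#' @export
print.fpcnn <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("Channel-wise force-pattern network\n",
                     "  %d filters of length %d over %d channels -> %d outputs ",
                     "(%d parameters)\n"),
              p$n_filters, p$win_len, p$n_channels, p$n_out,
              count_parameters(p)))
  cat(sprintf("  trained %d epochs on %d windows (final MSE %.4g deg^2)%s\n",
              length(x$loss_history), x$n_train,
              x$loss_history[length(x$loss_history)],
              if (x$config$freeze_conv) " [conv frozen]" else ""))
  invisible(x)
}

#' @export
summary.fpcnn <- function(object, ...) {
  p <- object$params
  out <- list(n_filters = p$n_filters, win_len = p$win_len,
              n_channels = p$n_channels, n_out = p$n_out,
              n_parameters = count_parameters(p),
              n_train = object$n_train,
              config = object$config,
              loss_history = object$loss_history)
  class(out) <- "summary.fpcnn"
  out
}

#' @export
print.summary.fpcnn <- function(x, ...) {
  cat("Channel-wise force-pattern network\n")
  cat(sprintf("  architecture : %d x %d filters, %d channels, %d outputs\n",
              x$n_filters, x$win_len, x$n_channels, x$n_out))
  cat(sprintf("  parameters   : %d\n", x$n_parameters))
  cat(sprintf("  training     : %d windows, %d epochs, lr %g, batch %d%s\n",
              x$n_train, x$config$epochs, x$config$learning_rate,
              x$config$batch_size,
              if (x$config$freeze_conv) ", conv frozen" else ""))
  cat(sprintf("  loss (MSE)   : %.4g -> %.4g deg^2\n",
              x$loss_history[1], x$loss_history[length(x$loss_history)]))
  invisible(x)
}
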