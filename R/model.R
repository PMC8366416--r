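## Numerics of the channel-wise force-pattern network.
##
## Architecture: six 60 x 1 temporal filters (stride 1, no padding)
## shared across the 32 channels, each collapsing the time axis of one
## channel to a single tanh activation -> a 6 x 32 feature map with no
## channel mixing; flattened feature-map-major to a 192-vector and mapped
## linearly to the three joint angles.  Loss is the mean squared error
## over samples and joints; training is plain minibatch Adam.
##
## Windows enter as an n x 60 x 32 array.  For speed the batch is
## reshaped to a 60 x (n*32) matrix M with column index (c-1)*n + i, so
## the whole convolution is one 6x60 by 60x(n*32) product; the matching
## reshapes below keep the feature-map-major flatten order
## phi[i, (j-1)*32 + c] = tanh(filter_j . X[i, , c] + bias_j).

#' Initialize force-pattern network parameters
#'
#' Filter taps are drawn nonnegative from U(0, 2/win_len), so every
#' feature map starts as an increasing function of the channel envelope
#' (an envelope-extracting polarity).  This matters for interpretation:
#' the FC-weight backtracking of [geometry_map()] superposes the six
#' per-feature-map weight blocks by plain summation, which is only
#' meaningful when the feature maps share one polarity — with
#' sign-symmetric filters the block sum is sign-degenerate.  FC weights
#' are scaled-uniform fan-in, U(-1/sqrt(n_filters * n_channels), ...);
#' biases start at zero.
#'
#' @param seed Integer seed; identical seeds give identical parameters.
#' @param n_filters Number of temporal filters (feature maps).
#' @param win_len Filter length in samples (= window length).
#' @param n_channels Electrode channels.
#' @param n_out Output joints.
#' @param conv_bias Include one bias per filter?
#' @return An object of class `fpcnn_params`: list with `conv_filters`
#'   (n_filters x win_len), `conv_bias` (n_filters), `W`
#'   (n_out x n_filters*n_channels), `b` (n_out), plus the dimensions.
#' @export
init_fpcnn_params <- function(seed = 1L, n_filters = 6, win_len = 60,
                              n_channels = 32, n_out = 3, conv_bias = TRUE) {
  n_flat <- n_filters * n_channels
  with_seed(seed, {
    r2 <- 1 / sqrt(n_flat)
    structure(list(
      conv_filters = matrix(stats::runif(n_filters * win_len, 0, 2 / win_len),
                            n_filters, win_len),
      conv_bias = if (conv_bias) numeric(n_filters) else NULL,
      W = matrix(stats::runif(n_out * n_flat, -r2, r2), n_out, n_flat),
      b = numeric(n_out),
      n_filters = n_filters, win_len = win_len,
      n_channels = n_channels, n_out = n_out,
      use_conv_bias = conv_bias),
      class = "fpcnn_params")
  })
}

#' Total number of trainable parameters
#'
#' With the default shape: 6*60 filter taps + 6 filter biases + 3*192 FC
#' weights + 3 FC biases = 945.
#'
#' @param params An `fpcnn_params` object (or a fitted `fpcnn` model).
#' @return Integer parameter count.
#' @export
count_parameters <- function(params) {
  p <- as_fpcnn_params(params)
  length(p$conv_filters) + length(p$conv_bias) + length(p$W) + length(p$b)
}

as_fpcnn_params <- function(x) {
  if (inherits(x, "fpcnn")) x$params
  else if (inherits(x, "fpcnn_params")) x
  else stop_config("expected an fpcnn model or fpcnn_params")
}

## Coerce a single 60x32 window or an n x 60 x 32 array to the batch array.
as_window_array <- function(X, win_len, n_channels) {
  if (is.matrix(X)) X <- array(X, c(1, nrow(X), ncol(X)))
  d <- dim(X)
  if (length(d) != 3 || d[2] != win_len || d[3] != n_channels)
    stop_data("window array must be n x ", win_len, " x ", n_channels,
              ", got ", paste(d, collapse = " x "))
  X
}

#' Convolutional (force-pattern) layer forward pass
#'
#' Each filter spans the full 60-sample time axis of one channel (stride
#' 1, no padding), so the time dimension collapses to length one and
#' channels never mix: `fm[j, c] = tanh(sum_t filter_j[t] * X[t, c] + bias_j)`.
#'
#' @param params An `fpcnn_params`.
#' @param X A single window (60 x 32 matrix).
#' @return The n_filters x n_channels post-tanh feature map.
#' @export
conv_forward <- function(params, X) {
  p <- as_fpcnn_params(params)
  if (!is.matrix(X) || nrow(X) != p$win_len || ncol(X) != p$n_channels)
    stop_data("X must be ", p$win_len, " x ", p$n_channels)
  A <- p$conv_filters %*% X
  if (p$use_conv_bias) A <- A + p$conv_bias
  tanh(A)
}

#' Flatten a feature map feature-map-major
#'
#' Concatenates the transposed 1 x 32 feature maps end to end: entries
#' 1-32 are feature map 1 over channels 1-32, entries 33-64 feature map
#' 2, and so on.  [unflatten_fm()] inverts it.
#'
#' @param fm n_filters x n_channels feature-map matrix.
#' @return Numeric vector of length n_filters * n_channels.
#' @export
flatten_fm <- function(fm) as.vector(t(fm))

#' @rdname flatten_fm
#' @param v Flattened feature vector.
#' @param n_filters,n_channels Feature-map dimensions.
#' @export
unflatten_fm <- function(v, n_filters = 6, n_channels = 32) {
  t(matrix(v, n_channels, n_filters))
}

#' Fully connected layer forward pass
#'
#' `angle_i = W_i . flatten(fm) + b_i` for the three joints; linear, no
#' activation.
#'
#' @param params An `fpcnn_params`.
#' @param fm Feature map from [conv_forward()] (matrix) or an
#'   already-flattened vector.
#' @return Named 3-vector of joint angles in degrees.
#' @export
fc_forward <- function(params, fm) {
  p <- as_fpcnn_params(params)
  v <- if (is.matrix(fm)) flatten_fm(fm) else fm
  if (length(v) != ncol(p$W))
    stop_data("feature vector must have length ", ncol(p$W))
  out <- drop(p$W %*% v) + p$b
  names(out) <- JOINT_NAMES[seq_along(out)]
  out
}

#' Full forward pass for one window
#'
#' @param params An `fpcnn_params`.
#' @param X A 60 x 32 window.
#' @return List with `fm` (6 x 32 feature map) and `angles` (3-vector).
#' @export
fpcnn_forward <- function(params, X) {
  fm <- conv_forward(params, X)
  list(fm = fm, angles = fc_forward(params, fm))
}

## Batch forward: X n x 60 x 32 -> list(phi n x 192, pred n x 3).
forward_batch <- function(p, X) {
  d <- dim(X); n <- d[1]
  M <- aperm(X, c(2, 1, 3))
  dim(M) <- c(p$win_len, n * p$n_channels)
  A <- p$conv_filters %*% M
  if (p$use_conv_bias) A <- A + p$conv_bias
  Tarr <- array(tanh(A), c(p$n_filters, n, p$n_channels))
  phi <- aperm(Tarr, c(2, 3, 1))
  dim(phi) <- c(n, p$n_filters * p$n_channels)
  pred <- phi %*% t(p$W) + rep(p$b, each = n)
  list(phi = phi, pred = pred, M = M)
}

## Analytic gradient of the batch MSE loss (mean over samples and joints)
## with respect to every parameter group.  Returns the loss too.
fpcnn_grad <- function(p, X, y) {
  d <- dim(X); n <- d[1]
  fwd <- forward_batch(p, X)
  E <- fwd$pred - y
  loss <- mean(E^2)
  g_pred <- 2 * E / length(E)
  dW <- t(g_pred) %*% fwd$phi
  db <- colSums(g_pred)
  dphi <- (g_pred %*% p$W) * (1 - fwd$phi^2)
  dAarr <- array(dphi, c(n, p$n_channels, p$n_filters))
  dAmat <- aperm(dAarr, c(3, 1, 2))
  dim(dAmat) <- c(p$n_filters, n * p$n_channels)
  dF <- dAmat %*% t(fwd$M)
  dbc <- if (p$use_conv_bias) rowSums(dAmat) else NULL
  list(conv_filters = dF, conv_bias = dbc, W = dW, b = db, loss = loss)
}

## One Adam update of state `st` for parameter group `name`.
adam_step <- function(p, g, st, name, lr, beta1, beta2, eps) {
  st$m[[name]] <- beta1 * st$m[[name]] + (1 - beta1) * g
  st$v[[name]] <- beta2 * st$v[[name]] + (1 - beta2) * g^2
  mhat <- st$m[[name]] / (1 - beta1^st$t)
  vhat <- st$v[[name]] / (1 - beta2^st$t)
  p[[name]] <- p[[name]] - lr * mhat / (sqrt(vhat) + eps)
  list(p = p, st = st)
}

## Minibatch Adam on MSE.  Returns updated params + per-epoch mean loss.
fit_adam <- function(p, X, y, epochs, learning_rate, batch_size,
                     freeze_conv = FALSE, shuffle = TRUE, seed = 1L,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (epochs < 1) stop_config("epochs must be >= 1")
  ## learning_rate 0 is allowed as an explicit no-update degenerate case
  if (learning_rate < 0) stop_config("learning_rate must be nonnegative")
  n <- dim(X)[1]
  if (n < 1) stop_data("training requires at least one sample")
  groups <- c("W", "b")
  if (!freeze_conv) {
    groups <- c("conv_filters", if (p$use_conv_bias) "conv_bias", groups)
  }
  st <- list(m = lapply(p[groups], function(z) z * 0),
             v = lapply(p[groups], function(z) z * 0), t = 0)
  history <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- if (shuffle) sample.int(n) else seq_len(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0
      for (bi in batches) {
        g <- fpcnn_grad(p, X[bi, , , drop = FALSE], y[bi, , drop = FALSE])
        if (!is.finite(g$loss))
          stop("training diverged: non-finite loss at epoch ", ep,
               " (lr = ", learning_rate, ", batch = ", batch_size, ")")
        st$t <- st$t + 1
        for (nm in groups) {
          upd <- adam_step(p, g[[nm]], st, nm, learning_rate, beta1, beta2, eps)
          p <- upd$p; st <- upd$st
        }
        ep_loss <- ep_loss + g$loss * length(bi)
      }
      history[ep] <- ep_loss / n
    }
  })
  list(params = p, history = history)
}
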