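test_that("initialization is seed-deterministic with the specified shapes", {
  p <- init_fpcnn_params(seed = 1)
  expect_identical(p, init_fpcnn_params(seed = 1))
  expect_false(identical(p$conv_filters, init_fpcnn_params(seed = 2)$conv_filters))
  expect_equal(dim(p$conv_filters), c(6, 60))
  expect_length(p$conv_bias, 6)
  expect_equal(dim(p$W), c(3, 192))
  expect_length(p$b, 3)
})

test_that("the force-pattern layer collapses time per channel without mixing", {
  p <- init_fpcnn_params(seed = 1)
  fm <- conv_forward(p, matrix(0, 60, 32))
  expect_equal(dim(fm), c(6, 32))
  expect_equal(fm, tanh(matrix(0, 6, 32)))   # zero input -> tanh(bias) = 0
  ## single all-ones filter on an all-ones channel gives tanh(60)
  p1 <- init_fpcnn_params(seed = 1, n_filters = 1)
  p1$conv_filters[] <- 1
  p1$conv_bias[] <- 0
  X <- matrix(0, 60, 32); X[, 7] <- 1
  expect_equal(conv_forward(p1, X)[1, 7], tanh(60))
  expect_equal(conv_forward(p1, X)[1, 1], 0)
  ## brute-force oracle for the full map
  set.seed(4)
  Xr <- matrix(rnorm(60 * 32), 60, 32)
  fm <- conv_forward(p, Xr)
  oracle <- matrix(0, 6, 32)
  for (j in 1:6) for (c in 1:32)
    oracle[j, c] <- tanh(sum(p$conv_filters[j, ] * Xr[, c]) + p$conv_bias[j])
  expect_equal(fm, oracle, tolerance = 1e-12)
  ## perturbing channel c changes only column c of the feature map
  Xp <- Xr; Xp[, 13] <- Xp[, 13] + 1
  diffcols <- which(colSums(abs(conv_forward(p, Xp) - fm)) > 0)
  expect_equal(diffcols, 13)
  expect_error(conv_forward(p, matrix(0, 59, 32)), class = "fpcnn_data_error")
})

test_that("the FC layer is the stated linear map over the flattened features", {
  p <- init_fpcnn_params(seed = 2)
  fm0 <- matrix(0, 6, 32)
  expect_equal(unname(fc_forward(p, fm0)), p$b)
  ## selector weight picks out one flattened coordinate
  psel <- p
  psel$W[] <- 0; psel$b[] <- 0
  psel$W[1, 37] <- 1
  set.seed(5)
  fm <- matrix(runif(192, -0.9, 0.9), 6, 32)
  expect_equal(unname(fc_forward(psel, fm)[1]), flatten_fm(fm)[37])
  ## brute-force elementwise-sum oracle
  got <- fc_forward(p, fm)
  v <- flatten_fm(fm)
  for (i in 1:3)
    expect_equal(unname(got[i]), sum(p$W[i, ] * v) + p$b[i], tolerance = 1e-12)
  ## linearity: doubling W and b doubles the output for fixed features
  pd <- p; pd$W <- 2 * p$W; pd$b <- 2 * p$b
  expect_equal(fc_forward(pd, fm), 2 * got)
})

test_that("flattening is feature-map-major and round-trips", {
  fm <- matrix(seq_len(192), 6, 32, byrow = TRUE)
  v <- flatten_fm(fm)
  expect_equal(v, as.numeric(1:192))        # fm 1 channels 1-32 first
  expect_equal(unflatten_fm(v), fm)
  set.seed(6)
  fm2 <- matrix(rnorm(192), 6, 32)
  expect_equal(unflatten_fm(flatten_fm(fm2)), fm2)
})

test_that("the full forward pass produces a 3-vector from a 192-feature map", {
  p <- init_fpcnn_params(seed = 3)
  set.seed(7)
  X <- matrix(runif(60 * 32), 60, 32)
  out <- fpcnn_forward(p, X)
  expect_length(out$angles, 3)
  expect_length(flatten_fm(out$fm), 192)
  expect_true(all(abs(out$fm) < 1))
  ## batched forward agrees with the single-window path
  Xb <- array(0, c(2, 60, 32)); Xb[1, , ] <- X; Xb[2, , ] <- X / 2
  batch <- fpcnn:::forward_batch(p, Xb)
  expect_equal(unname(batch$pred[1, ]), unname(out$angles), tolerance = 1e-12)
  expect_equal(unname(batch$pred[2, ]),
               unname(fpcnn_forward(p, X / 2)$angles), tolerance = 1e-12)
})

test_that("parameter counts follow the shape arithmetic", {
  expect_equal(count_parameters(init_fpcnn_params(seed = 1)), 945)
  expect_equal(count_parameters(init_fpcnn_params(seed = 1, n_filters = 1)), 160)
  expect_equal(count_parameters(init_fpcnn_params(seed = 9)), 945)
  expect_equal(count_parameters(init_fpcnn_params(seed = 1, conv_bias = FALSE)),
               945 - 6)
})

test_that("analytic gradients match central finite differences on small instances", {
  set.seed(8)
  p <- init_fpcnn_params(seed = 8, n_filters = 3, win_len = 7, n_channels = 5,
                         n_out = 2)
  X <- array(rnorm(6 * 7 * 5), c(6, 7, 5))
  y <- matrix(rnorm(12), 6, 2)
  g <- fpcnn:::fpcnn_grad(p, X, y)
  for (nm in c("conv_filters", "conv_bias", "W", "b")) {
    gn <- numeric_grad(p, nm, X, y)
    expect_lt(max(abs(g[[nm]] - gn) / pmax(abs(gn), 1e-6)), 1e-5)
  }
})
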