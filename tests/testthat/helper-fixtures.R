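## Shared fixtures, built in code and memoized so expensive objects are
## generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## A shortened paradigm (each motion once, 1 s hold, 0.5 s rest) for fast
## unit tests; the full-length default paradigm is used where the study
## conditions matter.
small_paradigm <- function() {
  paradigm_spec(motion_order = c("WF", "WE", "P", "S", "HG", "HO"),
                hold_duration = 1, rest_duration = 0.5)
}

small_session <- function() {
  memo("small_session",
       function() generate_session(paradigm = small_paradigm(),
                                   n_trials = 5, seed = 11))
}

small_dataset <- function() {
  memo("small_dataset", function() build_dataset(small_session()))
}

## Full study-condition fixtures (default paradigm, 10 + 5 trials) shared
## by the acceptance-level tests.
full_session <- function() {
  memo("full_session", function() generate_session(n_trials = 10, seed = 42))
}

full_dataset <- function() {
  memo("full_dataset", function() build_dataset(full_session()))
}

full_cv <- function() {
  memo("full_cv", function()
    cross_validate(full_dataset(), make_folds(1:10, mode = "initial", seed = 42),
                   seed = 42))
}

full_model <- function() {
  memo("full_model", function() fpcnn(full_dataset(), seed = 42))
}

## Central-finite-difference gradient oracle, independent of the analytic
## backward pass.
numeric_grad <- function(p, name, X, y, h = 1e-6) {
  loss_at <- function(pp) {
    fwd <- fpcnn:::forward_batch(pp, X)
    mean((fwd$pred - y)^2)
  }
  g <- p[[name]] * 0
  for (i in seq_along(p[[name]])) {
    pp <- p; pp[[name]][i] <- pp[[name]][i] + h
    pm <- p; pm[[name]][i] <- pm[[name]][i] - h
    g[i] <- (loss_at(pp) - loss_at(pm)) / (2 * h)
  }
  g
}

## Naive two-pass Pearson evaluator used as the scoring oracle.
naive_cc <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
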