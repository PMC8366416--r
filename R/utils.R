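#' @keywords internal
"_PACKAGE"

## Run code under a temporary RNG state so library functions do not clobber
## the caller's random stream.  seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_config <- function(...) {
  stop(structure(class = c("fpcnn_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("fpcnn_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_matrix <- function(x, what, ncol = NULL) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_data(what, " must be a numeric matrix")
  if (!all(is.finite(x)))
    stop_data(what, " contains non-finite values")
  if (!is.null(ncol) && ncol(x) != ncol)
    stop_data(what, " must have ", ncol, " columns, found ", ncol(x))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
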