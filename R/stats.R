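## Paired statistical comparison of models across subjects/sessions with
## multiple-comparison control.

#' Paired two-sided Student's t-test
#'
#' Thin wrapper around [stats::t.test()] on the paired differences, with
#' explicit handling of the degenerate cases: identical vectors give
#' `t = 0, p = 1`; a constant non-zero difference leaves the statistic
#' undefined and is signalled as an error.
#'
#' @param a,b Numeric vectors of equal length >= 2, paired by subject.
#' @return List with `t`, `p`, `df`, and `mean_diff`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop_data("paired vectors must have equal length")
  if (length(a) < 2) stop_data("need at least 2 pairs")
  d <- a - b
  ## constant differences (up to floating point) leave the statistic
  ## undefined -- except the all-zero case, where there is no difference
  if (stats::sd(d) <= 1e-10 * max(abs(mean(d)), 1)) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = length(d) - 1,
                                 mean_diff = 0))
    stop_data("paired differences are constant and non-zero: ",
              "t statistic undefined")
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment via [stats::p.adjust()]; input order is
#' preserved and values outside \[0, 1\] are rejected.
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted values (q-values) in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop_data("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Compare the network against each baseline across subjects
#'
#' Takes a subjects x models table of mean CC values (one row per
#' independent subject or session), runs a paired two-sided t-test of
#' the reference model against every other column, and BH-adjusts the
#' p-values.
#'
#' @param cc_table Numeric matrix or data frame, rows = subjects,
#'   named columns = models.
#' @param reference Column name of the reference model.
#' @return Data frame with columns `model`, `mean_diff`, `t`, `p`, `q`.
#' @export
compare_models <- function(cc_table, reference = "cnn") {
  cc_table <- as.matrix(cc_table)
  if (!reference %in% colnames(cc_table))
    stop_config("reference model '", reference, "' not in table")
  others <- setdiff(colnames(cc_table), reference)
  tests <- lapply(others, function(m)
    paired_t_test(cc_table[, reference], cc_table[, m]))
  out <- data.frame(model = others,
                    mean_diff = vapply(tests, `[[`, 0, "mean_diff"),
                    t = vapply(tests, `[[`, 0, "t"),
                    p = vapply(tests, `[[`, 0, "p"))
  out$q <- bh_fdr(out$p)
  out
}
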