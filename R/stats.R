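# Light inferential layer: one-sample and paired t-tests with Cohen's d,
# and multiple-comparison corrections. Linear mixed-effects models and
# post-hoc procedures used in the reference analyses for group inference
# are intentionally out of scope; this layer covers the descriptive +
# t-test reporting used throughout the package.

#' One-sample or paired t-test with effect size
#'
#' Wraps [stats::t.test()] and adds Cohen's d: for a one-sample test,
#' (mean - null) / SD of the data; for a paired test, mean(diff) / SD(diff).
#' One-sided tests report the \[lower, +Inf\] confidence-interval style.
#'
#' @param x Numeric sample.
#' @param y Optional paired partner (same length as `x`).
#' @param mu Null value (one-sample) or null difference (paired).
#' @param tail `"two"`, `"greater"` or `"less"`.
#' @param correction Correction tag recorded in the result (applied by the
#'   caller via [adjust_p()]).
#' @return A list of class `seq_test_result`: `statistic`, `df`, `p_value`,
#'   `ci`, `effect_size_d`, `tail`, `correction`, `estimate`.
#' @export
seq_t_test <- function(x, y = NULL, mu = 0, tail = c("two", "greater", "less"),
                       correction = "none") {
  tail <- match.arg(tail)
  stopifnot(is.numeric(x), length(x) >= 2L)
  alt <- switch(tail, two = "two.sided", greater = "greater", less = "less")
  if (is.null(y)) {
    if (stats::sd(x) == 0) stop("zero variance in sample", call. = FALSE)
    ht <- stats::t.test(x, mu = mu, alternative = alt)
    d <- (mean(x) - mu) / stats::sd(x)
  } else {
    stopifnot(length(y) == length(x))
    diffs <- x - y
    if (stats::sd(diffs) == 0) stop("zero variance in differences", call. = FALSE)
    ht <- stats::t.test(x, y, paired = TRUE, mu = mu, alternative = alt)
    d <- (mean(diffs) - mu) / stats::sd(diffs)
  }
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 ci = as.numeric(ht$conf.int),
                 effect_size_d = d,
                 tail = tail,
                 correction = correction,
                 estimate = unname(ht$estimate[1L])),
            class = "seq_test_result")
}

#' @export
print.seq_test_result <- function(x, ...) {
  cat(sprintf("t(%.4g) = %.4g, p = %.4g (%s-tailed), d = %.4g\n",
              x$df, x$statistic, x$p_value, x$tail, x$effect_size_d))
  invisible(x)
}

#' Multiple-comparison adjustment
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param method `"none"`, `"fdr_bh"` (Benjamini-Hochberg step-up) or
#'   `"bonferroni"` (capped at 1).
#' @return Adjusted p-values.
#' @export
adjust_p <- function(p, method = c("none", "fdr_bh", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = switch(method, none = "none", fdr_bh = "BH",
                                     bonferroni = "bonferroni"))
}

#' Tidy table of test results
#'
#' @param results Named list of `seq_test_result`s.
#' @param correction Correction applied jointly to the listed tests.
#' @return data.frame with one row per test, including adjusted p-values.
#' @export
test_results_table <- function(results, correction = c("none", "fdr_bh",
                                                       "bonferroni")) {
  correction <- match.arg(correction)
  df <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(test = nm, statistic = r$statistic, df = r$df,
               p_value = r$p_value, effect_size_d = r$effect_size_d,
               tail = r$tail)
  }))
  df$p_adjusted <- adjust_p(df$p_value, correction)
  df$correction <- correction
  df
}
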