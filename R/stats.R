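# Cohort-level hypothesis tests: one-sided threshold comparisons and the
# paired pre/post comparison. Both accept raw values or published
# summary statistics, so printed t statistics can be checked without
# raw data.

#' One-sample t-test against a threshold
#'
#' `t = (mean - threshold) / (sd / sqrt(n))`, df = n - 1, with a
#' one-sided p in the stated direction (or two-sided). The confidence
#' interval is the conventional two-sided interval on the mean at
#' `conf_level`, default 90% — the reporting convention for one-sided
#' threshold tests here.
#'
#' Supply either raw `values` or the summary triple (`mean`, `sd`,
#' `n`); the two routes agree to numerical precision.
#'
#' @param values Numeric vector of per-participant values, or NULL.
#' @param mean,sd,n Summary statistics (used when `values` is NULL).
#' @param threshold Null-hypothesis threshold.
#' @param direction `"greater"`, `"less"` or `"two_sided"`.
#' @param conf_level Two-sided CI level. Default 0.90.
#' @return A `cohort_test_result`.
#' @examples
#' one_sample_t(mean = 80.1, sd = 13.8, n = 30, threshold = 68,
#'              direction = "greater")
#' @export
one_sample_t <- function(values = NULL, mean = NULL, sd = NULL, n = NULL,
                         threshold, direction = c("greater", "less",
                                                  "two_sided"),
                         conf_level = 0.90) {
  direction <- match.arg(direction)
  if (!is.null(values)) {
    values <- values[!is.na(values)]
    n <- length(values)
    mean <- base::mean(values)
    sd <- stats::sd(values)
  }
  if (is.null(mean) || is.null(sd) || is.null(n))
    stop("supply values, or all of mean, sd, n")
  if (n < 2L) stop("n must be >= 2")
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0")
  se <- sd / sqrt(n)
  tt <- (mean - threshold) / se
  df <- n - 1L
  p <- switch(direction,
              greater = stats::pt(tt, df, lower.tail = FALSE),
              less = stats::pt(tt, df),
              two_sided = 2 * stats::pt(abs(tt), df, lower.tail = FALSE))
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  cohort_test_result(estimate = mean, t_statistic = tt, df = df,
                     p_value = p, ci = mean + c(-1, 1) * tcrit * se,
                     conf_level = conf_level, threshold = threshold,
                     direction = direction)
}

#' Paired t-test on pre/post values
#'
#' Tests the mean of the element-wise differences `post - pre` against
#' zero, reporting the mean difference with a two-sided 95% CI (the
#' reporting convention for the paired pre/post comparison).
#'
#' @param pre,post Equal-length numeric vectors (pairs with a missing
#'   member are dropped).
#' @param direction Alternative for the mean difference. Default
#'   `"two_sided"`.
#' @param conf_level CI level on the mean difference. Default 0.95.
#' @return A `cohort_test_result` whose `estimate` is the mean
#'   difference.
#' @export
paired_t <- function(pre, post, direction = c("two_sided", "greater",
                                              "less"),
                     conf_level = 0.95) {
  direction <- match.arg(direction)
  if (length(pre) != length(post)) stop("pre and post must pair up")
  ok <- !is.na(pre) & !is.na(post)
  d <- post[ok] - pre[ok]
  if (length(d) < 2L) stop("need >= 2 complete pairs")
  if (stats::sd(d) == 0) stop("differences are constant; t undefined")
  out <- one_sample_t(values = d, threshold = 0, direction = direction,
                      conf_level = conf_level)
  out$test <- "paired_t"
  out
}
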