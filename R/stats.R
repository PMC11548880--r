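# Small statistical kernel shared by the pipeline: nested-OLS F test,
# likelihood-ratio chi-square test, t procedures, and a seeded percentile
# bootstrap. Each returns a "fox_test" record so downstream tables are
# uniform.

fox_test <- function(statistic, df, p_value, estimate = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_, note = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), estimate = unname(estimate),
                 ci_low = unname(ci_low), ci_high = unname(ci_high),
                 note = note),
            class = "fox_test")
}

#' @export
print.fox_test <- function(x, ...) {
  cat("statistic =", format(x$statistic, digits = 4),
      " df =", paste(format(x$df, digits = 4), collapse = ", "),
      " p =", format.pval(x$p_value, digits = 3), "\n")
  if (!is.na(x$estimate))
    cat("estimate =", format(x$estimate, digits = 4),
        " CI [", format(x$ci_low, digits = 4), ",",
        format(x$ci_high, digits = 4), "]\n")
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' F test comparing nested least-squares models
#'
#' Classical extra-sum-of-squares F test: does the larger model (residual
#' sum of squares `rss1`, `df1` parameters) improve significantly on the
#' smaller nested model (`rss0`, `df0` parameters) fitted to the same `n`
#' observations? Used to validate a two-segment piecewise regression
#' against a single straight line.
#'
#' @param rss0,rss1 Residual sums of squares of the nested (smaller) and
#'   larger model.
#' @param df0,df1 Number of estimated mean parameters in each model.
#' @param n Number of observations.
#' @return A `fox_test` with the F statistic, (df1-df0, n-df1) degrees of
#'   freedom and its p-value.
#' @export
f_test_nested <- function(rss0, rss1, df0, df1, n) {
  stopifnot(is.numeric(rss0), is.numeric(rss1), rss0 >= 0, rss1 >= 0,
            df1 > df0, df0 >= 1)
  if (n <= df1) stop("n must exceed the larger model's parameter count")
  if (rss1 > rss0 * (1 + 1e-8) + 1e-12)
    stop("larger model has larger RSS; models are not nested as claimed")
  df_num <- df1 - df0
  df_den <- n - df1
  f <- ((rss0 - rss1) / df_num) / (rss1 / df_den)
  if (rss1 == 0) f <- if (rss0 == rss1) 0 else Inf
  p <- stats::pf(f, df_num, df_den, lower.tail = FALSE)
  fox_test(statistic = f, df = c(df_num, df_den), p_value = p)
}

#' Likelihood-ratio chi-square test
#'
#' Twice the log-likelihood gain of the larger model referred to a
#' chi-square distribution with `df_diff` degrees of freedom.
#'
#' @param loglik0,loglik1 Maximised log-likelihoods of the nested and
#'   larger model.
#' @param df_diff Difference in number of parameters (>= 1).
#' @return A `fox_test`.
#' @export
lrt_chi2 <- function(loglik0, loglik1, df_diff) {
  if (df_diff < 1) stop("df_diff must be >= 1")
  if (loglik1 < loglik0 - 1e-8)
    stop("larger model has lower log-likelihood; check nesting")
  stat <- max(0, 2 * (loglik1 - loglik0))
  p <- stats::pchisq(stat, df = df_diff, lower.tail = FALSE)
  fox_test(statistic = stat, df = df_diff, p_value = p)
}

#' Paired and two-sample t procedures
#'
#' `paired_t()` tests whether paired differences have mean zero;
#' `two_sample_t()` is the Welch two-sample test. Both wrap
#' [stats::t.test()] and return a `fox_test` with the mean difference and
#' its 95% confidence interval. A degenerate sample (zero variance) with a
#' non-zero mean difference is reported as p = 0 with an explanatory note.
#'
#' @param d Numeric vector of paired differences (x - y), length >= 3.
#' @param a,b Numeric vectors, each of length >= 3.
#' @return A `fox_test`.
#' @export
paired_t <- function(d) {
  d <- d[is.finite(d)]
  if (length(d) < 3) stop("need at least 3 paired differences")
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(fox_test(0, length(d) - 1, 1, estimate = 0, ci_low = 0, ci_high = 0))
    return(fox_test(Inf, length(d) - 1, 0, estimate = mean(d),
                    ci_low = mean(d), ci_high = mean(d),
                    note = "zero variance with non-zero mean difference"))
  }
  tt <- stats::t.test(d)
  fox_test(tt$statistic, tt$parameter, tt$p.value, estimate = mean(d),
           ci_low = tt$conf.int[1], ci_high = tt$conf.int[2])
}

#' @rdname paired_t
#' @export
two_sample_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) stop("need at least 3 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    dm <- mean(a) - mean(b)
    if (dm == 0)
      return(fox_test(0, length(a) + length(b) - 2, 1, estimate = 0,
                      ci_low = 0, ci_high = 0))
    return(fox_test(Inf, length(a) + length(b) - 2, 0, estimate = dm,
                    ci_low = dm, ci_high = dm,
                    note = "zero variance with non-zero mean difference"))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  fox_test(tt$statistic, tt$parameter, tt$p.value, estimate = mean(a) - mean(b),
           ci_low = tt$conf.int[1], ci_high = tt$conf.int[2])
}

#' Seeded percentile bootstrap confidence interval
#'
#' Resamples `values` with replacement `n_boot` times, applies `statistic`
#' to each resample and returns the percentile interval. The RNG state of
#' the caller is left untouched; results are reproducible for a fixed
#' `seed`.
#'
#' @param values Numeric vector.
#' @param statistic Function mapping a numeric vector to a scalar.
#' @param n_boot Number of bootstrap resamples (>= 200).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return A list with `estimate`, `ci_low`, `ci_high`, `n_boot`.
#' @export
bootstrap_ci <- function(values, statistic = mean, n_boot = 1000, seed = 1,
                         level = 0.95) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 values")
  if (n_boot < 200) stop("n_boot must be >= 200")
  reps <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      statistic(values[sample.int(length(values), replace = TRUE)])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(estimate = statistic(values), ci_low = qs[1], ci_high = qs[2],
       n_boot = n_boot)
}

# Run `expr` under a temporary RNG state so library users' streams are not
# disturbed.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
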