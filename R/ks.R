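# Empirical-CDF and two-sample Kolmogorov-Smirnov machinery (the detector's
# decision statistic), plus the one-way ANOVA used for hyperparameter
# sensitivity. Implemented from first principles; base R supplies only the
# F-distribution tail.

#' Evaluate an empirical CDF
#'
#' Right-continuous step function: the fraction of sample values `<= x`.
#'
#' @param sample Non-empty numeric vector (need not be pre-sorted).
#' @param x Evaluation points.
#' @return Numeric vector of ECDF values in \[0, 1\].
#' @export
ecdf_eval <- function(sample, x) {
  if (length(sample) == 0L)
    abort_field("sample", "must be non-empty")
  if (anyNA(sample) || any(!is.finite(sample)))
    abort_field("sample", "must be finite")
  findInterval(x, sort(sample)) / length(sample)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic D is the supremum over the real line of the absolute
#' difference between the two empirical CDFs. Both ECDFs are piecewise
#' constant with jumps only at pooled sample values, so the supremum is
#' attained at (the right limit of) one of the pooled unique values; ties are
#' therefore handled exactly. The p-value uses the asymptotic Kolmogorov
#' distribution \eqn{Q(\lambda) = 2 \sum_{k \ge 1} (-1)^{k-1} e^{-2k^2\lambda^2}}
#' at \eqn{\lambda = \sqrt{n_1 n_2 / (n_1 + n_2)}\, D}, with the series
#' truncated once a term falls below 1e-12 and the result clamped to
#' \[0, 1\]. No small-sample continuity correction is applied; the intended
#' inputs are pixel samples with n in the thousands.
#'
#' @param a,b Non-empty numeric vectors.
#' @return An object of class `ks_test_result`: list with `d_statistic`,
#'   `n1`, `n2`, `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L) abort_field("a", "must be non-empty")
  if (length(b) == 0L) abort_field("b", "must be non-empty")
  if (anyNA(a) || any(!is.finite(a))) abort_field("a", "must be finite")
  if (anyNA(b) || any(!is.finite(b))) abort_field("b", "must be finite")
  n1 <- length(a)
  n2 <- length(b)
  pts <- sort(unique(c(a, b)))
  d <- max(abs(ecdf_eval(a, pts) - ecdf_eval(b, pts)))
  structure(list(d_statistic = d, n1 = n1, n2 = n2,
                 p_value = ks_asymptotic_p(d, n1, n2)),
            class = "ks_test_result")
}

# Asymptotic two-sided Kolmogorov tail probability.
ks_asymptotic_p <- function(d, n1, n2) {
  if (d <= 0) return(1)
  lambda <- sqrt(n1 * n2 / (n1 + n2)) * d
  total <- 0
  for (k in 1:200) {
    term <- 2 * (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
    total <- total + term
    if (abs(term) < 1e-12) break
  }
  min(max(total, 0), 1)
}

#' @export
print.ks_test_result <- function(x, ...) {
  cat(sprintf("Two-sample KS test: D = %.6g (n1 = %d, n2 = %d), p = %.6g\n",
              x$d_statistic, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical between/within sum-of-squares decomposition. Degenerate cases:
#' all values identical across all groups gives F = 0, p = 1; zero
#' within-group variance with between-group separation gives F = Inf, p = 0.
#'
#' @param groups List of at least two numeric vectors, each non-empty, with
#'   at least one group of size >= 2.
#' @return An object of class `anova_result`: list with `f_statistic`,
#'   `df_between`, `df_within`, `p_value`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    abort_field("groups", "must be a list of at least two groups")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 1L))
    abort_field("groups", "every group must be non-empty")
  if (!any(sizes >= 2L))
    abort_field("groups", "at least one group needs two or more values")
  vals <- unlist(groups, use.names = FALSE)
  if (anyNA(vals) || any(!is.finite(vals)))
    abort_field("groups", "values must be finite")
  n <- length(vals)
  g <- length(groups)
  grand <- mean(vals)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum(vapply(seq_len(g),
                          function(i) sum((groups[[i]] - means[i])^2),
                          numeric(1)))
  df_b <- g - 1L
  df_w <- n - g
  if (ss_between <= 0 && ss_within <= 0) {
    f <- 0
    p <- 1
  } else if (ss_within <= 0) {
    f <- Inf
    p <- 0
  } else {
    f <- (ss_between / df_b) / (ss_within / df_w)
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  structure(list(f_statistic = f, df_between = df_b, df_within = df_w,
                 p_value = p),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.6g, p = %.6g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}
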