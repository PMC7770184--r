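#' @title Test-result container
#' @description Uniform return value of the test battery: statistic,
#'   statistic kind (`"t"`, `"F"`, `"chisq"`, `"r"`), degrees of
#'   freedom, two-sided p, optional corrected p, and per-group sizes.
#' @param statistic Statistic value.
#' @param kind Statistic kind.
#' @param df Degrees of freedom (scalar or length-2).
#' @param p Two-sided p-value.
#' @param n Sample size(s).
#' @param estimate Optional effect estimate (mean difference, r, ...).
#' @param degenerate TRUE when the input was degenerate (e.g. zero
#'   variance) and the p-value is a limit, not a t-distribution tail.
#' @return Object of class `fc_test`.
#' @export
fc_test <- function(statistic, kind, df, p, n, estimate = NA_real_,
                    degenerate = FALSE) {
  stopifnot(p >= 0, p <= 1)
  structure(list(statistic = unname(statistic), kind = kind,
                 df = unname(df), p = unname(p), p_corrected = NA_real_,
                 n = unname(n), estimate = unname(estimate),
                 degenerate = degenerate),
            class = "fc_test")
}

#' @export
print.fc_test <- function(x, ...) {
  cat(sprintf("%s = %.4g, df = %s, p = %.4g%s\n", x$kind, x$statistic,
              paste(signif(x$df, 4), collapse = ","), x$p,
              if (!is.na(x$p_corrected)) sprintf(" (corrected %.4g)", x$p_corrected) else ""))
  invisible(x)
}

#' Two-sample t-test
#'
#' Two-sided comparison of two independent samples. The default is the
#' Welch unequal-variance form; `variant = "pooled"` gives the classical
#' equal-variance test. Degenerate inputs (both samples constant) are
#' resolved to t = 0, p = 1 when the means agree and p = 0 otherwise,
#' with the `degenerate` flag set.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param variant `"welch"` or `"pooled"`.
#' @return An [fc_test()] with kind `"t"`.
#' @export
two_sample_t <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(fc_test(if (same) 0 else sign(mean(x) - mean(y)) * Inf, "t",
                   length(x) + length(y) - 2L, if (same) 1 else 0,
                   c(length(x), length(y)), mean(x) - mean(y),
                   degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  fc_test(ht$statistic, "t", ht$parameter, ht$p.value,
          c(length(x), length(y)), mean(x) - mean(y))
}

#' Two-sample t-test from summary statistics
#'
#' Identical contract to [two_sample_t()] but computed from the
#' sufficient statistics (n, mean, SD) of each sample — the form needed
#' to recompute published demographic comparisons from a summary table.
#'
#' @param n1,mean1,sd1 First sample size, mean, standard deviation.
#' @param n2,mean2,sd2 Second sample size, mean, standard deviation.
#' @param variant `"welch"` or `"pooled"`.
#' @return An [fc_test()] with kind `"t"`.
#' @examples
#' # age row of a typical demographics table
#' two_sample_t_from_summary(23, 41.96, 12.7, 24, 40.17, 10.6)
#' @export
two_sample_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                                      variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2L, n2 >= 2L, sd1 >= 0, sd2 >= 0)
  diff <- mean1 - mean2
  if (sd1 == 0 && sd2 == 0) {
    same <- isTRUE(all.equal(mean1, mean2))
    return(fc_test(if (same) 0 else sign(diff) * Inf, "t", n1 + n2 - 2L,
                   if (same) 1 else 0, c(n1, n2), diff, degenerate = TRUE))
  }
  if (variant == "welch") {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tval <- diff / se
  fc_test(tval, "t", df, 2 * stats::pt(-abs(tval), df), c(n1, n2), diff)
}

#' Paired t-test
#'
#' One-sample t-test on post - pre differences, aligned by subject id
#' when a pairing is given. All-equal nonzero differences (zero
#' variance) are flagged degenerate with p = 0.
#'
#' @param pre,post Numeric samples of equal length.
#' @param pairing Optional two-column data frame or named vectors: when
#'   `pre` and `post` carry subject names, `post` is reordered to match
#'   `pre` by name.
#' @return An [fc_test()] with kind `"t"`, df n - 1.
#' @export
paired_t <- function(pre, post, pairing = NULL) {
  if (!is.null(names(pre)) && !is.null(names(post))) {
    if (!setequal(names(pre), names(post)))
      stop("pre/post subject ids do not match: missing ",
           paste(setdiff(names(pre), names(post)), collapse = ", "))
    post <- post[names(pre)]
  } else if (length(pre) != length(post)) {
    stop("pre and post must have equal length (paired by position)")
  }
  d <- post - pre
  n <- length(d)
  stopifnot(n >= 2L)
  if (stats::sd(d) == 0) {
    zero <- isTRUE(all.equal(mean(d), 0))
    return(fc_test(if (zero) 0 else sign(mean(d)) * Inf, "t", n - 1L,
                   if (zero) 1 else 0, n, mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(d)
  fc_test(ht$statistic, "t", ht$parameter, ht$p.value, n, mean(d))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: F with (k - 1, N - k) degrees
#' of freedom.
#'
#' @param groups List of >= 2 numeric samples, each of length >= 2.
#' @return An [fc_test()] with kind `"F"`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::sd(values) == 0)
    return(fc_test(0, "F", c(length(groups) - 1L,
                             length(values) - length(groups)), 1,
                   lengths(groups), degenerate = TRUE))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  fc_test(ht$statistic, "F", ht$parameter, ht$p.value, lengths(groups))
}

#' Pearson chi-squared test on a contingency table
#'
#' Standard Pearson chi-squared without continuity correction;
#' degrees of freedom (rows - 1)(cols - 1).
#'
#' @param contingency Matrix of non-negative integer counts with
#'   positive margins.
#' @return An [fc_test()] with kind `"chisq"`.
#' @export
chi_square_test <- function(contingency) {
  tab <- as.matrix(contingency)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency margins must be positive")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  fc_test(ht$statistic, "chisq", ht$parameter, ht$p.value, sum(tab))
}

#' Bonferroni adjustment
#'
#' p_adj = min(1, m * p); `m` defaults to the number of p-values
#' (the family size).
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param m Family size; defaults to `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE), m >= 1)
  pmin(1, p_values * m)
}

#' Pearson correlation with t-based p
#'
#' Sample correlation r with the two-sided p-value from
#' t = r * sqrt(n - 2) / sqrt(1 - r^2) on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length n >= 3, all finite.
#' @return An [fc_test()] with kind `"r"`; `estimate` is r.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  ht <- stats::cor.test(x, y, method = "pearson")
  fc_test(ht$statistic, "r", ht$parameter, ht$p.value, length(x),
          estimate = unname(ht$estimate))
}

#' Two-sided p-value of a reported correlation coefficient
#'
#' The t-transform p used for every correlation in the analysis:
#' t = r * sqrt(n - 2) / sqrt(1 - r^2), p = 2 P(T_{n-2} > |t|). Useful
#' for checking printed (r, p) pairs.
#'
#' @param r Correlation in (-1, 1).
#' @param n Number of pairs, >= 3.
#' @return Two-sided p-value.
#' @examples
#' p_from_r(-0.54, 24)  # ~0.0065
#' @export
p_from_r <- function(r, n) {
  stopifnot(abs(r) < 1, n >= 3L)
  tval <- abs(r) * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(tval, n - 2, lower.tail = FALSE)
}
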