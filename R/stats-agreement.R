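# Agreement and clinical-association statistics for DTUEMP metrics.

label_correlation <- function(r) {
  a <- abs(r)
  if (a < 0.35) "weak" else if (a < 0.68) "moderate" else "strong"
}

label_icc <- function(icc) {
  if (icc < 0.50) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc < 0.90) "good"
  else "excellent"
}

label_mape <- function(m) {
  if (m < 5) "high" else if (m <= 25) "moderate" else "unacceptable"
}

new_association <- function(statistic, p_value, kind, n, df, label) {
  structure(list(statistic = statistic, p_value = p_value, kind = kind,
                 n = n, df = df, label = label), class = "association")
}

#' @export
print.association <- function(x, ...) {
  cat(sprintf("%s: %.4f (%s), p = %.4g, n = %d\n",
              x$kind, x$statistic, x$label, x$p_value, x$n))
  invisible(x)
}

#' Spearman rank correlation between two measurement methods
#'
#' Pearson correlation of mid-ranks (ties receive their average rank),
#' with a two-sided p-value from the t approximation on n - 2 degrees of
#' freedom. The qualitative label follows the conventional cut-offs for
#' method-agreement work: below 0.35 weak, 0.35-0.67 moderate, 0.68 and
#' above strong.
#'
#' @param method_a,method_b equal-length numeric vectors (n >= 3).
#' @return An `"association"` object: `statistic`, `p_value`,
#'   `kind = "spearman"`, `n`, `df`, `label`.
#' @export
spearman_assoc <- function(method_a, method_b) {
  check_paired(method_a, method_b)
  n <- length(method_a)
  ra <- rank(method_a, ties.method = "average")
  rb <- rank(method_b, ties.method = "average")
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    stop_dtuemp("Spearman correlation undefined: a ranking has zero variance")
  }
  rho <- stats::cor(ra, rb)
  df <- n - 2L
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt(df / (1 - rho^2))
    2 * stats::pt(-abs(tval), df)
  }
  new_association(rho, p, "spearman", n, df, label_correlation(rho))
}

check_paired <- function(a, b, min_n = 3L) {
  if (length(a) != length(b)) stop_dtuemp("inputs must have equal length")
  if (length(a) < min_n) stop_dtuemp("need at least %d pairs", min_n)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop_dtuemp("inputs must be finite")
  }
}

#' Intraclass correlation between two measurement methods
#'
#' ICC(2,1): two-way random effects, absolute agreement, single measures
#' — the form for asking whether two measurement systems produce
#' interchangeable values, where a systematic offset between systems
#' counts against agreement. Computed from the two-way ANOVA mean squares
#' with k = 2 raters:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with the p-value from the F test of `MSR / MSE` on
#' (n - 1, (n - 1)(k - 1)) degrees of freedom. Labels: below 0.50 poor,
#' 0.50-0.75 moderate, 0.75-0.90 good, above 0.90 excellent.
#'
#' @inheritParams spearman_assoc
#' @return An `"association"` object with `kind = "icc"`.
#' @export
icc_agreement <- function(method_a, method_b) {
  check_paired(method_a, method_b)
  n <- length(method_a)
  k <- 2L
  Y <- cbind(method_a, method_b)
  row_means <- rowMeans(Y)
  col_means <- colMeans(Y)
  grand <- mean(Y)
  if (stats::var(row_means) == 0) {
    stop_dtuemp("ICC undefined: no between-subject variance")
  }
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((Y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  fval <- msr / mse
  p <- stats::pf(fval, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  new_association(icc, p, "icc", n, n - 1L, label_icc(icc))
}

#' Normality diagnostics for an outcome variable
#'
#' Adjusted Fisher-Pearson skewness and excess kurtosis (the bias-adjusted
#' estimators standard statistical software reports) with a Shapiro-Wilk
#' decision at the 0.05 level.
#'
#' @param v numeric vector, n >= 8, non-constant.
#' @return A list: `skewness`, `kurtosis` (excess), `shapiro_p`,
#'   `is_normal`.
#' @export
normality_check <- function(v) {
  if (length(v) < 8L) stop_dtuemp("need at least 8 observations")
  if (any(!is.finite(v))) stop_dtuemp("input must be finite")
  if (stats::sd(v) == 0) stop_dtuemp("normality check undefined for constant input")
  sk <- e1071::skewness(v, type = 2)
  ku <- e1071::kurtosis(v, type = 2)
  sw <- stats::shapiro.test(v)
  list(skewness = sk, kurtosis = ku, shapiro_p = sw$p.value,
       is_normal = sw$p.value >= 0.05)
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal scores through their fractional ranks using the
#' Blom offset: `qnorm((r - 3/8) / (n + 1/4))` with mid-ranks for ties.
#' The transform is monotone, so it preserves the ordering (and hence all
#' rank correlations) while forcing an approximately normal marginal —
#' the standard preparation of a skewed outcome (such as TUG time) for
#' analyses that assume normality.
#'
#' @param v numeric vector, n >= 3.
#' @return Numeric vector of normal scores, same length and order.
#' @export
rank_inverse_normal <- function(v) {
  if (length(v) < 3L) stop_dtuemp("need at least 3 observations")
  if (any(!is.finite(v))) stop_dtuemp("input must be finite")
  r <- rank(v, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
}

#' Partial correlation controlling for covariates
#'
#' Correlation between a metric and an outcome after removing the linear
#' effect of covariates (age, sex, BMI in the intended use): both
#' variables are regressed on an intercept plus the covariates and the
#' Pearson correlation of the residuals is returned, with a two-sided
#' p-value from the t distribution on n - 2 - k degrees of freedom.
#'
#' When `transform_y = "auto"` (default) the outcome is passed through
#' [rank_inverse_normal()] first if it fails a Shapiro-Wilk test at 0.05
#' — the handling a skewed mobility score receives; `"never"` and
#' `"always"` force the choice.
#'
#' @param x metric values.
#' @param y outcome values.
#' @param covariates data frame or matrix of covariate columns (may have
#'   zero columns, in which case the plain Pearson correlation results).
#' @param transform_y `"auto"`, `"never"` or `"always"`.
#' @return An `"association"` object with `kind = "partial"` and a
#'   `transformed` flag.
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                transform_y = c("auto", "never", "always")) {
  transform_y <- match.arg(transform_y)
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = length(x), ncol = 0)
  }
  Z <- as.matrix(covariates)
  storage.mode(Z) <- "double"
  n <- length(x)
  k <- ncol(Z)
  check_paired(x, y, min_n = 3L)
  if (nrow(Z) != n) stop_dtuemp("covariates must have one row per subject")
  if (n <= k + 2L) stop_dtuemp("need n > k + 2 observations (n=%d, k=%d)", n, k)

  transformed <- FALSE
  if (transform_y == "always" ||
      (transform_y == "auto" && stats::shapiro.test(y)$p.value < 0.05)) {
    y <- rank_inverse_normal(y)
    transformed <- TRUE
  }

  if (k == 0L) {
    rx <- x - mean(x)
    ry <- y - mean(y)
  } else {
    X <- cbind(1, Z)
    if (qr(X)$rank < ncol(X)) {
      stop_dtuemp("covariate matrix is rank deficient")
    }
    rx <- stats::lsfit(Z, x, intercept = TRUE)$residuals
    ry <- stats::lsfit(Z, y, intercept = TRUE)$residuals
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop_dtuemp("partial correlation undefined: residuals have zero variance")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tval), df)
  }
  out <- new_association(r, p, "partial", n, df, label_correlation(r))
  out$transformed <- transformed
  out
}
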