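#' Pearson correlation with two-tailed significance
#'
#' Product-moment correlation with the two-tailed p-value from the exact
#' t-transform `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom,
#' and the significance star used in clinical correlation tables
#' (`*` for p < 0.05, `**` for p < 0.001, otherwise `ns`).
#'
#' @param x,y Numeric vectors of equal length, n >= 3, both non-constant.
#' @return A `correlation_result`: list with `r`, `p_two_tailed`, `n`, `star`.
#' @examples
#' pearson_test(1:10, (1:10) + rnorm(10))
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y))
    stop("invalid input: `x` and `y` differ in length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop("insufficient data: need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant series", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate),
                 p_two_tailed = ct$p.value,
                 n = n,
                 star = significance_star(ct$p.value)),
            class = "correlation_result")
}

significance_star <- function(p) {
  ifelse(p < 0.001, "**", ifelse(p < 0.05, "*", "ns"))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d, two-tailed p = %.4g) %s\n",
              x$r, x$n, x$p_two_tailed, x$star))
  invisible(x)
}

#' Pairwise Pearson correlation matrix with significance stars
#'
#' Symmetric correlation matrix over a set of named variables, with
#' two-tailed p-values and the star coding of clinical correlation tables.
#' Pairs are complete-case pairwise; the diagonal is marked undefined.
#'
#' @param data data.frame (or named list) of numeric variables, >= 2 columns.
#' @return A `correlation_matrix`: list of matrices `r`, `p`, `n` and a
#'   character matrix `star` (diagonal `"----"`).
#' @export
correlation_matrix <- function(data) {
  data <- as.data.frame(data)
  vars <- names(data)
  k <- length(vars)
  if (k < 2L) stop("need at least two variables", call. = FALSE)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  star <- matrix("----", k, k, dimnames = list(vars, vars))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      res <- pearson_test(data[[i]], data[[j]])
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p_two_tailed
      n[i, j] <- n[j, i] <- res$n
      star[i, j] <- star[j, i] <- res$star
    }
  }
  structure(list(r = r, p = p, n = n, star = star),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat("Pearson correlations (lower: r, stars: * p<0.05, ** p<0.001)\n")
  disp <- x$star
  lower <- lower.tri(disp)
  disp[lower] <- sprintf(paste0("%.", digits, "f%s"),
                         x$r[lower],
                         ifelse(x$star[lower] == "ns", "", x$star[lower]))
  print(as.data.frame(disp), right = TRUE)
  invisible(x)
}

#' Simple linear regression fit
#'
#' OLS fit of `y` on `x` with the slope's two-tailed p-value (identical to
#' the Pearson p for simple regression) and the correlation coefficient.
#'
#' @param x,y Numeric vectors, n >= 3, `x` non-constant.
#' @return A `regression_fit`: list with `slope`, `intercept`, `r`,
#'   `p_slope`, `n`.
#' @export
ols_fit <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("insufficient data: need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("invalid input: `x` is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = sign(unname(stats::coef(fit)[2])) * sqrt(sm$r.squared),
                 p_slope = unname(sm$coefficients[2, 4]),
                 n = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS: y = %.4g + %.4g x (r = %.4f, slope p = %.4g, n = %d)\n",
              x$intercept, x$slope, x$r, x$p_slope, x$n))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Agreement between two paired measurement series via the differences
#' `d = a - b` plotted against the pairwise means: mean bias, SD of the
#' differences, 95% limits of agreement (bias -/+ 1.96 SD), and a
#' proportional-bias test (two-tailed OLS slope of the differences on the
#' means).
#'
#' @param a,b Paired numeric vectors, n >= 3.
#' @return A `bland_altman_result`: list with `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `proportional_slope`, `proportional_p`, `n`.
#' @export
bland_altman <- function(a, b) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L)
    stop("insufficient data: need at least 3 complete pairs", call. = FALSE)
  d <- a - b
  m <- (a + b) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  if (stats::sd(m) > 0 && sd_diff > 0) {
    fit <- summary(stats::lm(d ~ m))
    prop_slope <- unname(fit$coefficients[2, 1])
    prop_p <- unname(fit$coefficients[2, 4])
  } else {
    prop_slope <- 0
    prop_p <- NA_real_
  }
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 proportional_slope = prop_slope,
                 proportional_p = prop_p, n = n),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4g (SD %.4g), LoA [%.4g, %.4g], n = %d\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$n))
  cat(sprintf("  proportional bias: slope %.4g (p = %.4g)\n",
              x$proportional_slope, x$proportional_p))
  invisible(x)
}

#' Paired two-tailed t-test
#'
#' Standard paired t-test on `a - b` with `n - 1` degrees of freedom.
#' Zero-variance differences are signalled as a degenerate test rather than
#' returned as NaN.
#'
#' @param a,b Paired numeric vectors, n >= 2, differences non-constant.
#' @return A `paired_test_result`: list with `t_statistic`, `p_two_tailed`,
#'   `mean_difference`, `n`.
#' @export
paired_t <- function(a, b) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2L)
    stop("insufficient data: need at least 2 complete pairs", call. = FALSE)
  if (stats::sd(a - b) == 0)
    stop("degenerate test: paired differences have zero variance", call. = FALSE)
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  structure(list(t_statistic = unname(tt$statistic),
                 p_two_tailed = tt$p.value,
                 mean_difference = unname(tt$estimate),
                 n = n),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("Paired t: mean diff %.4g, t = %.4g, two-tailed p = %.4g, n = %d\n",
              x$mean_difference, x$t_statistic, x$p_two_tailed, x$n))
  invisible(x)
}
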