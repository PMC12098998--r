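#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation for test-retest reliability, from the two-way ANOVA
#' decomposition:
#' `ICC = (MSR - MSE) / (MSR + (k - 1) MSE + (k / n)(MSC - MSE))`,
#' with `MSR` the between-subject, `MSC` the between-occasion and `MSE`
#' the residual mean squares. The confidence interval follows the F-based
#' construction for the absolute-agreement single-measure case.
#'
#' @param ratings Numeric matrix or data frame, one row per subject and
#'   one column per measurement occasion; no missing cells.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `icc_result`: `icc`, `lower`, `upper`, mean
#'   squares, and the design size.
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4, 5, 6), b = c(1.1, 2.2, 2.9, 4.2, 4.8, 6.1))
#' icc21(m)
icc21 <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  if (any(is.na(x))) stop("Missing cells are not supported.")
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3 || k < 2) stop("Need at least 3 subjects and 2 occasions.")

  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols

  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0 || (msr == 0 && mse == 0)) {
    warning("Degenerate variance decomposition; ICC undefined, returning 0.")
    icc <- 0
  } else {
    icc <- (msr - mse) / denom
  }

  # F-based CI for the absolute-agreement single-measure ICC.
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  alpha <- 1 - conf_level
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  structure(list(icc = icc, lower = lower, upper = upper,
                 conf_level = conf_level, msr = msr, msc = msc, mse = mse,
                 n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f, %d%% CI [%.3f, %.3f] (n = %d, k = %d)\n",
              x$icc, round(100 * x$conf_level), x$lower, x$upper, x$n, x$k))
  invisible(x)
}

#' Spearman correlation with permutation test
#'
#' Spearman's rank correlation (average ranks for ties) with a two-sided
#' permutation p-value: `y` is permuted `n_perm` times and
#' `p = (1 + #\{|r_perm| >= |r_obs|\}) / (1 + n_perm)`. The add-one
#' correction keeps p strictly positive regardless of the number of
#' permutations.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Seed for the permutations.
#' @return List with `estimate` (rho) and `p_value`.
#' @export
#' @examples
#' spearman_perm(1:10, (1:10)^2, n_perm = 999, seed = 1)
spearman_perm <- function(x, y, n_perm = 10000, seed = 1) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length.")
  if (length(x) < 3) stop("Need at least 3 observations.")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("Zero variance in ranks; the correlation is undefined.")
  }
  r_obs <- stats::cor(rx, ry)
  r_perm <- with_local_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) stats::cor(rx, sample(ry)), numeric(1))
  })
  p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (1 + n_perm)
  list(estimate = r_obs, p_value = p, n_perm = n_perm)
}
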