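#' Lin's concordance correlation coefficient
#'
#' Agreement between paired measurements, combining Pearson correlation
#' (precision) with deviation from the identity line (accuracy):
#' `ccc = 2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with biased
#' (1/n) moment estimators. The confidence interval applies the Fisher
#' z-transform to the estimate with Lin's asymptotic variance and
#' back-transforms. Used here to compare cell-type proportion estimates
#' (e.g. model-derived epithelial percentages against pathologist deciles).
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, finite.
#' @param ci_level Confidence level, default 0.95.
#' @return An object of class `ccc_result`: list with `estimate`, `ci_low`,
#'   `ci_high`, `n` and `ci_level`. `ci_low <= estimate <= ci_high` and
#'   `|estimate| <= 1` always hold.
#' @references Lin, L. I-K. (1989) A concordance correlation coefficient to
#'   evaluate reproducibility. Biometrics 45, 255-268.
#' @export
lin_ccc <- function(x, y, ci_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  mx <- mean(x)
  my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) {
    stop("concordance undefined: both vectors constant with equal means")
  }
  rho_c <- 2 * sxy / denom

  # Fisher z CI with Lin's asymptotic variance of the z-transformed estimate
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else 0
  u <- (mx - my) / (sx2 * sy2)^(1 / 4)
  ci_low <- ci_high <- rho_c
  if (n > 2L && abs(rho_c) < 1 && r != 0) {
    var_z <- (1 / (n - 2)) *
      ((1 - r^2) * rho_c^2 / ((1 - rho_c^2) * r^2) +
       2 * rho_c^3 * (1 - rho_c) * u^2 / (r * (1 - rho_c^2)^2) -
       rho_c^4 * u^4 / (2 * r^2 * (1 - rho_c^2)^2))
    var_z <- max(var_z, 0)
    z <- atanh(rho_c)
    half <- stats::qnorm(1 - (1 - ci_level) / 2) * sqrt(var_z)
    ci_low <- tanh(z - half)
    ci_high <- tanh(z + half)
  }
  structure(list(estimate = rho_c, ci_low = min(ci_low, rho_c),
                 ci_high = max(ci_high, rho_c), n = n, ci_level = ci_level),
            class = "ccc_result")
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf("Concordance correlation coefficient: %.4f [%.4f, %.4f] (n = %d, %g%% CI)\n",
              x$estimate, x$ci_low, x$ci_high, x$n, 100 * x$ci_level))
  invisible(x)
}

#' Two-sample t-test with explicit degenerate-variance handling
#'
#' Thin wrapper around [stats::t.test()] (Welch by default, pooled with
#' `equal_var = TRUE`) used to compare mean cell-type proportion estimates
#' between methods or strata. Zero-variance corner cases that `t.test()`
#' refuses are resolved by convention: both samples constant and equal in
#' mean gives `t = 0, p = 1`; constant samples with different means give an
#' infinite t flagged as degenerate with `p = 0`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param equal_var Pool the variances (classic Student test)? Default
#'   `FALSE` (Welch).
#' @return List with `t`, `p_value`, `df` (`NA` in degenerate cases),
#'   `mean_x`, `mean_y` and logical `degenerate`.
#' @export
two_sample_t <- function(x, y, equal_var = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, p_value = 1, df = NA_real_, mean_x = mean(x),
                  mean_y = mean(y), degenerate = TRUE))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, p_value = 0,
                df = NA_real_, mean_x = mean(x), mean_y = mean(y),
                degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = equal_var)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), mean_x = mean(x), mean_y = mean(y),
       degenerate = FALSE)
}
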