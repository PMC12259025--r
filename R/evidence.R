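#' Generative specification for a pair of correlated Gaussian sources
#'
#' Describes the stimulus-generating process for one trial: each observation
#' is a pair \eqn{(x_1, x_2)} drawn from a bivariate Gaussian with equal
#' means \eqn{\pm\mu_g} (sign by source), equal standard deviations
#' \eqn{\sigma_g}, and pairwise correlation \eqn{\rho}. `mu_0` is the
#' zero-correlation reference mean used to equate expected evidence strength
#' across correlation conditions via \eqn{\mu_\rho = \mu_0\sqrt{1+\rho}}.
#'
#' @param mu_g per-coordinate mean magnitude (window-height units).
#' @param sigma_g per-coordinate standard deviation; must be positive.
#' @param rho pairwise correlation, in (-1, 1).
#' @param mu_0 zero-correlation reference mean (defaults to
#'   `mu_g / sqrt(1 + rho)`, i.e. assumes `mu_g` is calibrated).
#' @return An object of class `generative_spec`.
#' @examples
#' spec <- generative_spec(mu_g = 0.1, sigma_g = 0.1, rho = 0.6)
#' loglr_pair(0.1, 0.06, spec)
#' @export
generative_spec <- function(mu_g, sigma_g = 0.1, rho = 0, mu_0 = NULL) {
  stopifnot(is.numeric(mu_g), length(mu_g) == 1L, is.finite(mu_g))
  if (!is.numeric(sigma_g) || sigma_g <= 0) stop("sigma_g must be positive")
  check_rho(rho)
  if (is.null(mu_0)) mu_0 <- mu_g / sqrt(1 + rho)
  structure(list(mu_g = mu_g, sigma_g = sigma_g, rho = rho, mu_0 = mu_0),
            class = "generative_spec")
}

check_rho <- function(rho, open_lower_only = FALSE) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho))
    stop("rho must be a single finite number")
  if (open_lower_only) {
    if (rho <= -1) stop("invalid correlation: rho must be > -1, got ", rho)
  } else if (abs(rho) >= 1) {
    stop("invalid correlation: |rho| must be < 1, got ", rho)
  }
  invisible(rho)
}

#' Log-likelihood ratio of a correlated observation pair
#'
#' The weight of evidence carried by one pair \eqn{(x_1, x_2)} for the
#' positive-mean source over the negative-mean source:
#' \deqn{\mathrm{logLR} = \frac{2\mu_g}{\sigma_g^2 (1+\rho)} (x_1 + x_2).}
#' The pair enters only through its sum, so the sum of pairs is a sufficient
#' statistic; logLRs add across independent pairs.
#'
#' @param x1,x2 observation coordinates (vectorized).
#' @param spec a [generative_spec()].
#' @return Numeric vector of log-likelihood ratios (natural-log units).
#' @export
loglr_pair <- function(x1, x2, spec) {
  stopifnot(inherits(spec, "generative_spec"))
  check_rho(spec$rho)
  2 * spec$mu_g / (spec$sigma_g^2 * (1 + spec$rho)) * (x1 + x2)
}

#' Expected evidence strength of a single observation pair
#'
#' The expected logLR of one pair drawn from the positive source,
#' \eqn{4\mu_g^2 / (\sigma_g^2 (1+\rho))}. This is the quantity held
#' constant across correlation conditions by the mean calibration
#' [calibrated_mean()].
#'
#' @inheritParams loglr_pair
#' @return A single non-negative number (natural-log units).
#' @export
expected_evidence_strength <- function(spec) {
  stopifnot(inherits(spec, "generative_spec"))
  check_rho(spec$rho)
  4 * spec$mu_g^2 / (spec$sigma_g^2 * (1 + spec$rho))
}

#' Correlation-calibrated generative mean
#'
#' The mean \eqn{\mu_\rho = \mu_0 \sqrt{1+\rho}} that equates the expected
#' evidence strength of a condition with correlation `rho` to that of the
#' zero-correlation condition with mean `mu_0`.
#'
#' @param mu_0 zero-correlation generative mean; must be positive.
#' @param rho pairwise correlation, > -1.
#' @return Calibrated mean (window-height units).
#' @export
calibrated_mean <- function(mu_0, rho) {
  if (!is.numeric(mu_0) || any(mu_0 <= 0)) stop("mu_0 must be positive")
  check_rho(rho, open_lower_only = TRUE)
  mu_0 * sqrt(1 + rho)
}

#' Normative correlation-dependent evidence scale factor
#'
#' The factor \eqn{1/(1+\rho)} by which the sum of an observation pair must
#' be scaled (up to correlation-independent constants) to yield the logLR.
#' It exceeds 1 for negative correlations (synergy), equals 1 at
#' \eqn{\rho = 0}, and falls below 1 for positive correlations (redundancy).
#'
#' @param rho pairwise correlation, > -1.
#' @return Positive scale factor.
#' @export
correlation_scale_factor <- function(rho) {
  check_rho(rho, open_lower_only = TRUE)
  1 / (1 + rho)
}

#' Empirical within-trial correlation of an observation stream
#'
#' Pearson correlation of the \eqn{(x_1, x_2)} pairs observed within one
#' trial. With very few pairs this estimator is noisy and its magnitude is
#' biased toward zero on average.
#'
#' @param pairs a two-column matrix (or data.frame) of observation pairs.
#' @return The sample correlation, or `NA` if either coordinate has zero
#'   variance.
#' @export
empirical_correlation <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (!is.numeric(pairs) || ncol(pairs) != 2L)
    stop("pairs must be a numeric two-column matrix")
  if (nrow(pairs) < 2L)
    stop("insufficient data: at least 2 pairs are required")
  if (stats::sd(pairs[, 1]) == 0 || stats::sd(pairs[, 2]) == 0)
    return(NA_real_)
  stats::cor(pairs[, 1], pairs[, 2])
}

#' Fisher z-transform and its inverse
#'
#' `fisher_z()` maps a correlation to the variance-stabilized scale
#' \eqn{z = \mathrm{atanh}(\rho)}; `fisher_z_inverse()` maps back.
#'
#' @param rho correlation(s) in (-1, 1).
#' @param z value(s) on the Fisher z scale.
#' @return Transformed numeric vector.
#' @export
fisher_z <- function(rho) {
  if (any(!is.finite(rho)) || any(abs(rho) >= 1))
    stop("invalid correlation: |rho| must be < 1")
  atanh(rho)
}

#' @rdname fisher_z
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Fisher-z mean of correlations
#'
#' Averages correlations on the Fisher z scale and back-transforms, the
#' convention used for summarizing subjective correlation estimates.
#'
#' @param rho correlations in (-1, 1); `NA`s removed.
#' @return A single correlation.
#' @export
fisher_z_mean <- function(rho) {
  rho <- rho[!is.na(rho)]
  fisher_z_inverse(mean(fisher_z(rho)))
}

#' @export
print.generative_spec <- function(x, ...) {
  cat(sprintf(
    "Bivariate Gaussian source: mu_g = %.4g, sigma_g = %.4g, rho = %.3g\n",
    x$mu_g, x$sigma_g, x$rho))
  cat(sprintf("  expected evidence strength E[logLR] = %.4g\n",
              expected_evidence_strength(x)))
  invisible(x)
}
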