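#' Task configuration
#'
#' Design constants of the correlated star-pair discrimination task: a
#' 4-block by 192-trial session with 12 crossed conditions (2 sources x
#' 2 evidence levels x 3 correlation conditions), stimulus pairs updated
#' every 0.2 s with per-coordinate SD 0.1 (window-height units) and display
#' truncation at |x| <= 0.7.
#'
#' @param correlation_magnitude magnitude of the nonzero correlation
#'   conditions, in (0, 1); groups in the study used 0.2, 0.4, 0.6, 0.8.
#' @param sigma_g per-coordinate generative SD (window-height units).
#' @param frame_interval seconds between successive stimulus pairs.
#' @param truncation_limit display clipping limit (window-height units).
#' @param n_blocks,trials_per_block session structure; the product must be
#'   divisible by 12.
#' @param evidence_multipliers named pair `c(low=, high=)` of multipliers
#'   applied to the threshold evidence strength (expected logLR).
#' @param multiplier_scale `"strength"` applies the multipliers to the
#'   expected logLR (mean scales as the square root); `"mean"` applies them
#'   to the generative mean directly.
#' @param staircase_duration fixed trial duration during calibration (s).
#' @return An object of class `task_config`.
#' @export
task_config <- function(correlation_magnitude = 0.6,
                        sigma_g = 0.1,
                        frame_interval = 0.2,
                        truncation_limit = 0.7,
                        n_blocks = 4L,
                        trials_per_block = 192L,
                        evidence_multipliers = c(low = 0.4, high = 2.5),
                        multiplier_scale = c("strength", "mean"),
                        staircase_duration = 1.4) {
  if (correlation_magnitude <= 0 || correlation_magnitude >= 1)
    stop("correlation_magnitude must be in (0, 1)")
  if (sigma_g <= 0) stop("sigma_g must be positive")
  if (truncation_limit <= 0) stop("truncation_limit must be positive")
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  n_cond <- 12L
  if ((n_blocks * trials_per_block) %% n_cond != 0L)
    stop("configuration error: n_blocks * trials_per_block = ",
         n_blocks * trials_per_block, " is not divisible by ", n_cond,
         " conditions")
  if (trials_per_block %% n_cond != 0L)
    stop("configuration error: trials_per_block = ", trials_per_block,
         " is not divisible by ", n_cond, " conditions (sets must be whole)")
  if (!all(c("low", "high") %in% names(evidence_multipliers)))
    stop("evidence_multipliers must be named c(low=, high=)")
  structure(list(
    correlation_magnitude = correlation_magnitude,
    sigma_g = sigma_g,
    frame_interval = frame_interval,
    truncation_limit = truncation_limit,
    n_blocks = n_blocks,
    trials_per_block = trials_per_block,
    evidence_multipliers = evidence_multipliers[c("low", "high")],
    multiplier_scale = match.arg(multiplier_scale),
    staircase_duration = staircase_duration
  ), class = "task_config")
}

#' The 12 trial conditions
#'
#' @param config a [task_config()].
#' @return Data frame with one row per condition: `source` (left/right),
#'   `evidence_level` (low/high), `correlation_condition`
#'   (negative/zero/positive) and the signed `rho`.
#' @export
condition_table <- function(config = task_config()) {
  grid <- expand.grid(
    source = c("left", "right"),
    evidence_level = c("low", "high"),
    correlation_condition = c("negative", "zero", "positive"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rho <- c(negative = -config$correlation_magnitude, zero = 0,
                positive = config$correlation_magnitude)[grid$correlation_condition]
  grid
}

#' Build the trial sequence for a session
#'
#' Each block is divided into sets of 12 trials; within a set every
#' condition appears exactly once in random order, so all 12 conditions are
#' seen before any repeats.
#'
#' @param config a [task_config()].
#' @return Data frame with one row per trial: `block`, `set`, `trial`
#'   (session-wide index) and the condition columns of [condition_table()].
#' @examples
#' trials <- build_trial_sequence(task_config())
#' nrow(trials)                        # 768
#' table(trials$correlation_condition) # balanced
#' @export
build_trial_sequence <- function(config = task_config()) {
  stopifnot(inherits(config, "task_config"))
  cond <- condition_table(config)
  n_cond <- nrow(cond)
  sets_per_block <- config$trials_per_block %/% n_cond
  rows <- vector("list", config$n_blocks * sets_per_block)
  i <- 0L
  for (b in seq_len(config$n_blocks)) {
    for (s in seq_len(sets_per_block)) {
      i <- i + 1L
      ord <- sample.int(n_cond)
      set <- cond[ord, , drop = FALSE]
      set$block <- b
      set$set <- s
      rows[[i]] <- set
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$trial <- seq_len(nrow(out))
  out[, c("block", "set", "trial", "source", "evidence_level",
          "correlation_condition", "rho")]
}

#' Generate a within-trial stimulus stream
#'
#' Draws `n_frames` i.i.d. pairs from the bivariate Gaussian with means
#' `(mu_rho, mu_rho)`, SDs `sigma_g` and correlation `rho`, then clips each
#' coordinate to the display limit (truncation is clipping, not
#' resampling).
#'
#' @param mu_rho signed generative mean (negative for a left source).
#' @param sigma_g per-coordinate SD.
#' @param rho pairwise correlation, |rho| < 1.
#' @param n_frames number of pairs (>= 1).
#' @param truncation_limit clipping limit; `Inf` disables clipping.
#' @return `n_frames` x 2 numeric matrix with columns `x1`, `x2`.
#' @export
generate_stimulus_stream <- function(mu_rho, sigma_g, rho, n_frames,
                                     truncation_limit = 0.7) {
  check_rho(rho)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  sigma <- sigma_g^2 * matrix(c(1, rho, rho, 1), 2, 2)
  x <- MASS::mvrnorm(n_frames, mu = c(mu_rho, mu_rho), Sigma = sigma)
  x <- matrix(x, ncol = 2)
  if (is.finite(truncation_limit))
    x[] <- pmin(pmax(x, -truncation_limit), truncation_limit)
  colnames(x) <- c("x1", "x2")
  x
}

#' Generative mean for a condition, given a threshold mean
#'
#' Converts a staircase threshold (the zero-correlation generative mean at
#' threshold evidence strength) into the zero-correlation mean of an
#' evidence level, applying the configured multiplier on the strength or
#' mean scale, then calibrates for the correlation via
#' \eqn{\mu_\rho = \mu_0\sqrt{1+\rho}}.
#'
#' @param threshold_mean staircase threshold (window-height units).
#' @param evidence_level `"low"` or `"high"`.
#' @param rho signed condition correlation.
#' @param config a [task_config()].
#' @return Unsigned generative mean for the condition.
#' @export
condition_mean <- function(threshold_mean, evidence_level, rho,
                           config = task_config()) {
  mult <- config$evidence_multipliers[[evidence_level]]
  mu_0 <- switch(config$multiplier_scale,
                 strength = threshold_mean * sqrt(mult),
                 mean = threshold_mean * mult)
  calibrated_mean(mu_0, rho)
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(
    "Task: %d blocks x %d trials, 12 conditions, |rho| = %.2g\n",
    x$n_blocks, x$trials_per_block, x$correlation_magnitude))
  cat(sprintf(
    "  sigma_g = %.3g, frame every %.2g s, clipped at |x| <= %.2g\n",
    x$sigma_g, x$frame_interval, x$truncation_limit))
  cat(sprintf("  evidence multipliers (on %s): low = %.2g, high = %.2g\n",
              x$multiplier_scale,
              x$evidence_multipliers[["low"]],
              x$evidence_multipliers[["high"]]))
  invisible(x)
}
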