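#' Adaptive 3-down-1-up staircase calibration
#'
#' Estimates the generative mean at which a responder reaches the accuracy
#' targeted by an n-down-1-up rule (for 3-down-1-up, the root of
#' \eqn{p^3 = 0.5}, i.e. about 79.4% correct) on fixed-duration,
#' zero-correlation trials. The mean is lowered after `n_down` consecutive
#' correct responses and raised after every error, moving in log space; the
#' step shrinks after an initial set of reversals, and the threshold is the
#' mean of the remaining reversal values.
#'
#' @param observer a function of the candidate generative mean returning
#'   `TRUE` (correct) or `FALSE` for one fixed-duration trial. See
#'   [staircase_observer_ideal()].
#' @param config a [task_config()] (provides the fixed trial duration and
#'   `sigma_g`; recorded in the result).
#' @param initial_mean starting mean (window-height units).
#' @param step_factor,fine_step_factor multiplicative step sizes before and
#'   after `coarse_reversals` reversals.
#' @param n_down consecutive correct responses required to lower the mean.
#' @param n_reversals total reversals before stopping.
#' @param coarse_reversals reversals run at the coarse step.
#' @param discard_reversals initial reversals dropped from the threshold
#'   average.
#' @param max_trials trials allowed before declaring non-convergence.
#' @param mean_ceiling mean above which the responder is declared at or
#'   below chance (non-convergence).
#' @return An object of class `staircase_fit`: list with `threshold`,
#'   `reversal_means`, `n_trials`, and the full `trace` of tested means.
#' @examples
#' obs <- staircase_observer_ideal(task_config())
#' set.seed(1)
#' fit <- run_staircase(obs)
#' fit$threshold
#' @export
run_staircase <- function(observer, config = task_config(),
                          initial_mean = 0.2,
                          step_factor = 10^0.05,
                          fine_step_factor = 10^0.02,
                          n_down = 3L, n_reversals = 12L,
                          coarse_reversals = 4L, discard_reversals = 2L,
                          max_trials = 2000L, mean_ceiling = 1) {
  stopifnot(is.function(observer))
  mean_floor <- 1e-6
  m <- initial_mean
  streak <- 0L
  last_dir <- 0L   # -1 down, +1 up
  reversals <- numeric(0)
  trace <- numeric(0)
  trial <- 0L
  while (length(reversals) < n_reversals && trial < max_trials) {
    trial <- trial + 1L
    trace[trial] <- m
    correct <- isTRUE(observer(m))
    dir <- 0L
    if (correct) {
      streak <- streak + 1L
      if (streak >= n_down) { dir <- -1L; streak <- 0L }
    } else {
      streak <- 0L
      dir <- 1L
    }
    if (dir != 0L) {
      if (last_dir != 0L && dir != last_dir) reversals <- c(reversals, m)
      last_dir <- dir
      f <- if (length(reversals) >= coarse_reversals) fine_step_factor
           else step_factor
      m <- if (dir < 0L) m / f else m * f
      m <- max(m, mean_floor)
      if (m >= mean_ceiling)
        stop("staircase non-convergence: mean reached the ceiling (",
             mean_ceiling, "); responder appears to be at or below chance")
    }
  }
  if (length(reversals) < n_reversals)
    stop("staircase non-convergence: only ", length(reversals),
         " reversals in ", trial, " trials (responder may be degenerate)")
  if (length(reversals) <= discard_reversals)
    stop("threshold undefined: need more than ", discard_reversals,
         " reversals")
  kept <- reversals[(discard_reversals + 1L):length(reversals)]
  structure(list(threshold = mean(kept), reversal_means = reversals,
                 n_trials = trial, trace = trace, config = config),
            class = "staircase_fit")
}

#' Accuracy targeted by an n-down-1-up staircase
#'
#' The converged accuracy solves \eqn{p^{n} = 1/2}; for the 3-down-1-up
#' rule this is \eqn{0.5^{1/3} \approx 0.794}.
#'
#' @param n_down the "down" count of the rule.
#' @return Target probability correct.
#' @export
staircase_target_accuracy <- function(n_down = 3L) 0.5^(1 / n_down)

#' Ideal fixed-duration responder for staircase calibration
#'
#' Returns a responder closure for zero-correlation, fixed-duration trials.
#' The ideal observer sums the logLR of the `n_frames` pairs shown in
#' `staircase_duration` seconds and reports the sign; its accuracy at mean
#' `m` is \eqn{\Phi(\sqrt{n E / 2})} with \eqn{E = 4 m^2 / \sigma_g^2},
#' a smooth, monotone psychometric function.
#'
#' @param config a [task_config()].
#' @return A function `m -> logical` (stochastic, uses the R RNG). The
#'   accuracy function itself is attached as attribute `"accuracy"`.
#' @export
staircase_observer_ideal <- function(config = task_config()) {
  n_frames <- ceiling(config$staircase_duration / config$frame_interval)
  acc <- function(m) {
    e <- 4 * m^2 / config$sigma_g^2
    stats::pnorm(sqrt(n_frames * e / 2))
  }
  f <- function(m) stats::runif(1) < acc(m)
  attr(f, "accuracy") <- acc
  f
}

#' @export
print.staircase_fit <- function(x, ...) {
  cat(sprintf(
    "3-down-1-up staircase: threshold mean = %.4g after %d trials (%d reversals)\n",
    x$threshold, x$n_trials, length(x$reversal_means)))
  invisible(x)
}
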