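#' Simulate a full behavioral dataset from a DDM observer
#'
#' Builds a complete session ([build_trial_sequence()]), then draws each
#' trial's (choice, RT) from the Euler-Maruyama path sampler under the
#' trial's condition-specific drift and bound. RTs include the non-decision
#' time; with probability `lapse` a trial is replaced by a random choice at
#' a uniform RT. Optionally attaches the per-trial stimulus stream
#' (`ceiling(rt / frame_interval)` clipped bivariate pairs).
#'
#' @param spec a [ddm_spec()] (its `mu0` is interpreted as the observer's
#'   staircase threshold mean, i.e. the zero-correlation generative mean at
#'   threshold evidence strength).
#' @param config a [task_config()].
#' @param participant_id identifier stored in the output.
#' @param include_stimulus attach stimulus streams as a list column.
#' @param dt_sim,horizon path-sampler settings.
#' @return Data frame (one row per trial) with the behavioral CSV schema:
#'   `participant_id`, `group_magnitude`, `block`, `trial_index`, `source`,
#'   `evidence_level`, `correlation_condition`, `rho`, `mu_rho`, `choice`,
#'   `rt_seconds`, `accuracy`, `n_frames`, plus `points` (scoring
#'   annotation: +1 correct, -2 error) and optionally `stimulus`.
#' @examples
#' spec <- ddm_spec("full_rho", k0 = 8, B0 = 1.2, tB = 0.05, ndt = 0.35,
#'                  lapse = 0.02, rho_minus = -0.5, rho_plus = 0.5,
#'                  mu0 = 0.15)
#' set.seed(7)
#' dat <- simulate_observer_dataset(spec, task_config(n_blocks = 1))
#' mean(dat$accuracy)
#' @export
simulate_observer_dataset <- function(spec, config = task_config(),
                                      participant_id = "sim01",
                                      include_stimulus = FALSE,
                                      dt_sim = 1e-3, horizon = 15) {
  stopifnot(inherits(spec, "ddm_spec"), inherits(config, "task_config"))
  trials <- build_trial_sequence(config)
  trials$choice <- NA_character_
  trials$rt_seconds <- NA_real_
  trials$mu_rho <- NA_real_
  lapse <- spec$params$lapse
  ndt <- spec$params$ndt

  key <- interaction(trials$evidence_level, trials$correlation_condition,
                     drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    rho <- trials$rho[idx[1]]
    lev <- trials$evidence_level[idx[1]]
    cp <- condition_params(spec, rho, lev)
    trials$mu_rho[idx] <- cp$mu_rho
    sim <- em_sample_cpp(cp$drift, cp$B0, cp$tB, cp$bound_scale,
                         length(idx), dt_sim, horizon)
    correct <- sim$choice == 1L
    rt <- sim$rt + ndt
    # unabsorbed paths (choice 0) respond at the horizon by current sign
    hang <- sim$choice == 0L
    if (any(hang)) {
      correct[hang] <- stats::runif(sum(hang)) < 0.5
      rt[hang] <- horizon
    }
    if (lapse > 0) {
      is_lapse <- stats::runif(length(idx)) < lapse
      nl <- sum(is_lapse)
      if (nl > 0) {
        correct[is_lapse] <- stats::runif(nl) < 0.5
        rt[is_lapse] <- stats::runif(nl, 0, horizon)
      }
    }
    src <- trials$source[idx]
    other <- ifelse(src == "left", "right", "left")
    trials$choice[idx] <- ifelse(correct, src, other)
    trials$rt_seconds[idx] <- rt
  }

  trials$accuracy <- as.integer(trials$choice == trials$source)
  trials$points <- ifelse(trials$accuracy == 1L, 1L, -2L)
  trials$n_frames <- as.integer(ceiling(trials$rt_seconds /
                                          config$frame_interval))
  trials$participant_id <- participant_id
  trials$group_magnitude <- config$correlation_magnitude
  # signed generative mean: negative for left sources
  trials$mu_rho <- ifelse(trials$source == "left", -trials$mu_rho,
                          trials$mu_rho)

  if (include_stimulus) {
    trials$stimulus <- lapply(seq_len(nrow(trials)), function(i) {
      generate_stimulus_stream(trials$mu_rho[i], config$sigma_g,
                               trials$rho[i], trials$n_frames[i],
                               config$truncation_limit)
    })
  }
  cols <- c("participant_id", "group_magnitude", "block", "set",
            "trial_index", "source", "evidence_level",
            "correlation_condition", "rho", "mu_rho", "choice",
            "rt_seconds", "accuracy", "points", "n_frames")
  names(trials)[names(trials) == "trial"] <- "trial_index"
  if (include_stimulus) cols <- c(cols, "stimulus")
  trials[, cols]
}
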