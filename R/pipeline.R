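#' Cohort configuration for end-to-end synthetic studies
#'
#' Describes a synthetic cohort of DDM observers: group correlation
#' magnitudes, participants per group, the distribution their individual
#' parameters are drawn from, and how their subjective correlations relate
#' to the objective ones. Subjective correlations are generated as
#' `tanh(attenuation * atanh(rho) + noise)`, i.e. attenuated on the Fisher
#' z scale, emulating observers who systematically underestimate the
#' correlation magnitude.
#'
#' The default desk-scale profile (one group at |rho| = 0.6, 8
#' participants, a single 192-trial block, reduced optimizer budget) runs
#' every code path quickly; the full study scale is reached by widening
#' `groups`, `n_per_group`, and the task config.
#'
#' @param groups correlation magnitudes, each in (0, 1).
#' @param n_per_group participants per group.
#' @param generating_variant variant the synthetic observers follow.
#' @param observer_means,observer_sds means and SDs of the (independent
#'   truncated-normal) per-participant draws of `k0`, `B0`, `tB`, `ndt`,
#'   `lapse`.
#' @param attenuation subjective-correlation attenuation factor in (0, 1]
#'   (Fisher z scale).
#' @param rho_hat_noise_sd SD of participant-level noise on the subjective
#'   correlation (Fisher z scale).
#' @param task base [task_config()] (its correlation magnitude is replaced
#'   per group).
#' @param fit_variants variants fitted to every participant.
#' @param de_control,solver_control optimizer and solver settings used for
#'   the fits.
#' @param master_seed seed from which all per-participant seeds derive.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(groups = 0.6, n_per_group = 8L,
                          generating_variant = "full_rho",
                          observer_means = c(k0 = 8, B0 = 1.2, tB = 0.05,
                                             ndt = 0.35, lapse = 0.02),
                          observer_sds = c(k0 = 1.5, B0 = 0.2, tB = 0.02,
                                           ndt = 0.05, lapse = 0.01),
                          attenuation = 0.7, rho_hat_noise_sd = 0.15,
                          task = task_config(n_blocks = 1L),
                          fit_variants = ddm_variants(),
                          de_control = list(n_pop = 30L, max_gen = 40L),
                          solver_control = corrddm::solver_control(
                            dt = 0.01, dx = 0.01, mass_tol = 1e-6,
                            max_half_cells = 250L),
                          master_seed = 1L) {
  stopifnot(all(groups > 0 & groups < 1), n_per_group >= 1,
            attenuation > 0, attenuation <= 1)
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 generating_variant = generating_variant,
                 observer_means = observer_means,
                 observer_sds = observer_sds,
                 attenuation = attenuation,
                 rho_hat_noise_sd = rho_hat_noise_sd,
                 task = task, fit_variants = fit_variants,
                 de_control = de_control, solver_control = solver_control,
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

# one truncated-normal draw per basic parameter
draw_observer_params <- function(config) {
  m <- config$observer_means; s <- config$observer_sds
  lo <- c(k0 = 0.5, B0 = 0.2, tB = 0, ndt = 0.05, lapse = 0)
  hi <- c(k0 = 40, B0 = 8, tB = 1.5, ndt = 0.9, lapse = 0.1)
  out <- m
  for (nm in names(m)) {
    repeat {
      v <- stats::rnorm(1, m[[nm]], s[[nm]])
      if (v >= lo[[nm]] && v <= hi[[nm]]) { out[[nm]] <- v; break }
    }
  }
  as.list(out)
}

# subjective correlation: Fisher-z attenuation plus participant noise
draw_rho_hat <- function(rho, attenuation, noise_sd) {
  z <- attenuation * fisher_z(rho) + stats::rnorm(1, 0, noise_sd)
  fisher_z_inverse(z)
}

make_observer_spec <- function(config, magnitude, mu0) {
  pars <- draw_observer_params(config)
  variant <- config$generating_variant
  extra <- list()
  if (variant %in% c("full_rho")) {
    extra <- list(
      rho_minus = draw_rho_hat(-magnitude, config$attenuation,
                               config$rho_hat_noise_sd),
      rho_plus = draw_rho_hat(magnitude, config$attenuation,
                              config$rho_hat_noise_sd))
  } else if (variant %in% c("bound_rho", "bound_rho_plus_drift")) {
    extra <- list(
      rho_B_minus = draw_rho_hat(-magnitude, config$attenuation,
                                 config$rho_hat_noise_sd),
      rho_B_plus = draw_rho_hat(magnitude, config$attenuation,
                                config$rho_hat_noise_sd))
  } else if (variant == "scaled_rho") {
    rm <- draw_rho_hat(-magnitude, config$attenuation,
                       config$rho_hat_noise_sd)
    rp <- draw_rho_hat(magnitude, config$attenuation,
                       config$rho_hat_noise_sd)
    extra <- list(rho_SD_minus = rm, rho_SD_plus = rp,
                  rho_B_minus = rm, rho_B_plus = rp)
  }
  if (variant %in% c("drift", "bound_rho_plus_drift"))
    extra <- c(extra, list(k_minus = pars$k0, k_plus = pars$k0))
  do.call(ddm_spec, c(list(variant = variant), pars, extra,
                      list(mu0 = mu0,
                           evidence_multipliers =
                             config$task$evidence_multipliers)))
}

#' Run an end-to-end synthetic cohort
#'
#' For each synthetic participant: draws observer parameters, calibrates
#' the evidence levels with the 3-down-1-up staircase (using the observer's
#' own fixed-duration accuracy), simulates a full session, applies RT
#' exclusions, and fits the configured model variants. Model comparison
#' (AIC-based random-effects BMS) is run over the cohort and per group.
#' Fully reproducible from `master_seed`.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory; when given, writes `cohort.csv`
#'   (trial level), `fits.json`, `bms.json` and `summary.json` (requires
#'   the jsonlite package for the JSON artifacts).
#' @param progress print per-participant progress lines.
#' @return List of class `cohort_result` with `trials` (all participants),
#'   `fits` (list of `fit_result`), `aic_table`, `bms`, `bms_by_group`,
#'   `participants` (true generating parameters and thresholds), and
#'   `summary` (RT-difference and subjective-correlation summaries).
#' @export
run_cohort <- function(config = cohort_config(), out_dir = NULL,
                       progress = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$master_seed)
  participants <- list()
  all_trials <- list()
  fits <- list()
  pid <- 0L
  for (g in config$groups) {
    task <- config$task
    task$correlation_magnitude <- g
    for (i in seq_len(config$n_per_group)) {
      pid <- pid + 1L
      id <- sprintf("p%02d_g%02.0f", pid, 100 * g)
      # staircase calibration against the observer's own accuracy at fixed
      # duration (interrogation accuracy of the diffusion, Phi(drift*sqrt(T)))
      res <- tryCatch({
        spec0 <- make_observer_spec(config, g, mu0 = 0.1)
        responder <- function(m) {
          drift <- spec0$params$k0 * m
          stats::runif(1) < stats::pnorm(drift *
                                           sqrt(task$staircase_duration))
        }
        sc <- run_staircase(responder, task)
        spec <- spec0
        spec$mu0 <- sc$threshold
        trials <- simulate_observer_dataset(spec, task, participant_id = id)
        trials <- apply_rt_exclusions(trials)
        pfits <- list()
        for (v in config$fit_variants) {
          fit_seed <- config$master_seed * 1000L + pid * 10L +
            match(v, ddm_variants())
          pfits[[v]] <-
            fit_participant(trials, v, mu0 = sc$threshold,
                            evidence_multipliers = task$evidence_multipliers,
                            seed = fit_seed,
                            control = config$solver_control,
                            de_control = config$de_control)
        }
        if (progress) message("fitted participant ", id)
        list(spec = spec, threshold = sc$threshold, trials = trials,
             fits = pfits)
      }, error = function(e) {
        warning("participant ", id, " failed and was skipped: ",
                conditionMessage(e))
        NULL
      })
      if (is.null(res)) next
      participants[[id]] <- list(spec = res$spec,
                                 threshold = res$threshold, group = g)
      all_trials[[id]] <- res$trials
      for (v in names(res$fits))
        fits[[paste(id, v, sep = ".")]] <- res$fits[[v]]
    }
  }
  trials <- do.call(rbind, all_trials)
  rownames(trials) <- NULL

  ids <- names(participants)
  aic_table <- matrix(NA_real_, length(ids), length(config$fit_variants),
                      dimnames = list(ids, config$fit_variants))
  for (id in ids)
    for (v in config$fit_variants)
      aic_table[id, v] <- fits[[paste(id, v, sep = ".")]]$aic

  bms <- if (length(config$fit_variants) >= 2L)
    random_effects_bms(evidence_from_aic(aic_table)) else NULL
  bms_by_group <- NULL
  if (length(config$groups) > 1L && !is.null(bms)) {
    grp <- vapply(participants, `[[`, numeric(1), "group")
    bms_by_group <- lapply(split(ids, grp), function(sub) {
      if (length(sub) >= 2L)
        random_effects_bms(evidence_from_aic(aic_table[sub, , drop = FALSE]))
    })
  }

  summary <- list(
    rt_difference = rt_difference_summary(trials),
    subjective_correlation = subjective_correlation_summary(
      fits, participants, config$fit_variants)
  )
  result <- structure(list(trials = trials, fits = fits,
                           aic_table = aic_table, bms = bms,
                           bms_by_group = bms_by_group,
                           participants = participants, summary = summary,
                           config = config),
                      class = "cohort_result")
  if (!is.null(out_dir)) write_cohort_artifacts(result, out_dir)
  result
}

write_cohort_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$trials, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    fits <- lapply(result$fits, function(f)
      list(participant_id = f$participant_id, variant = f$variant,
           parameters = as.list(f$parameters),
           log_likelihood = f$log_likelihood, aic = f$aic,
           n_trials = f$n_trials, converged = f$optimizer$converged))
    jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(result$bms))
      jsonlite::write_json(
        list(expected_frequencies = as.list(result$bms$expected_frequencies),
             exceedance_prob = as.list(result$bms$exceedance_prob),
             protected_exceedance_prob =
               as.list(result$bms$protected_exceedance_prob),
             bor = result$bms$bor),
        file.path(out_dir, "bms.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(out_dir)
}

# regression of fitted subjective correlations on the objective ones,
# Fisher z scale, plus the sign-flipped deviation summary
subjective_correlation_summary <- function(fits, participants, variants) {
  if (!"full_rho" %in% variants) return(NULL)
  rows <- do.call(rbind, lapply(names(participants), function(id) {
    f <- fits[[paste(id, "full_rho", sep = ".")]]
    g <- participants[[id]]$group
    data.frame(participant_id = id,
               rho = c(-g, g),
               rho_hat = unname(f$parameters[c("rho_minus", "rho_plus")]))
  }))
  z_obj <- fisher_z(rows$rho)
  z_hat <- fisher_z(pmin(pmax(rows$rho_hat, -0.999), 0.999))
  slope <- stats::coef(stats::lm(z_hat ~ 0 + z_obj))[[1]]
  # sign-flip deviations for negative conditions so under/over-estimates align
  dev <- (z_hat - z_obj) * sign(rows$rho)
  list(table = rows, fisher_z_slope = slope,
       mean_signed_deviation = mean(dev))
}

#' Positive-minus-negative RT differences with reference curves
#'
#' Per-participant difference in mean correct-trial RT between the
#' positive- and negative-correlation conditions, with the closed-form
#' reference predictions of a fixed-bound accumulator whose weight of
#' evidence is computed in four regimes: `unscaled` (raw star positions),
#' `naive` (scaled by the generative mean, ignoring the correlation),
#' `true` (the full correlation-dependent logLR scale factor, predicting
#' exactly zero difference), and `underestimate` (scale factor computed
#' with `1 + 0.9 * rho` in place of `1 + rho`).
#'
#' @param dataset trial-level data frame (may span participants/groups).
#' @param magnitudes correlation magnitudes at which reference curves are
#'   evaluated.
#' @param drift_snr effective per-second signal-to-noise ratio
#'   \eqn{a = 2\mu_0/(\sigma_g\sqrt{2\Delta t})} of the reference
#'   accumulator (constant across correlation conditions by design).
#' @param bound_0 reference bound at zero correlation (in units of the
#'   unit-diffusion process).
#' @return List with `per_participant` (data frame of RT differences) and
#'   `reference` (data frame: magnitude, regime, predicted difference).
#' @export
rt_difference_summary <- function(dataset,
                                  magnitudes = c(0.2, 0.4, 0.6, 0.8),
                                  drift_snr = 1.4, bound_0 = 1.1) {
  stopifnot(all(c("participant_id", "correlation_condition",
                  "rt_seconds", "accuracy") %in% names(dataset)))
  per <- lapply(split(dataset, dataset$participant_id), function(d) {
    d <- d[d$accuracy == 1L, , drop = FALSE]
    has <- c("positive", "negative") %in% d$correlation_condition
    if (!all(has)) {
      warning("participant ", d$participant_id[1],
              " lacks a signed correlation condition; skipped")
      return(NULL)
    }
    data.frame(
      participant_id = d$participant_id[1],
      group_magnitude = if (!is.null(d$group_magnitude))
        d$group_magnitude[1] else NA_real_,
      rt_diff = mean(d$rt_seconds[d$correlation_condition == "positive"]) -
        mean(d$rt_seconds[d$correlation_condition == "negative"]))
  })
  per <- do.call(rbind, per)
  if (is.null(per))
    per <- data.frame(participant_id = character(),
                      group_magnitude = numeric(), rt_diff = numeric())
  rownames(per) <- NULL

  # fixed-bound accumulator: mean decision time (b/a) tanh(a b); the
  # effective drift a is correlation-independent (evidence strength is
  # equated), while the effective bound depends on the weighing regime
  mean_dt <- function(a, b) (b / a) * tanh(a * b)
  regimes <- c("unscaled", "naive", "true", "underestimate")
  rel_bound <- function(regime, rho) {
    switch(regime,
      unscaled = 1 / sqrt(1 + rho),
      naive = 1 / (1 + rho),
      true = 1,
      underestimate = (1 + 0.9 * rho) / (1 + rho))
  }
  ref <- expand.grid(magnitude = magnitudes, regime = regimes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ref$rt_diff <- mapply(function(m, reg) {
    mean_dt(drift_snr, bound_0 * rel_bound(reg, m)) -
      mean_dt(drift_snr, bound_0 * rel_bound(reg, -m))
  }, ref$magnitude, ref$regime)
  list(per_participant = per, reference = ref)
}

#' Ideal and naive projections of a fitted observer
#'
#' From a fitted subjective-correlation variant, predicts expected accuracy
#' and mean RT (via the solver) for three observers sharing the non-rho
#' parameters: the `fitted` observer as estimated; the `ideal` observer
#' that encodes and weighs the true correlation (`rho_hat = rho`); and the
#' `naive` observer that encodes the fitted subjective correlation but does
#' not use it to adjust the bound (`rho_SD = rho_hat`, `rho_B = 0`).
#'
#' @param fit a `fit_result` from a rho-bearing variant (`full_rho`,
#'   `bound_rho`, `scaled_rho`, `bound_rho_plus_drift`).
#' @param magnitude objective correlation magnitude of the participant's
#'   group.
#' @param control a [solver_control()].
#' @return Data frame: `observer`, `evidence_level`, `rho`, `accuracy`,
#'   `mean_rt`.
#' @export
ideal_vs_naive_projection <- function(fit, magnitude,
                                      control = solver_control()) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$variant %in% c("full_rho", "bound_rho", "scaled_rho",
                          "bound_rho_plus_drift"))
    stop("variant '", fit$variant, "' has no subjective correlation terms")
  p <- as.list(fit$parameters)
  base <- p[c("k0", "B0", "tB", "ndt", "lapse")]
  rho_hat <- if (fit$variant == "full_rho")
    c(p$rho_minus, p$rho_plus)
  else c(p$rho_B_minus, p$rho_B_plus)   # weighing slot as the estimate

  mk <- function(rm, rp, bm = rm, bp = rp)
    do.call(ddm_spec, c(list(variant = "scaled_rho"), base,
                        list(rho_SD_minus = rm, rho_SD_plus = rp,
                             rho_B_minus = bm, rho_B_plus = bp,
                             mu0 = fit$mu0,
                             evidence_multipliers =
                               fit$evidence_multipliers)))
  specs <- list(
    fitted = mk(rho_hat[1], rho_hat[2]),
    ideal = mk(-magnitude, magnitude),
    naive = mk(rho_hat[1], rho_hat[2], 0, 0))

  rows <- list()
  for (obs in names(specs)) {
    for (lev in c("low", "high")) {
      for (rho in c(-magnitude, 0, magnitude)) {
        sol <- predicted_rt_distribution(specs[[obs]], rho, lev, control)
        rows[[length(rows) + 1L]] <- data.frame(
          observer = obs, evidence_level = lev, rho = rho,
          accuracy = fp_accuracy(sol), mean_rt = fp_mean_rt(sol))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d trials, %d variants fit\n",
              length(x$participants), nrow(x$trials),
              length(x$config$fit_variants)))
  if (!is.null(x$bms)) {
    cat("Protected exceedance probabilities:\n")
    print(round(x$bms$protected_exceedance_prob, 3))
  }
  invisible(x)
}
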