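#' Response-time exclusions
#'
#' Removes trials with RTs below 0.3 s or above 15 s (indicative of
#' off-task behavior); the boundaries themselves are retained.
#'
#' @param dataset behavioral data frame with an `rt_seconds` column.
#' @param min_rt,max_rt exclusion thresholds (s).
#' @return The filtered data frame; the excluded fraction is attached as
#'   attribute `"excluded_fraction"`.
#' @export
apply_rt_exclusions <- function(dataset, min_rt = 0.3, max_rt = 15) {
  stopifnot("rt_seconds" %in% names(dataset))
  keep <- dataset$rt_seconds >= min_rt & dataset$rt_seconds <= max_rt
  keep[is.na(keep)] <- FALSE
  out <- dataset[keep, , drop = FALSE]
  attr(out, "excluded_fraction") <- 1 - mean(keep)
  out
}

#' Default fitting bounds per variant
#'
#' Box constraints for the maximum-likelihood fits: `k` terms in (0, 50\],
#' `B0` in (0, 10\], `tB` in \[0, 2\], `ndt` in \[0, 1\] s, `lapse` in
#' \[0, 0.1\], subjective correlations in (-0.95, 0.95).
#'
#' @param variant one of [ddm_variants()].
#' @return List with numeric vectors `lower` and `upper`, named by
#'   parameter.
#' @export
default_fit_bounds <- function(variant) {
  nms <- variant_param_names(variant)
  lower <- upper <- stats::setNames(numeric(length(nms)), nms)
  for (nm in nms) {
    b <- switch(sub("_(minus|plus)$", "", nm),
      k0 = , k = c(1e-3, 50),
      B0 = c(1e-2, 10),
      tB = c(0, 2),
      ndt = c(0, 1),
      lapse = c(0, 0.1),
      rho = , rho_SD = , rho_B = c(-0.95, 0.95))
    lower[nm] <- b[1]; upper[nm] <- b[2]
  }
  list(lower = lower, upper = upper)
}

# build a ddm_spec from a named parameter vector
spec_from_par <- function(par, variant, mu0, evidence_multipliers) {
  do.call(ddm_spec, c(list(variant = variant), as.list(par),
                      list(mu0 = mu0,
                           evidence_multipliers = evidence_multipliers)))
}

#' Negative log-likelihood of a dataset under a DDM spec
#'
#' Sums `-log` of the predicted defective RT density at each trial's
#' (choice, RT), caching one first-passage solution per condition. The
#' density is floored at `1e-10` per second so the objective stays finite;
#' trials with RTs beyond the solver horizon draw on that floor (with a
#' warning), their mass being part of the reported survival deficit.
#'
#' @param dataset behavioral data frame (schema of
#'   [simulate_observer_dataset()]); RT exclusions should already have been
#'   applied.
#' @param spec a [ddm_spec()].
#' @param control a [solver_control()].
#' @return The negative log-likelihood (natural-log units).
#' @export
ddm_negative_log_likelihood <- function(dataset, spec,
                                        control = solver_control()) {
  if (nrow(dataset) == 0L) return(0)
  needed <- c("evidence_level", "rho", "source", "choice", "rt_seconds")
  stopifnot(all(needed %in% names(dataset)))
  if (any(dataset$rt_seconds > control$horizon, na.rm = TRUE))
    warning("trials with RT beyond the solver horizon contribute the ",
            "density floor (survival deficit)")
  floor_d <- 1e-10
  nll <- 0
  key <- paste(dataset$evidence_level, dataset$rho)
  cache <- new.env(parent = emptyenv())   # conditions sharing drift/bound
  for (k in unique(key)) {
    idx <- which(key == k)
    cp <- condition_params(spec, dataset$rho[idx[1]],
                           dataset$evidence_level[idx[1]])
    ck <- paste(signif(c(cp$drift, cp$B0, cp$tB, cp$bound_scale), 12),
                collapse = "|")
    raw <- cache[[ck]]
    if (is.null(raw)) {
      raw <- solve_first_passage(cp$drift, cp$B0, cp$tB, cp$bound_scale,
                                 control)
      cache[[ck]] <- raw
    }
    sol <- shift_and_mix(raw, cp$ndt, cp$lapse)
    correct <- dataset$choice[idx] == dataset$source[idx]
    rt <- dataset$rt_seconds[idx]
    dc <- stats::approx(sol$time_grid, sol$density_correct, rt,
                        yleft = 0, yright = 0)$y
    de <- stats::approx(sol$time_grid, sol$density_error, rt,
                        yleft = 0, yright = 0)$y
    d <- ifelse(correct, dc, de)
    nll <- nll - sum(log(pmax(d, floor_d)))
  }
  nll
}

#' Fit a DDM variant to one participant's data
#'
#' Maximum-likelihood fit of the full choice/RT distributions by
#' differential evolution ([de_minimize()]). Deterministic given `seed`.
#'
#' @inheritParams ddm_negative_log_likelihood
#' @param variant one of [ddm_variants()].
#' @param mu0 the participant's threshold mean (zero-correlation generative
#'   mean at threshold evidence strength), a known task quantity.
#' @param evidence_multipliers task evidence-strength multipliers.
#' @param bounds list with `lower`/`upper` named vectors; defaults to
#'   [default_fit_bounds()].
#' @param seed RNG seed for the optimizer.
#' @param de_control list of [de_minimize()] settings (`n_pop`, `max_gen`,
#'   `tol`).
#' @param control a [solver_control()]; the default fitting grid
#'   (`dt = dx = 0.01`) is coarser than the solver default, trading a small
#'   constant likelihood bias for speed.
#' @return Object of class `fit_result`: `participant_id`, `variant`,
#'   named `parameters`, `log_likelihood`, `n_trials`, `aic`, and
#'   `optimizer` diagnostics.
#' @export
fit_participant <- function(dataset, variant, mu0,
                            evidence_multipliers = c(low = 0.4, high = 2.5),
                            bounds = NULL, seed = 1L,
                            control = solver_control(dt = 0.01, dx = 0.01,
                                                     mass_tol = 1e-6,
                                                     max_half_cells = 250L),
                            de_control = list()) {
  variant <- match.arg(variant, ddm_variants())
  if (is.null(bounds)) bounds <- default_fit_bounds(variant)
  # densities are only ever evaluated at observed RTs, so the solver horizon
  # can stop just past the slowest trial (the lapse support stays at 15 s)
  if (nrow(dataset) > 0L)
    control$horizon <- min(control$horizon,
                           max(dataset$rt_seconds, na.rm = TRUE) + 0.1)
  nms <- variant_param_names(variant)
  stopifnot(identical(names(bounds$lower), nms))
  obj <- function(par) {
    names(par) <- nms
    spec <- spec_from_par(par, variant, mu0, evidence_multipliers)
    # parameter corners the solver grid cannot resolve get an infinite
    # objective, steering the optimizer back inside the feasible region
    tryCatch(
      suppressWarnings(ddm_negative_log_likelihood(dataset, spec, control)),
      error = function(e) 1e10)
  }
  de_args <- utils::modifyList(
    list(fn = obj, lower = bounds$lower, upper = bounds$upper,
         max_gen = 150L, tol = 1e-6),
    de_control)
  set.seed(seed)
  opt <- do.call(de_minimize, de_args)
  pars <- stats::setNames(opt$par, nms)
  ll <- -opt$value
  n_par <- length(pars)
  structure(list(
    participant_id = if (!is.null(dataset$participant_id))
      dataset$participant_id[1] else NA_character_,
    variant = variant,
    parameters = pars,
    log_likelihood = ll,
    n_trials = nrow(dataset),
    aic = aic(ll, n_par),
    mu0 = mu0,
    evidence_multipliers = evidence_multipliers,
    optimizer = list(generations = opt$generations, n_eval = opt$n_eval,
                     converged = opt$converged, seed = seed)
  ), class = "fit_result")
}

#' Split-half fits
#'
#' Fits a variant independently to the first and second halves of a
#' participant's trials (by trial order), for assessing the stability of
#' parameter estimates over a session.
#'
#' @inheritParams fit_participant
#' @return List with elements `first` and `second`, each a `fit_result`.
#' @export
fit_split_half <- function(dataset, variant, mu0, ..., seed = 1L) {
  n <- nrow(dataset)
  if (n < 4L) stop("insufficient trials for split-half fitting")
  half <- n %/% 2L
  first <- dataset[seq_len(half), , drop = FALSE]
  second <- dataset[(half + 1L):n, , drop = FALSE]
  check_half <- function(d, lab) {
    cnt <- table(paste(d$evidence_level, d$rho))
    if (any(cnt < 2L))
      stop("insufficient trials per condition in the ", lab, " half")
  }
  check_half(first, "first"); check_half(second, "second")
  list(first = fit_participant(first, variant, mu0, ..., seed = seed),
       second = fit_participant(second, variant, mu0, ...,
                                seed = seed + 1L))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("DDM fit ('%s', %s): logL = %.2f, AIC = %.2f, %d trials\n",
              x$variant, x$participant_id, x$log_likelihood, x$aic,
              x$n_trials))
  cat("  ", paste(sprintf("%s = %.4g", names(x$parameters), x$parameters),
                  collapse = ", "), "\n")
  if (!x$optimizer$converged)
    cat("  (optimizer did not reach its tolerance; best-so-far returned)\n")
  invisible(x)
}
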