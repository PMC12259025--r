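#' @keywords internal
variant_param_names <- function(variant) {
  base <- c("k0", "B0", "tB", "ndt", "lapse")
  switch(variant,
    base = base,
    drift = c(base, "k_minus", "k_plus"),
    bound_rho = c(base, "rho_B_minus", "rho_B_plus"),
    full_rho = c(base, "rho_minus", "rho_plus"),
    scaled_rho = c(base, "rho_SD_minus", "rho_SD_plus",
                   "rho_B_minus", "rho_B_plus"),
    bound_rho_plus_drift = c(base, "k_minus", "k_plus",
                             "rho_B_minus", "rho_B_plus"),
    stop("unknown variant: ", variant))
}

#' The six drift-diffusion model variants
#'
#' @return Character vector of variant names, ordered from the base model to
#'   the most flexible.
#' @export
ddm_variants <- function() {
  c("base", "drift", "bound_rho", "full_rho", "scaled_rho",
    "bound_rho_plus_drift")
}

#' Drift-diffusion model specification
#'
#' A variant name plus its parameter vector fully determines predicted
#' choice/RT behavior in every task condition. All variants share five basic
#' parameters: drift sensitivity `k0`, bound height `B0`, linear bound
#' collapse rate `tB`, non-decision time `ndt`, and lapse rate `lapse`.
#' Variants differ in how they respond to the trial's correlation:
#' \describe{
#'   \item{base}{no correlation-dependent adjustment; drift `k0*mu0`,
#'     bound `B0 - tB*t`.}
#'   \item{drift}{free per-correlation drift sensitivities `k_minus`, `k0`,
#'     `k_plus`; bound unscaled.}
#'   \item{bound_rho}{suboptimal weighing: internal noise follows the true
#'     correlation, but the bound is scaled with subjective `rho_B_minus` /
#'     `rho_B_plus`: scale \eqn{\sqrt{1+\hat\rho_B}/\sqrt{1+\rho}}.}
#'   \item{full_rho}{suboptimal encoding: a single subjective correlation
#'     `rho_minus` / `rho_plus` enters both drift and bound; bound scale
#'     \eqn{\sqrt{1+\hat\rho}/\sqrt{1+\rho}}, drift
#'     \eqn{k_0\mu_0\sqrt{(1+\rho)/(1+\hat\rho)}}.}
#'   \item{scaled_rho}{independent encoding (`rho_SD_*`) and weighing
#'     (`rho_B_*`) terms; bound scale
#'     \eqn{(1+\hat\rho_B)/(\sqrt{1+\rho}\sqrt{1+\hat\rho_{SD}})}.}
#'   \item{bound_rho_plus_drift}{bound_rho scaling plus free per-correlation
#'     drifts.}
#' }
#' Variants without explicit encoding parameters assume
#' \eqn{\hat\rho_{SD}=\rho}, the standard DDM convention. The diffusion
#' coefficient is 1; `sigma_g` is absorbed into `k0` and `B0`.
#'
#' @param variant one of [ddm_variants()].
#' @param ... named parameters (see Details); all parameters required by the
#'   variant must be supplied, extras are rejected.
#' @param mu0 task reference mean: the zero-correlation generative mean at
#'   threshold evidence strength (window-height units).
#' @param evidence_multipliers multipliers on threshold evidence strength
#'   defining the low/high levels.
#' @return An object of class `ddm_spec`.
#' @examples
#' spec <- ddm_spec("full_rho", k0 = 8, B0 = 1.2, tB = 0.05, ndt = 0.35,
#'                  lapse = 0.02, rho_minus = -0.5, rho_plus = 0.5,
#'                  mu0 = 0.15)
#' condition_params(spec, rho = 0.6, evidence_level = "high")
#' @export
ddm_spec <- function(variant, ..., mu0 = 0.15,
                     evidence_multipliers = c(low = 0.4, high = 2.5)) {
  variant <- match.arg(variant, ddm_variants())
  pars <- list(...)
  need <- variant_param_names(variant)
  missing <- setdiff(need, names(pars))
  extra <- setdiff(names(pars), need)
  if (length(missing))
    stop("specification error: variant '", variant, "' is missing parameters: ",
         paste(missing, collapse = ", "))
  if (length(extra))
    stop("specification error: variant '", variant,
         "' does not use parameters: ", paste(extra, collapse = ", "))
  pars <- lapply(pars[need], as.numeric)
  with(pars, {
    if (k0 <= 0) stop("k0 must be positive")
    if (B0 <= 0) stop("B0 must be positive")
    if (tB < 0) stop("tB must be non-negative")
    if (ndt < 0) stop("ndt must be non-negative")
    if (lapse < 0 || lapse > 1) stop("lapse must be in [0, 1]")
  })
  for (nm in grep("^rho_", need, value = TRUE)) check_rho(pars[[nm]])
  structure(list(variant = variant, params = pars, mu0 = mu0,
                 evidence_multipliers = evidence_multipliers),
            class = "ddm_spec")
}

# pick the minus/zero/plus slot of a subjective-correlation parameter pair
rho_hat_slot <- function(pars, rho, prefix) {
  if (rho < 0) pars[[paste0(prefix, "_minus")]]
  else if (rho > 0) pars[[paste0(prefix, "_plus")]]
  else 0
}

#' Condition-level drift and bound parameters
#'
#' Maps a `ddm_spec` onto one task condition (signed correlation and
#' evidence level), returning the drift rate and the time-varying bound in
#' the solver's parameterization `bound(t) = scale * (B0 - tB * t)`. The
#' generative mean of the condition is
#' \eqn{\mu_\rho = \mu_0\sqrt{m}\sqrt{1+\rho}} with evidence multiplier
#' \eqn{m}, and the drift rate is
#' \eqn{k\,\mu_\rho/\sqrt{1+\hat\rho_{SD}}}.
#'
#' @param spec a [ddm_spec()].
#' @param rho signed condition correlation (its sign selects the subjective
#'   correlation slot).
#' @param evidence_level `"low"` or `"high"`.
#' @return List with `drift`, `bound_scale`, `B0`, `tB`, `ndt`, `lapse`,
#'   and a convenience function `bound_at(t)` (class `condition_params`).
#' @export
condition_params <- function(spec, rho, evidence_level = c("low", "high")) {
  stopifnot(inherits(spec, "ddm_spec"))
  evidence_level <- match.arg(evidence_level)
  check_rho(rho)
  p <- spec$params
  mult <- spec$evidence_multipliers[[evidence_level]]
  mu0_e <- spec$mu0 * sqrt(mult)          # multiplier acts on E[logLR]
  mu_rho <- mu0_e * sqrt(1 + rho)

  k <- p$k0
  if (spec$variant %in% c("drift", "bound_rho_plus_drift")) {
    k <- if (rho < 0) p$k_minus else if (rho > 0) p$k_plus else p$k0
  }

  rho_sd <- switch(spec$variant,
    full_rho = rho_hat_slot(p, rho, "rho"),
    scaled_rho = rho_hat_slot(p, rho, "rho_SD"),
    rho)                                  # rho_SD = rho for the others
  drift <- k * mu_rho / sqrt(1 + rho_sd)

  bound_scale <- switch(spec$variant,
    base = 1,
    drift = 1,
    bound_rho = sqrt(1 + rho_hat_slot(p, rho, "rho_B")) / sqrt(1 + rho),
    bound_rho_plus_drift =
      sqrt(1 + rho_hat_slot(p, rho, "rho_B")) / sqrt(1 + rho),
    full_rho = sqrt(1 + rho_hat_slot(p, rho, "rho")) / sqrt(1 + rho),
    scaled_rho = (1 + rho_hat_slot(p, rho, "rho_B")) /
      (sqrt(1 + rho) * sqrt(1 + rho_sd)))

  out <- list(drift = drift, bound_scale = bound_scale,
              B0 = p$B0, tB = p$tB, ndt = p$ndt, lapse = p$lapse,
              rho = rho, evidence_level = evidence_level,
              mu_rho = mu_rho)
  out$bound_at <- function(t) pmax(bound_scale * (p$B0 - p$tB * t), 0)
  class(out) <- "condition_params"
  out
}

#' @export
print.ddm_spec <- function(x, ...) {
  cat(sprintf("DDM spec: variant '%s'\n", x$variant))
  cat("  ", paste(sprintf("%s = %.4g", names(x$params),
                          unlist(x$params)), collapse = ", "), "\n")
  cat(sprintf("  mu0 = %.4g, multipliers low = %.2g / high = %.2g\n",
              x$mu0, x$evidence_multipliers[["low"]],
              x$evidence_multipliers[["high"]]))
  invisible(x)
}
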