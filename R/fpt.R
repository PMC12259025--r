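#' Solver control settings
#'
#' Numerical defaults for the first-passage solver: Crank-Nicolson
#' integration of the Fokker-Planck equation with absorbing, linearly
#' collapsing boundaries. `dt` = 5 ms and `dx` = 5e-3 evidence units
#' converge well for the parameter ranges used here; `horizon` = 15 s
#' matches the RT exclusion ceiling.
#'
#' @param dt time step (s).
#' @param dx spatial step (evidence units).
#' @param horizon latest decision time represented (s).
#' @param mass_tol survival mass below which integration stops early.
#' @param lapse_support upper end of the uniform lapse-RT distribution (s);
#'   fixed at the RT ceiling independently of the solver horizon, so that
#'   truncating the horizon (e.g. to a dataset's largest RT during fitting)
#'   does not change the lapse density.
#' @param max_half_cells optional cap on the number of spatial cells between
#'   the start point and one bound; when the bound exceeds
#'   `max_half_cells * dx`, `dx` is stretched to keep the cell count fixed.
#'   `0` (the default) disables the cap; the fitting grid caps at 250 so
#'   implausibly tall bounds explored by the optimizer stay cheap.
#' @return List of class `solver_control`.
#' @export
solver_control <- function(dt = 0.005, dx = 0.005, horizon = 15,
                           mass_tol = 1e-8, lapse_support = 15,
                           max_half_cells = 0L) {
  stopifnot(dt > 0, dx > 0, horizon > dt, lapse_support > 0)
  structure(list(dt = dt, dx = dx, horizon = horizon, mass_tol = mass_tol,
                 lapse_support = lapse_support,
                 max_half_cells = as.integer(max_half_cells)),
            class = "solver_control")
}

#' First-passage-time distributions for a collapsing-bound diffusion
#'
#' Solves the Fokker-Planck equation for a unit-diffusion process with
#' constant drift, started at 0 between symmetric absorbing bounds
#' `+/- scale * (B0 - tB * t)` (clamped one spatial cell above zero), and
#' returns defective RT densities for absorption at the upper bound
#' (`density_correct`, the drift-congruent choice when `drift > 0`) and the
#' lower bound (`density_error`).
#'
#' @param drift drift rate (evidence units per second).
#' @param B0 bound height at t = 0 before scaling.
#' @param tB linear collapse rate (evidence units per second).
#' @param scale correlation-dependent bound scale factor.
#' @param control a [solver_control()].
#' @return Object of class `first_passage_solution`: `time_grid`,
#'   `density_correct`, `density_error`, masses `p_correct`, `p_error`, and
#'   `survival` (mass not absorbed within the horizon).
#' @examples
#' sol <- solve_first_passage(drift = 1, B0 = 1, tB = 0)
#' sol$p_correct           # close to 1 / (1 + exp(-2))
#' @export
solve_first_passage <- function(drift, B0, tB = 0, scale = 1,
                                control = solver_control()) {
  raw <- fpt_solve_cpp(drift, B0, tB, scale, control$dt, control$dx,
                       control$horizon, control$mass_tol,
                       if (is.null(control$max_half_cells)) 0L
                       else control$max_half_cells)
  structure(list(
    time_grid = seq(0, by = control$dt, length.out = raw$n_steps + 1L),
    density_correct = raw$g_up,
    density_error = raw$g_lo,
    p_correct = raw$p_up,
    p_error = raw$p_lo,
    survival = raw$survival,
    dt = control$dt, dx = raw$dx, horizon = control$horizon,
    lapse_support = control$lapse_support
  ), class = "first_passage_solution")
}

#' Predicted RT distribution for one task condition
#'
#' Evaluates [condition_params()] for the spec and condition, solves the
#' first-passage problem, shifts the decision-time densities by the
#' non-decision time, and mixes in the lapse process: with probability
#' `lapse` the response is a random choice at a uniform RT over
#' `[0, horizon]` (lapse RTs are not shifted by `ndt`).
#'
#' @inheritParams condition_params
#' @param control a [solver_control()].
#' @return A `first_passage_solution` on the RT scale (`density_correct` is
#'   the defective density of correct-choice RTs).
#' @export
predicted_rt_distribution <- function(spec, rho,
                                      evidence_level = c("low", "high"),
                                      control = solver_control()) {
  cp <- condition_params(spec, rho, match.arg(evidence_level))
  sol <- solve_first_passage(cp$drift, cp$B0, cp$tB, cp$bound_scale, control)
  shift_and_mix(sol, cp$ndt, cp$lapse)
}

# shift decision-time densities by ndt (whole grid cells) and mix lapse
shift_and_mix <- function(sol, ndt, lapse) {
  n <- length(sol$time_grid)
  m <- as.integer(round(ndt / sol$dt))
  shift <- function(g) {
    if (m == 0L) return(g)
    c(rep(0, min(m, n)), g)[seq_len(n)]
  }
  gc <- shift(sol$density_correct)
  ge <- shift(sol$density_error)
  # mass pushed past the horizon by the shift joins the survival deficit
  pc_raw <- sum(gc) * sol$dt
  pe_raw <- sum(ge) * sol$dt
  support <- if (!is.null(sol$lapse_support)) sol$lapse_support
             else sol$horizon
  lap <- lapse / (2 * support)
  out <- sol
  out$density_correct <- (1 - lapse) * gc + lap
  out$density_error <- (1 - lapse) * ge + lap
  out$p_correct <- (1 - lapse) * pc_raw + lapse / 2
  out$p_error <- (1 - lapse) * pe_raw + lapse / 2
  out$survival <- max(0, 1 - out$p_correct - out$p_error)
  out$ndt <- ndt
  out$lapse <- lapse
  out
}

#' Summaries of a first-passage solution
#'
#' `fp_accuracy()` is the probability of absorbing at the correct bound,
#' conditional on absorption; `fp_mean_rt()` is the mean RT, by default over
#' both absorption sides (optionally correct-side only).
#'
#' @param sol a `first_passage_solution`.
#' @param correct_only for `fp_mean_rt()`, restrict to correct choices.
#' @return A single number.
#' @export
fp_accuracy <- function(sol) {
  sol$p_correct / (sol$p_correct + sol$p_error)
}

#' @rdname fp_accuracy
#' @export
fp_mean_rt <- function(sol, correct_only = FALSE) {
  g <- if (correct_only) sol$density_correct
       else sol$density_correct + sol$density_error
  sum(sol$time_grid * g) / sum(g)
}

#' Simulate first-passage paths
#'
#' Euler-Maruyama simulation (step `dt_sim` <= 1 ms) of the same process the
#' solver integrates, for one task condition, including non-decision time
#' and lapses. Serves as the solver's Monte-Carlo oracle and as the
#' generator of synthetic behavior.
#'
#' @inheritParams condition_params
#' @param n number of simulated trials.
#' @param dt_sim simulation step (s).
#' @param horizon simulation horizon (s).
#' @return Data frame with `correct` (logical; drift-congruent bound) and
#'   `rt` (seconds; `NA` if not absorbed within the horizon).
#' @export
sample_paths <- function(spec, rho, evidence_level = c("low", "high"),
                         n = 1000L, dt_sim = 1e-3, horizon = 15) {
  cp <- condition_params(spec, rho, match.arg(evidence_level))
  n <- as.integer(n)
  stopifnot(n >= 1L, dt_sim <= 1e-3 + 1e-12)
  sim <- em_sample_cpp(cp$drift, cp$B0, cp$tB, cp$bound_scale, n, dt_sim,
                       horizon)
  correct <- sim$choice == 1L
  correct[sim$choice == 0L] <- NA
  rt <- sim$rt + cp$ndt
  if (cp$lapse > 0) {
    is_lapse <- stats::runif(n) < cp$lapse
    n_lapse <- sum(is_lapse)
    if (n_lapse > 0) {
      correct[is_lapse] <- stats::runif(n_lapse) < 0.5
      rt[is_lapse] <- stats::runif(n_lapse, 0, horizon)
    }
  }
  data.frame(correct = correct, rt = rt)
}

#' Check bound-scaling / observation-scaling equivalence
#'
#' Scaling the bound by `1/c` on each trial is mathematically equivalent to
#' keeping the bound fixed and scaling each observation (the evidence
#' increments) by `c`: the scaled evidence has drift `c * drift` and
#' diffusion SD `c`, and crossing a fixed bound `B` with scaled evidence is
#' the same event as crossing `B / c` with unscaled evidence. This function
#' verifies the equivalence numerically with two independent routes: the
#' Fokker-Planck solver run with the bound scaled by `1/c`, versus
#' Euler-Maruyama simulation of the observation-scaled process (drift
#' `c * drift`, diffusion `c`, unscaled bound).
#'
#' @param drift,B0,tB unit-diffusion parameterization of the unscaled
#'   process.
#' @param scale observation scale factor `c > 0`.
#' @param n_sim simulated paths for the observation-scaled route.
#' @param control a [solver_control()].
#' @return List with `p_correct_solver`, `p_correct_sim`,
#'   `p_correct_diff`, and `ks_distance` between the simulated RTs and the
#'   solver's (all-choice) RT CDF.
#' @export
bound_equivalence_check <- function(drift, B0, tB = 0, scale = 1,
                                    n_sim = 20000L,
                                    control = solver_control()) {
  stopifnot(scale > 0)
  sol <- solve_first_passage(drift, B0, tB, scale = 1 / scale, control)
  sim <- em_sample_cpp(scale * drift, B0, tB, 1, as.integer(n_sim), 1e-3,
                       control$horizon, sigma = scale)
  rts <- sim$rt[sim$choice != 0L]
  p_sim <- mean(sim$choice == 1L)
  cdf_grid <- cumsum(sol$density_correct + sol$density_error) * sol$dt
  total <- sol$p_correct + sol$p_error
  emp <- stats::ecdf(rts)
  ks <- max(abs(emp(sol$time_grid) - cdf_grid / total))
  list(p_correct_solver = sol$p_correct, p_correct_sim = p_sim,
       p_correct_diff = abs(sol$p_correct - p_sim), ks_distance = ks)
}

#' @export
print.first_passage_solution <- function(x, ...) {
  cat(sprintf(
    "First-passage solution: p(correct) = %.4f, p(error) = %.4f, survival = %.2g\n",
    x$p_correct, x$p_error, x$survival))
  cat(sprintf("  mean RT = %.3f s on a %d-point grid (dt = %.3g s)\n",
              fp_mean_rt(x), length(x$time_grid), x$dt))
  invisible(x)
}
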