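#' Differential-evolution minimizer
#'
#' A best/1/bin differential-evolution optimizer with box constraints
#' (reflection at the bounds), used for the global maximum-likelihood fits.
#' Deterministic given the R RNG state.
#'
#' @param fn objective function of a numeric parameter vector.
#' @param lower,upper numeric bounds (equal length).
#' @param n_pop population size (default `max(15, 5 * d)`).
#' @param max_gen maximum generations.
#' @param tol stop when the population cost spread falls below
#'   `tol * (|best| + tol)`.
#' @param f_weight,cr differential weight and crossover probability.
#' @return List with `par`, `value`, `generations`, `n_eval`, `converged`.
#' @export
de_minimize <- function(fn, lower, upper, n_pop = NULL, max_gen = 300L,
                        tol = 1e-6, f_weight = 0.8, cr = 0.9) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  if (is.null(n_pop)) n_pop <- max(15L, 5L * d)
  pop <- matrix(stats::runif(n_pop * d, lower, upper), nrow = n_pop,
                byrow = TRUE)
  cost <- apply(pop, 1, fn)
  n_eval <- n_pop
  converged <- FALSE
  gen <- 0L
  reflect <- function(x) {
    for (rep in 1:3) {
      lo <- x < lower; x[lo] <- 2 * lower[lo] - x[lo]
      hi <- x > upper; x[hi] <- 2 * upper[hi] - x[hi]
      if (!any(x < lower | x > upper)) break
    }
    pmin(pmax(x, lower), upper)
  }
  while (gen < max_gen) {
    gen <- gen + 1L
    best <- pop[which.min(cost), ]
    for (i in seq_len(n_pop)) {
      r <- sample(setdiff(seq_len(n_pop), i), 2L)
      mutant <- best + f_weight * (pop[r[1], ] - pop[r[2], ])
      cross <- stats::runif(d) < cr
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      trial <- reflect(trial)
      tc <- fn(trial)
      n_eval <- n_eval + 1L
      if (tc <= cost[i]) { pop[i, ] <- trial; cost[i] <- tc }
    }
    spread <- max(cost) - min(cost)
    if (spread < tol * (abs(min(cost)) + tol)) { converged <- TRUE; break }
  }
  i <- which.min(cost)
  list(par = pop[i, ], value = cost[i], generations = gen, n_eval = n_eval,
       converged = converged)
}
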