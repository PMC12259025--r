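# shared fixtures and independent oracles used across test files

# log-density of the full bivariate Gaussian, written out directly from the
# quadratic form; independent oracle for the simplified logLR expression
log_bvn_density <- function(x1, x2, mu, sigma, rho) {
  q <- ((x1 - mu) / sigma)^2 + ((x2 - mu) / sigma)^2 -
    2 * rho * (x1 - mu) * (x2 - mu) / sigma^2
  -log(2 * pi * sigma^2 * sqrt(1 - rho^2)) - q / (2 * (1 - rho^2))
}

# logLR oracle: ratio of the two full densities (positive vs negative mean)
loglr_oracle <- function(x1, x2, mu, sigma, rho) {
  log_bvn_density(x1, x2, mu, sigma, rho) -
    log_bvn_density(x1, x2, -mu, sigma, rho)
}

# reference observer used in fitting / simulation tests
fixture_full_rho_spec <- function(rho_hat = 0.5, tB = 0.05, lapse = 0.02) {
  ddm_spec("full_rho", k0 = 8, B0 = 1.2, tB = tB, ndt = 0.35,
           lapse = lapse, rho_minus = -rho_hat, rho_plus = rho_hat,
           mu0 = 0.15)
}

# small simulated session, deterministic given seed
fixture_dataset <- function(spec = fixture_full_rho_spec(), seed = 42,
                            config = task_config()) {
  set.seed(seed)
  apply_rt_exclusions(simulate_observer_dataset(spec, config))
}

# tiny optimizer budget for smoke-level fits
tiny_de <- list(n_pop = 8L, max_gen = 3L)
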