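test_that("RT exclusions drop off-task trials and keep the boundaries", {
  d <- data.frame(rt_seconds = c(0.2, 0.3, 1.0, 15, 15.1, NA))
  out <- apply_rt_exclusions(d)
  expect_equal(out$rt_seconds, c(0.3, 1.0, 15))
  expect_equal(attr(out, "excluded_fraction"), 0.5)
  ok <- data.frame(rt_seconds = c(0.5, 1, 2))
  expect_equal(apply_rt_exclusions(ok)$rt_seconds, ok$rt_seconds)
})

test_that("the likelihood prefers the generating parameters", {
  spec <- fixture_full_rho_spec()
  dat <- fixture_dataset(spec, seed = 42)
  perturbed <- spec
  perturbed$params$k0 <- spec$params$k0 * 1.5
  ctl <- solver_control(dt = 0.01, dx = 0.01, mass_tol = 1e-6)
  expect_lt(ddm_negative_log_likelihood(dat, spec, ctl),
            ddm_negative_log_likelihood(dat, perturbed, ctl))
  # empty dataset contributes nothing
  expect_identical(ddm_negative_log_likelihood(dat[0, ], spec), 0)
  # order invariance: the likelihood is a product over trials
  shuffled <- dat[sample(nrow(dat)), ]
  expect_equal(ddm_negative_log_likelihood(shuffled, spec, ctl),
               ddm_negative_log_likelihood(dat, spec, ctl))
})

test_that("a pure-lapse model has the closed-form likelihood", {
  spec <- ddm_spec("full_rho", k0 = 8, B0 = 1.2, tB = 0, ndt = 0.3,
                   lapse = 1, rho_minus = -0.5, rho_plus = 0.5, mu0 = 0.15)
  set.seed(8)
  dat <- apply_rt_exclusions(
    simulate_observer_dataset(spec, task_config(n_blocks = 1)))
  nll <- ddm_negative_log_likelihood(dat, spec)
  expect_equal(nll, nrow(dat) * -log(1 / (2 * 15)), tolerance = 1e-6)
})

test_that("fits are deterministic given a seed and satisfy the AIC identity", {
  dat <- fixture_dataset(seed = 43, config = task_config(n_blocks = 1))
  f1 <- fit_participant(dat, "base", mu0 = 0.15, seed = 7,
                        de_control = tiny_de)
  f2 <- fit_participant(dat, "base", mu0 = 0.15, seed = 7,
                        de_control = tiny_de)
  expect_identical(f1$parameters, f2$parameters)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
  expect_equal(f1$aic, 2 * length(f1$parameters) - 2 * f1$log_likelihood)
  f3 <- fit_participant(dat, "base", mu0 = 0.15, seed = 8,
                        de_control = tiny_de)
  expect_false(identical(f1$parameters, f3$parameters))
})

test_that("split-half fitting partitions trials by order", {
  dat <- fixture_dataset(seed = 44, config = task_config(n_blocks = 1))
  sh <- fit_split_half(dat, "base", mu0 = 0.15, de_control = tiny_de,
                       seed = 3)
  expect_equal(sh$first$n_trials + sh$second$n_trials, nrow(dat))
  expect_s3_class(sh$first, "fit_result")
  sh2 <- fit_split_half(dat, "base", mu0 = 0.15, de_control = tiny_de,
                        seed = 3)
  expect_identical(sh$first$parameters, sh2$first$parameters)
  expect_error(fit_split_half(dat[1:10, ], "base", mu0 = 0.15),
               "insufficient")
})

test_that("the lapse-augmented logistic recovers known psychometric parameters", {
  p_fun <- function(b0, be, lam, e) lam + (1 - 2 * lam) / (1 + exp(-(b0 + be * e)))
  expect_equal(p_fun(0, 1, 0, 0), 0.5)
  expect_equal(p_fun(0, 1, 0, 1), 0.7310586, tolerance = 1e-6)

  set.seed(17)
  e <- rep(c(-4, -0.64, 0.64, 4), each = 1000)
  y <- rbinom(length(e), 1, p_fun(0.1, 0.8, 0.03, e))
  d <- data.frame(choice = ifelse(y == 1, "right", "left"),
                  source = "right", E = e,
                  correlation_condition = rep(c("negative", "zero",
                                                "positive"),
                                              length.out = length(e)))
  fit <- fit_psychometric(d, "joint")
  expect_lt(abs(fit$coefficients[1, "beta_e"] - 0.8), 0.1)
  expect_lt(abs(fit$coefficients[1, "lapse"] - 0.03), 0.02)
  expect_equal(fit$aic, 2 * 3 - 2 * fit$log_likelihood)

  sep <- fit_psychometric(d, "separate")
  expect_equal(nrow(sep$coefficients), 3L)
  expect_equal(sep$n_params, 9L)
})

test_that("shared psychometric parameters favor the joint model on average", {
  p_fun <- function(e) 0.02 + 0.96 / (1 + exp(-0.9 * e))
  set.seed(18)
  delta <- replicate(25, {
    e <- rep(c(-4, -0.64, 0.64, 4), each = 48)   # one session's worth
    cond <- rep(c("negative", "zero", "positive"), length.out = length(e))
    y <- rbinom(length(e), 1, p_fun(e))
    d <- data.frame(choice = ifelse(y == 1, "right", "left"),
                    source = "right", E = e, correlation_condition = cond)
    suppressWarnings(
      fit_psychometric(d, "joint")$aic - fit_psychometric(d, "separate")$aic)
  })
  expect_lt(mean(delta), 0)
})
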