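no_mult <- c(low = 1, high = 1)

test_that("condition parameters implement the variant-specific scalings", {
  # full_rho with rho_hat = rho: exact cancellation, all conditions equal
  sp <- ddm_spec("full_rho", k0 = 10, B0 = 2, tB = 0.1, ndt = 0.3,
                 lapse = 0, rho_minus = -0.6, rho_plus = 0.6, mu0 = 0.15,
                 evidence_multipliers = no_mult)
  for (rho in c(-0.6, 0, 0.6)) {
    cp <- condition_params(sp, rho, "high")
    expect_equal(cp$drift, 10 * 0.15)
    expect_equal(cp$bound_scale * 2, 2)
    expect_equal(cp$bound_at(0), 2)
  }

  # bound_rho with rho_hat_B = 0 at rho = 0.6: bound at 0 is B0 / sqrt(1.6)
  sp2 <- ddm_spec("bound_rho", k0 = 10, B0 = 2, tB = 0, ndt = 0.3,
                  lapse = 0, rho_B_minus = 0, rho_B_plus = 0, mu0 = 0.15,
                  evidence_multipliers = no_mult)
  cp2 <- condition_params(sp2, 0.6, "high")
  expect_equal(cp2$bound_at(0), 2 / sqrt(1.6), tolerance = 1e-12)
  expect_equal(cp2$bound_at(0) / 2, 0.7905694, tolerance = 1e-7)
  expect_equal(cp2$drift, 10 * 0.15)   # rho_SD = rho cancels sqrt(1+rho)

  # full_rho with rho_hat = 0.3 at rho = 0.6, k0 = 10, mu0 = 0.15
  sp3 <- ddm_spec("full_rho", k0 = 10, B0 = 1, tB = 0, ndt = 0.3,
                  lapse = 0, rho_minus = -0.3, rho_plus = 0.3, mu0 = 0.15,
                  evidence_multipliers = no_mult)
  cp3 <- condition_params(sp3, 0.6, "high")
  expect_equal(cp3$drift, 10 * 0.15 * sqrt(1.6 / 1.3), tolerance = 1e-12)
  expect_equal(cp3$drift, 1.6641, tolerance = 1e-4)
  expect_equal(cp3$bound_scale, sqrt(1.3 / 1.6), tolerance = 1e-12)
  expect_equal(cp3$bound_scale, 0.9014, tolerance = 1e-4)

  # base: no correlation-dependent scaling at all
  sp4 <- ddm_spec("base", k0 = 10, B0 = 1, tB = 0.2, ndt = 0.3, lapse = 0,
                  mu0 = 0.15, evidence_multipliers = no_mult)
  for (rho in c(-0.6, 0.6)) {
    cp4 <- condition_params(sp4, rho, "low")
    expect_equal(cp4$drift, 1.5)
    expect_equal(cp4$bound_scale, 1)
    expect_equal(cp4$bound_at(1), 0.8)
  }

  # variant/parameter mismatches are named
  expect_error(ddm_spec("full_rho", k0 = 1, B0 = 1, tB = 0, ndt = 0,
                        lapse = 0), "missing parameters.*rho_minus")
  expect_error(ddm_spec("base", k0 = 1, B0 = 1, tB = 0, ndt = 0, lapse = 0,
                        rho_minus = 0.1), "does not use")
})

test_that("the solver reproduces constant-bound closed forms", {
  sol <- solve_first_passage(drift = 1, B0 = 1, tB = 0)
  p_exact <- 1 / (1 + exp(-2))
  expect_lt(abs(sol$p_correct - p_exact) / p_exact, 0.01)
  expect_lt(abs(fp_mean_rt(sol) - tanh(1)) / tanh(1), 0.01)
  expect_lt(abs(sol$p_correct + sol$p_error + sol$survival - 1), 1e-6)
  expect_true(all(sol$density_correct >= 0) && all(sol$density_error >= 0))
  # trapezoidal mass identity
  expect_lt(abs(sum(sol$density_correct) * sol$dt - sol$p_correct), 1e-3)

  # zero drift: symmetric absorption
  s0 <- solve_first_passage(0, 1, 0)
  expect_equal(s0$p_correct, 0.5, tolerance = 1e-6)

  # full collapse forces absorption by the collapse time
  sc <- solve_first_passage(0.5, 1, 1)
  expect_equal(sc$p_correct + sc$p_error, 1, tolerance = 1e-6)
  tot <- sc$density_correct + sc$density_error
  expect_lte(max(sc$time_grid[tot > 0]), 1 + sc$dt)

  expect_error(solve_first_passage(1, 1, tB = 2, scale = 10,
                                   control = solver_control()),
               "resolution")
})

test_that("path samples agree with the solver distributions", {
  spec <- ddm_spec("base", k0 = 1, B0 = 1, tB = 0, ndt = 0, lapse = 0,
                   mu0 = 1, evidence_multipliers = no_mult)
  set.seed(31)
  sim <- sample_paths(spec, 0, "high", n = 4e4)
  sol <- solve_first_passage(1, 1, 0)
  se <- sqrt(sol$p_correct * (1 - sol$p_correct) / nrow(sim))
  expect_lt(abs(mean(sim$correct) - sol$p_correct), 3 * se)
  cdf <- cumsum(sol$density_correct) * sol$dt / sol$p_correct
  ks <- max(abs(ecdf(sim$rt[sim$correct])(sol$time_grid) - cdf))
  expect_lt(ks, 0.015)

  # zero drift: choices at chance
  spec0 <- ddm_spec("base", k0 = 1, B0 = 1, tB = 0, ndt = 0, lapse = 0,
                    mu0 = 1e-9, evidence_multipliers = no_mult)
  set.seed(32)
  sim0 <- sample_paths(spec0, 0, "high", n = 2e4)
  expect_lt(abs(mean(sim0$correct) - 0.5), 3 * 0.5 / sqrt(nrow(sim0)))
})

test_that("lapse mixing and non-decision shift act as specified", {
  spec <- function(l) ddm_spec("base", k0 = 8, B0 = 1.2, tB = 0.05,
                               ndt = 0.35, lapse = l, mu0 = 0.15)
  s_nolapse <- predicted_rt_distribution(spec(0), 0, "high")
  raw <- solve_first_passage(condition_params(spec(0), 0, "high")$drift,
                             1.2, 0.05)
  # lapse 0: identical to the ndt-shifted raw solution
  m <- round(0.35 / raw$dt)
  expect_equal(s_nolapse$density_correct[(m + 1):length(raw$time_grid)],
               raw$density_correct[1:(length(raw$time_grid) - m)],
               tolerance = 1e-12)
  # no mass before ndt beyond the lapse component
  s_lapse <- predicted_rt_distribution(spec(0.01), 0, "high")
  before <- s_lapse$time_grid < 0.35
  expect_true(all(abs(s_lapse$density_correct[before] -
                        0.01 / (2 * 15)) < 1e-12))
  # mixture weights: 99% diffusion + 1% uniform
  expect_equal(s_lapse$density_correct,
               0.99 * s_nolapse$density_correct + 0.01 / 30,
               tolerance = 1e-12)
})

test_that("bound scaling is equivalent to observation scaling", {
  set.seed(41)
  eq1 <- bound_equivalence_check(1, 1, 0, scale = 1, n_sim = 2e4)
  expect_lt(eq1$p_correct_diff, 0.01)
  eq2 <- bound_equivalence_check(1, 1, 0, scale = 2, n_sim = 4e4)
  expect_lt(eq2$p_correct_diff / eq2$p_correct_solver, 0.015)
  expect_lt(eq2$ks_distance, 0.015)
})

test_that("suboptimal weighing moves accuracy and RT in opposite bound directions", {
  # bound_rho ignoring the correlation: higher effective bound at rho < 0
  sp <- ddm_spec("bound_rho", k0 = 8, B0 = 1.2, tB = 0.05, ndt = 0.35,
                 lapse = 0, rho_B_minus = 0, rho_B_plus = 0, mu0 = 0.15)
  out <- vapply(c(-0.6, 0, 0.6), function(r) {
    s <- predicted_rt_distribution(sp, r, "high")
    c(fp_accuracy(s), fp_mean_rt(s))
  }, numeric(2))
  expect_true(all(diff(out[1, ]) < 0))  # accuracy falls with rho
  expect_true(all(diff(out[2, ]) < 0))  # RT falls with rho
})
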