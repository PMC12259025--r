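test_that("logLR of a pair matches the full bivariate density ratio", {
  # frozen example: mu 0.1, sigma 0.1, rho 0.6, x1 + x2 = 0.16 -> 2.0
  spec <- generative_spec(mu_g = 0.1, sigma_g = 0.1, rho = 0.6)
  expect_equal(loglr_pair(0.10, 0.06, spec), 2.0, tolerance = 1e-12)
  expect_equal(loglr_pair(0.10, 0.06, spec),
               loglr_oracle(0.10, 0.06, 0.1, 0.1, 0.6), tolerance = 1e-10)

  # grid equivalence with the density-ratio oracle
  for (mu in c(0.03, 0.1)) for (sig in c(0.05, 0.1)) {
    for (rho in c(-0.8, -0.2, 0, 0.4, 0.9)) {
      sp <- generative_spec(mu, sig, rho)
      for (x1 in c(-0.3, 0, 0.21)) for (x2 in c(-0.14, 0.07)) {
        expect_equal(loglr_pair(x1, x2, sp),
                     loglr_oracle(x1, x2, mu, sig, rho),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("logLR depends on the pair only through its sum and adds over pairs", {
  spec <- generative_spec(0.08, 0.1, -0.4)
  expect_equal(loglr_pair(0.3, -0.1, spec), loglr_pair(-0.1, 0.3, spec))
  expect_equal(loglr_pair(0.3, -0.1, spec), loglr_pair(0.15, 0.05, spec))
  expect_identical(loglr_pair(0.1, -0.1, spec), 0)
  # additivity: the logLR of concatenated evidence is the sum of pair logLRs
  x1 <- c(0.1, -0.2, 0.05); x2 <- c(0.0, 0.3, -0.1)
  expect_equal(sum(loglr_pair(x1, x2, spec)),
               loglr_pair(sum(x1), sum(x2), spec))
})

test_that("expected evidence strength matches its Monte-Carlo oracle", {
  expect_equal(expected_evidence_strength(generative_spec(0.1, 0.1, 0)), 4)
  # equating: calibrated mean at rho = 0.6 gives the same strength
  expect_equal(
    expected_evidence_strength(generative_spec(0.1 * sqrt(1.6), 0.1, 0.6)),
    4, tolerance = 1e-12)
  expect_identical(expected_evidence_strength(generative_spec(0, 0.1, 0.3)), 0)

  set.seed(101)
  for (rho in c(0, 0.6)) {
    mu <- 0.1 * sqrt(1 + rho)
    sp <- generative_spec(mu, 0.1, rho)
    x <- MASS::mvrnorm(2e5, c(mu, mu), 0.01 * matrix(c(1, rho, rho, 1), 2))
    mc <- mean(loglr_pair(x[, 1], x[, 2], sp))
    se <- sd(loglr_pair(x[, 1], x[, 2], sp)) / sqrt(nrow(x))
    expect_lt(abs(mc - expected_evidence_strength(sp)), 4 * se)
  }
})

test_that("mean calibration holds the evidence strength constant in rho", {
  # oracle: solve E[logLR_rho] = E[logLR_0] numerically for the mean
  solve_mean <- function(mu0, rho) {
    stats::uniroot(function(m)
      expected_evidence_strength(generative_spec(m, 0.1, rho)) -
        expected_evidence_strength(generative_spec(mu0, 0.1, 0)),
      c(1e-6, 1), tol = 1e-12)$root
  }
  expect_equal(calibrated_mean(0.05, 0), 0.05)
  expect_equal(calibrated_mean(0.05, 0.8), solve_mean(0.05, 0.8),
               tolerance = 1e-8)
  expect_equal(calibrated_mean(0.05, -0.8), solve_mean(0.05, -0.8),
               tolerance = 1e-8)
  expect_equal(calibrated_mean(0.05, 0.8), 0.0670820, tolerance = 1e-6)
  expect_equal(calibrated_mean(0.05, -0.8), 0.0223607, tolerance = 1e-6)
  for (rho in seq(-0.9, 0.9, by = 0.3)) {
    sp <- generative_spec(calibrated_mean(0.07, rho), 0.1, rho)
    expect_equal(expected_evidence_strength(sp),
                 expected_evidence_strength(generative_spec(0.07, 0.1, 0)),
                 tolerance = 1e-12)
  }
  # sign symmetry: flipping the source sign negates the expected logLR
  sp_pos <- generative_spec(0.1, 0.1, 0.3)
  set.seed(7)
  x <- MASS::mvrnorm(1e4, c(-0.1, -0.1), 0.01 * matrix(c(1, .3, .3, 1), 2))
  expect_lt(mean(loglr_pair(x[, 1], x[, 2], sp_pos)), 0)
})

test_that("the correlation scale factor is 1/(1+rho) and ties to the logLR", {
  expect_identical(correlation_scale_factor(0), 1)
  expect_equal(correlation_scale_factor(0.6), 0.625)
  expect_equal(correlation_scale_factor(-0.5), 2.0)
  # cross-check: ratio of logLRs at equal mu, sigma, x-sum
  s06 <- generative_spec(0.1, 0.1, 0.6)
  s00 <- generative_spec(0.1, 0.1, 0.0)
  expect_equal(loglr_pair(0.1, 0.06, s06) / loglr_pair(0.1, 0.06, s00),
               correlation_scale_factor(0.6) / correlation_scale_factor(0))
  # strictly decreasing
  rs <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(vapply(rs, correlation_scale_factor,
                              numeric(1))) < 0))
  expect_error(correlation_scale_factor(-1), "invalid correlation")
})

test_that("empirical within-trial correlations behave like Pearson r", {
  expect_equal(abs(empirical_correlation(rbind(c(0, 0), c(1, 2)))), 1)
  expect_error(empirical_correlation(rbind(c(0, 0))), "insufficient")
  expect_true(is.na(empirical_correlation(rbind(c(1, 0), c(1, 2)))))
  set.seed(11)
  big <- MASS::mvrnorm(1e6, c(0, 0), matrix(c(1, .6, .6, 1), 2))
  expect_lt(abs(empirical_correlation(big) - 0.6), 0.01)
  # small-sample bias toward zero: the mean estimate over many 5-pair
  # trials falls short of the generative 0.6 (the signed estimator is
  # attenuated; |r| itself is variance-inflated at n = 5 and is not)
  rs <- replicate(3000, {
    x <- MASS::mvrnorm(5, c(0, 0), matrix(c(1, .6, .6, 1), 2))
    empirical_correlation(x)
  })
  expect_lt(mean(rs), 0.6 - 2 * sd(rs) / sqrt(length(rs)))
})

test_that("display clipping leaves the evidence strength essentially intact", {
  # the ideal observer ignores the +/-0.7 truncation; at task-scale means
  # (sigma_g = 0.1) the clipped tail mass is ~pnorm(-4.5) or less, so the
  # realized mean logLR is indistinguishable from the unclipped one
  set.seed(23)
  sp <- generative_spec(0.25, 0.1, 0.3)   # larger than any calibrated mean
  raw <- generate_stimulus_stream(0.25, 0.1, 0.3, 2e5,
                                  truncation_limit = Inf)
  clipped <- pmin(pmax(raw, -0.7), 0.7)
  e_raw <- mean(loglr_pair(raw[, 1], raw[, 2], sp))
  e_clip <- mean(loglr_pair(clipped[, 1], clipped[, 2], sp))
  expect_lt(abs(e_clip - e_raw) / e_raw, 1e-3)
})

test_that("Fisher z transform round-trips and matches its closed form", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.6), 0.5 * log(1.6 / 0.4), tolerance = 1e-12)
  expect_equal(fisher_z(0.6), 0.6931472, tolerance = 1e-7)
  expect_equal(fisher_z_inverse(fisher_z(0.8)), 0.8)
  expect_equal(fisher_z(-0.4), -fisher_z(0.4))
  expect_error(fisher_z(1), "invalid correlation")
  expect_equal(fisher_z_mean(c(0.5, 0.5)), 0.5)
})
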