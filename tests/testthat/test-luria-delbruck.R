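test_that("clone-size pmf matches the closed form and normalises", {
  expect_equal(clone_size_pmf(1, 1), 1 / 2)
  expect_equal(clone_size_pmf(3, 1), 1 / 12)
  expect_equal(clone_size_pmf(1:50, 1), 1 / ((1:50) * (2:51)))
  for (rho in c(0.5, 1, 2)) {
    q <- clone_size_pmf(1:2e5, rho)
    expect_true(all(q > 0 & q <= 1))
    expect_true(sum(q) < 1)
    # tail mass S_k ~ Gamma(rho+1) k^-rho: check the partial sum approaches 1
    expect_lt(1 - sum(clone_size_pmf(1:1e6, 2)), 1e-5)
  }
  expect_error(clone_size_pmf(0), "positive integers")
  expect_error(clone_size_pmf(2, fitness = 0), "fitness")
})

test_that("clone-size pmf with fitness 2 matches an inverse-CDF sampling oracle", {
  set.seed(101)
  n <- 1e6
  draws <- oracle_sample_clones(n, fitness = 2)
  for (k in 1:5) {
    phat <- mean(draws == k)
    se <- sqrt(phat * (1 - phat) / n)
    expect_lt(abs(clone_size_pmf(k, 2) - phat), 3 * se)
  }
})

test_that("count pmf recursion: degenerate and closed-form cases", {
  expect_equal(ld_pmf(0, 5), c(1, 0, 0, 0, 0, 0))
  for (m in c(0.2, 0.5, 1, 2, 4)) {
    p <- ld_pmf(m, 3)
    expect_equal(p[1], exp(-m))
    expect_equal(p[2], m * exp(-m) / 2)  # p1 closed form under fitness 1
  }
  p <- ld_pmf(1, 2000)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(cumsum(p) <= 1 + 1e-12))
  expect_gt(sum(p), 0.999)  # monotone convergence of the partial sums
})

test_that("simulator agrees with the recursion and the P0 law", {
  counts0 <- simulate_counts(100, 0, seed = 1)
  expect_true(all(counts0 == 0))
  n <- 1e5
  counts <- simulate_counts(n, 1, seed = 2)
  p0 <- mean(counts == 0)
  expect_lt(abs(p0 - exp(-1)), 3 * sqrt(exp(-1) * (1 - exp(-1)) / n))
  counts2 <- simulate_counts(n, 2, seed = 3)
  pm <- ld_pmf(2, 10)
  for (k in 0:10) {
    phat <- mean(counts2 == k)
    se <- sqrt(max(phat, 1e-6) * (1 - phat) / n)
    expect_lt(abs(phat - pm[k + 1]), 3 * se)
  }
  # determinism for a fixed seed
  expect_identical(simulate_counts(500, 1.5, seed = 9),
                   simulate_counts(500, 1.5, seed = 9))
})

test_that("log-likelihood: explicit values and winsorization cap", {
  expect_equal(ld_loglik(c(0, 0), m = 1), -2)
  expect_equal(ld_loglik(c(0, 1), m = 1), -2 - log(2))
  expect_identical(ld_loglik(5, m = 1, winsor_cap = 3),
                   ld_loglik(3, m = 1, winsor_cap = 3))
  # invariance to inflating counts already above the cap
  base <- c(0, 2, 7, 1500)
  expect_equal(ld_loglik(base, 0.8), ld_loglik(c(0, 2, 7, 99999), 0.8))
  expect_equal(fluctuation_ml(base)$m_hat,
               fluctuation_ml(c(0, 2, 7, 99999))$m_hat)
  expect_identical(ld_loglik(c(0, 0), 0), 0)
  expect_identical(ld_loglik(c(0, 1), 0), -Inf)
})

test_that("ML estimator equals the grid-search maximizer on fixtures", {
  fixtures <- list(c(0, 0, 0, 1, 0, 2, 0, 0, 0, 0),
                   c(0, 1, 1, 0, 3, 0, 0, 2, 0, 0, 5, 0),
                   c(rep(0, 30), 1, 1, 2, 8))
  for (cts in fixtures) {
    # agreement to 3 decimals (the grid step is 0.001)
    expect_lt(abs(fluctuation_ml(cts)$m_hat - oracle_grid_mle(cts)),
              5.1e-4)
  }
})

test_that("all-zero counts give the boundary estimate with flagged SE", {
  fit <- fluctuation_ml(rep(0, 100))
  expect_identical(fit$m_hat, 0)
  expect_true(fit$boundary)
  expect_true(is.na(fit$se_m))
  expect_match(fit$note, "boundary")
})

test_that("joint (m, fitness) estimation recovers both parameters", {
  counts <- simulate_counts(500, 1.5, fitness = 1, seed = 21)
  fit <- fluctuation_ml(counts, fitness_mode = "joint")
  expect_true(fit$converged)
  expect_lt(abs(fit$m_hat - 1.5), 4 * fit$se_m)
  expect_lt(abs(fit$fitness - 1), 4 * fit$se_fitness)
})

test_that("P0 estimator: closed forms and simulation consistency", {
  expect_equal(fluctuation_p0(c(rep(0, 50), rep(1, 50)))$m_hat, log(2))
  fit0 <- fluctuation_p0(rep(0, 10))
  expect_identical(fit0$m_hat, 0)
  expect_true(fit0$boundary)
  expect_error(fluctuation_p0(c(1, 2, 3)), "undefined")
  counts <- simulate_counts(1e4, 1, seed = 31)
  fit <- fluctuation_p0(counts)
  expect_lt(abs(fit$m_hat - 1), 3 * fit$se_m)
})

test_that("rate conversion divides by the mean CFU total", {
  r <- rate_from_m(1, cfu_totals = c(1e8, 1e8, 1e8), se_m = 0.1)
  expect_equal(r$mu_hat, 1e-8)
  expect_equal(r$se_mu, 1e-9)
  r2 <- rate_from_m(1.5, cfu_totals = c(0.8e8, 1.0e8, 1.2e8), se_m = 0.2)
  expect_equal(r2$Nt, 1.0e8)
  expect_equal(r2$mu_hat, 1.5e-8)
  expect_equal(rate_from_m(0, cfu_totals = 2e8, se_m = 0)$mu_hat, 0)
  expect_equal(r2$mu_hat, r2$m_hat / r2$Nt)
  # propagating CFU error can only widen the se
  r3 <- rate_from_m(1.5, cfu_totals = c(0.8e8, 1.0e8, 1.2e8), se_m = 0.2,
                    propagate_nt = TRUE)
  expect_gt(r3$se_mu, r2$se_mu)
  expect_error(rate_from_m(1, cfu_totals = numeric(0)), "positive")
})

test_that("fit methods expose the usual modelling interface", {
  counts <- simulate_counts(182, 1.2, seed = 41)
  fit <- fluctuation_ml(counts)
  expect_named(coef(fit), "m")
  expect_equal(unname(sqrt(vcov(fit)[1, 1])), fit$se_m)
  ci <- confint(fit)
  expect_true(ci["lower"] < fit$m_hat && fit$m_hat < ci["upper"])
  expect_s3_class(logLik(fit), "logLik")
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_length(sims[[1]], 182)
  expect_output(print(summary(fit)), "zero-count fraction")
})
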