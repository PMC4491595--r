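test_that("samplers are reproducible and respect their contracts", {
  pan <- simulate_panel(misclass_params(0.1, c(0.9, 0.85, 0.8),
                                        c(0.95, 0.9, 0.97)),
                        n = 2000, seed = 5)
  cfg <- quick_cfg(31)
  f1 <- lca_gibbs(pan, config = cfg)
  f2 <- lca_gibbs(pan, config = cfg)
  expect_identical(f1$draws, f2$draws)

  # all draws in [0,1]; every retained draw satisfies S_j + C_j > 1
  expect_true(all(f1$draws >= 0 & f1$draws <= 1))
  m <- as.matrix(f1)
  for (j in 1:3) {
    expect_true(all(m[, paste0("S_", j)] + m[, paste0("C_", j)] > 1))
  }
  expect_equal(dim(f1$draws), c(cfg$n_kept, 7L, cfg$n_chains))
})

test_that("model and prior mismatches raise clear errors", {
  pan3 <- random_panel(3, 60)
  pan1 <- test_panel(c(70, 30), k = 1)
  expect_error(single_test_gibbs(pan3, config = quick_cfg(1)), "k = 1")
  expect_error(lca_gibbs(pan3, model_priors(2), quick_cfg(1)), "k = 2")
  expect_error(mcmc_config(), "seed")
  expect_error(model_priors(1, pi = beta_prior(0, 1)), "positive")
})

test_that("the perfect-test limit reduces to a binomial proportion", {
  pan <- test_panel(c(70, 30), k = 1)
  pr <- model_priors(1, sens = beta_prior(1e6, 1), spec = beta_prior(1e6, 1))
  fit <- single_test_gibbs(pan, pr, quick_cfg(3, n_iter = 3000, burn_in = 500))
  s <- posterior_summary(fit)
  expect_equal(s$mean[s$parameter == "pi"], 0.30, tolerance = 0.02)
})

test_that("tight priors reproduce the closed-form correction stochastically", {
  # observed proportion 1% of n = 1e6, priors tightly centered at
  # S = C = 0.995: the posterior median must sit at the Rogan-Gladen value
  pan <- test_panel(c(990000, 10000), k = 1)
  pr <- model_priors(1, sens = beta_prior_from_mean(0.995, 2e5),
                     spec = beta_prior_from_mean(0.995, 2e5))
  fit <- single_test_gibbs(pan, pr, quick_cfg(13, n_iter = 4000, burn_in = 1000))
  s <- posterior_summary(fit)
  target <- correct_prevalence(0.01, 0.995, 0.995)
  med <- s$median[s$parameter == "pi"]
  expect_lt(abs(med - target), 0.001)
})

test_that("flat priors leave the single-test posterior wide, matching the
           grid-integration oracle", {
  # 30 positives of 100 with Beta(1,1) priors on all three parameters:
  # the model is non-identifiable, so the prevalence interval must stay
  # wide; the oracle is direct numerical integration on a lattice
  oracle_ci <- oracle_single_test_ci(30, 100)
  expect_gt(oracle_ci["upper"] - oracle_ci["lower"], 0.5)
  pan <- test_panel(c(70, 30), k = 1)
  fit <- single_test_gibbs(pan, model_priors(1),
                           mcmc_config(seed = 8, n_iter = 8000,
                                       burn_in = 2000, n_chains = 4))
  s <- posterior_summary(fit)
  expect_lt(abs(s$lower[s$parameter == "pi"] - oracle_ci[["lower"]]), 0.06)
  expect_lt(abs(s$upper[s$parameter == "pi"] - oracle_ci[["upper"]]), 0.06)
})

test_that("posterior interval width shrinks with n only when identifiable", {
  truth <- misclass_params(0.1, c(0.9, 0.85, 0.8), c(0.95, 0.9, 0.97))
  width_at <- function(n, seed) {
    pan <- simulate_panel(truth, n = n, seed = seed, method = "multinomial")
    s <- posterior_summary(lca_gibbs(pan, config = quick_cfg(seed,
                                                             n_iter = 2500,
                                                             burn_in = 500)))
    s$upper[s$parameter == "pi"] - s$lower[s$parameter == "pi"]
  }
  w_small <- width_at(500, 61)
  w_large <- width_at(50000, 62)
  expect_lt(w_large, w_small)

  # non-identifiable single test: width stays bounded away from zero as n
  # grows under flat priors
  op <- misclass_params(0.3, 0.8, 0.85)
  widths <- vapply(c(1000, 100000), function(n) {
    x <- round(apparent_prevalence(0.3, 0.8, 0.85) * n)
    pan <- test_panel(c(n - x, x), k = 1)
    s <- posterior_summary(single_test_gibbs(pan, model_priors(1),
                                             mcmc_config(seed = 77,
                                                         n_iter = 6000,
                                                         burn_in = 1500,
                                                         n_chains = 4)))
    s$upper[s$parameter == "pi"] - s$lower[s$parameter == "pi"]
  }, numeric(1))
  expect_true(all(widths > 0.3))
})

test_that("Gibbs posterior means agree with the EM MLE on identifiable data", {
  truth <- misclass_params(0.1, c(0.9, 0.85, 0.8), c(0.95, 0.9, 0.97))
  pan <- simulate_panel(truth, n = 2e4, seed = 19, method = "multinomial")
  em <- lca_em(pan)
  fit <- lca_gibbs(pan, config = quick_cfg(20, n_iter = 4000, burn_in = 1000))
  s <- posterior_summary(fit)
  mle <- c(em$params$pi, em$params$sens, em$params$spec)
  expect_lt(max(abs(s$mean - mle)), 0.02)
  expect_true(all(s$rhat < 1.1))
})
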