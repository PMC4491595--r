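test_that("uninformative tests give the closed-form uniform log-likelihood", {
  # with S = C = 0.5 every pattern has probability 2^-k
  for (k in 1:3) {
    pan <- random_panel(k, n = 40)
    par <- misclass_params(0.3, rep(0.5, k), rep(0.5, k))
    expect_equal(lca_loglik(pan, par), 40 * k * log(0.5), tolerance = 1e-12)
  }
})

test_that("k = 1 collapses to the binomial likelihood in apparent prevalence", {
  pan <- test_panel(c(70, 30), k = 1)
  par <- misclass_params(0.2, 0.9, 0.85)
  p <- apparent_prevalence(0.2, 0.9, 0.85)
  expect_equal(lca_loglik(pan, par), 30 * log(p) + 70 * log(1 - p),
               tolerance = 1e-12)
})

test_that("lca_loglik agrees with brute-force latent class enumeration", {
  set.seed(99)
  for (rep in 1:30) {
    k <- sample(1:4, 1)
    pan <- random_panel(k, n = 50)
    par <- random_params(k)
    expect_equal(lca_loglik(pan, par),
                 oracle_loglik(as.numeric(pan$counts), k, par$pi, par$sens,
                               par$spec),
                 tolerance = 1e-10)
  }
})

test_that("zero-probability patterns with positive counts are flagged -Inf", {
  pan <- test_panel(c(0, 50, 50, 0), k = 2)  # "01" and "10" observed
  par <- misclass_params(0.5, c(1, 1), c(1, 1))  # only "11"/"00" possible
  ll <- lca_loglik(pan, par)
  expect_identical(as.numeric(ll), -Inf)
  expect_true(attr(ll, "zero_pattern"))
})

test_that("dimension mismatches are rejected", {
  pan <- test_panel(c(70, 30), k = 1)
  expect_error(lca_loglik(pan, random_params(2)), "does not match")
})

test_that("EM log-likelihood is non-decreasing and converges", {
  set.seed(7)
  for (rep in 1:5) {
    truth <- random_params(3)
    pan <- simulate_panel(truth, n = 500, seed = 700 + rep)
    fit <- lca_em(pan, tol = 1e-8)
    expect_true(all(diff(fit$loglik_trace) > -1e-9))
    expect_true(fit$converged)
    expect_true(all(fit$params$sens + fit$params$spec > 1))
  }
  # monotone even on structureless data
  noise <- random_panel(3, n = 300)
  nfit <- lca_em(noise, max_iter = 200)
  expect_true(all(diff(nfit$loglik_trace) > -1e-9))
})

test_that("EM stays at an exact-fit fixed point", {
  # counts exactly proportional to the model cell probabilities at
  # theta* = (pi = 0.5, S_j = 0.8, C_j = 0.8): pattern with s positives has
  # probability (4^s + 4^(3-s))/250, so n = 250 gives integer counts
  s_per_pattern <- rowSums(pattern_matrix(3))
  cnt <- (4^s_per_pattern + 4^(3 - s_per_pattern))
  expect_equal(sum(cnt), 250)
  pan <- test_panel(as.integer(cnt))
  theta_star <- misclass_params(0.5, rep(0.8, 3), rep(0.8, 3))
  fit <- lca_em(pan, init = theta_star)
  expect_equal(fit$params$pi, 0.5, tolerance = 1e-6)
  expect_equal(fit$params$sens, rep(0.8, 3), tolerance = 1e-6)
  expect_equal(fit$params$spec, rep(0.8, 3), tolerance = 1e-6)
  # and the fit is a likelihood optimum: no worse than nearby points
  expect_gte(fit$loglik, lca_loglik(pan, misclass_params(0.52, rep(0.8, 3),
                                                         rep(0.8, 3))))
})

test_that("EM recovers the generating parameters at large n", {
  truth <- misclass_params(0.1, c(0.9, 0.85, 0.8), c(0.95, 0.9, 0.97))
  pan <- simulate_panel(truth, n = 1e5, seed = 41, method = "multinomial")
  fit <- lca_em(pan)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$pi - truth$pi), 0.01)
  expect_lt(max(abs(fit$params$sens - truth$sens)), 0.01)
  expect_lt(max(abs(fit$params$spec - truth$spec)), 0.01)
})

test_that("EM relabels mirror-mode solutions to informative tests", {
  truth <- misclass_params(0.1, c(0.9, 0.85, 0.8), c(0.95, 0.9, 0.97))
  pan <- simulate_panel(truth, n = 2e4, seed = 43, method = "multinomial")
  # start on the mirrored side of the likelihood
  mirror <- misclass_params(0.9, 1 - truth$spec, 1 - truth$sens)
  fit <- lca_em(pan, init = mirror)
  expect_true(all(fit$params$sens + fit$params$spec > 1))
  expect_lt(fit$params$pi, 0.5)
})

test_that("EM warns for non-identifiable designs and validates init", {
  pan <- test_panel(c(70, 30), k = 1)
  expect_warning(lca_em(pan, max_iter = 50), "not identifiable")
  pan3 <- random_panel(3, n = 100)
  expect_error(lca_em(pan3, init = misclass_params(0, rep(0.8, 3), rep(0.8, 3))),
               "strictly inside")
})
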