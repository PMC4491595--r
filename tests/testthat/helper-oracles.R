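# Independent oracles, deliberately coded without reusing the package's
# internal probability machinery.

# Brute-force latent class log-likelihood: for each observed pattern,
# enumerate both latent classes and multiply per-test probabilities in an
# explicit double loop. Test 1 is the most significant bit of the pattern
# index; bit value 1 = positive.
oracle_loglik <- function(counts, k, pi, sens, spec) {
  ll <- 0
  for (r in seq_along(counts)) {
    raw <- as.integer(intToBits(r - 1L))  # little-endian bits
    bits <- raw[k:1]                      # bits[j] = result of test j
    pr <- 0
    for (cls in c(TRUE, FALSE)) {
      term <- if (cls) pi else 1 - pi
      for (j in seq_len(k)) {
        pj <- if (cls) sens[j] else 1 - spec[j]
        term <- term * (if (bits[j] == 1L) pj else 1 - pj)
      }
      pr <- pr + term
    }
    if (counts[r] > 0) ll <- ll + counts[r] * log(pr)
  }
  ll
}

# Oracle cell probabilities via the same enumeration (for goodness-of-fit)
oracle_cell_probs <- function(k, pi, sens, spec) {
  vapply(seq_len(2^k), function(r) {
    raw <- as.integer(intToBits(r - 1L))
    bits <- raw[k:1]
    pr <- 0
    for (cls in c(TRUE, FALSE)) {
      term <- if (cls) pi else 1 - pi
      for (j in seq_len(k)) {
        pj <- if (cls) sens[j] else 1 - spec[j]
        term <- term * (if (bits[j] == 1L) pj else 1 - pj)
      }
      pr <- pr + term
    }
    pr
  }, numeric(1))
}

# Fine-grid numerical integration of the 3-parameter single-test posterior
# under flat priors constrained to S + C > 1: returns the equal-tailed
# credible interval of the prevalence marginal.
oracle_single_test_ci <- function(x, n, G = 150, level = 0.95) {
  g <- (seq_len(G) - 0.5) / G
  SC <- expand.grid(S = g, C = g)
  keep <- SC$S + SC$C > 1
  S <- SC$S[keep]; C <- SC$C[keep]
  w <- vapply(g, function(pi) sum(stats::dbinom(x, n, pi * S + (1 - pi) * (1 - C))),
              numeric(1))
  w <- w / sum(w)
  cdf <- cumsum(w)
  a <- (1 - level) / 2
  c(lower = g[which(cdf >= a)[1]], upper = g[which(cdf >= 1 - a)[1]])
}

# random parameter set with informative tests, for property loops
random_params <- function(k) {
  pi <- stats::runif(1, 0.02, 0.6)
  sens <- stats::runif(k, 0.55, 0.99)
  spec <- stats::runif(k, 0.55, 0.99)
  misclass_params(pi, sens, spec)
}

random_panel <- function(k, n = 50) {
  cnt <- as.integer(stats::rmultinom(1, n, rep(1, 2^k)))
  test_panel(cnt, k = k)
}

# short MCMC configuration for fast functional tests
quick_cfg <- function(seed, n_iter = 1500, burn_in = 500, n_chains = 2) {
  mcmc_config(seed = seed, n_iter = n_iter, burn_in = burn_in,
              n_chains = n_chains)
}
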