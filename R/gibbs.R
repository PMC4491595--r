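#' Posterior draws container
#'
#' MCMC output: an array of retained draws indexed by (iteration, parameter,
#' chain), plus the configuration actually used. Parameters are labeled
#' \code{pi}, \code{S_1..S_k}, \code{C_1..C_k} (and for hierarchical fits
#' \code{pi_<region>}, \code{mu}, \code{tau}). All draws lie in \code{[0, 1]}
#' except the logit-scale hyperparameters, and every retained draw satisfies
#' the informative-test labeling constraint \eqn{S_j + C_j > 1}.
#'
#' @param draws numeric array \code{[n_kept, n_param, n_chains]} with
#'   parameter dimnames.
#' @param config the \code{\link{mcmc_config}} used.
#' @param model character tag identifying the sampler.
#' @param details optional list of sampler diagnostics (acceptance rates,
#'   relabeling fallback counts).
#' @return An object of class \code{"posterior_draws"}.
#' @export
posterior_draws <- function(draws, config, model, details = list()) {
  stopifnot(is.array(draws), length(dim(draws)) == 3L,
            inherits(config, "mcmc_config"))
  structure(list(draws = draws, config = config, model = model,
                 details = details),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Posterior draws (%s model): %d parameters, %d chains x %d draws\n",
              x$model, d[2], d[3], d[1]))
  cat("Parameters:", paste(dimnames(x$draws)[[2]], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.posterior_draws <- function(object, level = 0.95, ...) {
  posterior_summary(object, level = level)
}

#' Flatten posterior draws to a matrix
#'
#' @param x a \code{posterior_draws} object.
#' @param ... unused.
#' @return A matrix with one column per parameter, chains stacked by rows.
#' @export
as.matrix.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  out <- do.call(rbind, lapply(seq_len(d[3]), function(c) x$draws[, , c, drop = FALSE][, , 1]))
  colnames(out) <- dimnames(x$draws)[[2]]
  out
}

# Draw (S_j, C_j) pairs from independent beta full conditionals truncated to
# the informative-test region S_j + C_j > 1, by joint rejection; after
# max_tries the mirrored pair (1 - C, 1 - S) is used (it satisfies the
# constraint whenever the raw pair violated it). Returns list(sens, spec,
# fallbacks).
draw_sc_constrained <- function(aS, bS, aC, bC, max_tries = 1000L) {
  k <- length(aS)
  sens <- stats::rbeta(k, aS, bS)
  spec <- stats::rbeta(k, aC, bC)
  bad <- which(sens + spec <= 1)
  tries <- 0L
  while (length(bad) > 0L && tries < max_tries) {
    sens[bad] <- stats::rbeta(length(bad), aS[bad], bS[bad])
    spec[bad] <- stats::rbeta(length(bad), aC[bad], bC[bad])
    bad <- bad[sens[bad] + spec[bad] <= 1]
    tries <- tries + 1L
  }
  fallbacks <- length(bad)
  if (fallbacks > 0L) {
    s_old <- sens[bad]
    sens[bad] <- 1 - spec[bad]
    spec[bad] <- 1 - s_old
  }
  list(sens = sens, spec = spec, fallbacks = fallbacks)
}

# one Gibbs chain for the k-test latent class model; returns a matrix of
# retained draws [n_kept x (2k+1)]
run_lca_chain <- function(panel, priors, n_iter, burn_in, thin, chain_seed) {
  set.seed(chain_seed)
  k <- panel$k
  pm <- pattern_matrix(k)
  cnt <- as.numeric(panel$counts)
  n <- panel$n
  a_pi <- priors$pi$shape1; b_pi <- priors$pi$shape2
  aS <- vapply(priors$sens, `[[`, numeric(1), "shape1")
  bS <- vapply(priors$sens, `[[`, numeric(1), "shape2")
  aC <- vapply(priors$spec, `[[`, numeric(1), "shape1")
  bC <- vapply(priors$spec, `[[`, numeric(1), "shape2")

  # dispersed initialization: draw from the priors, constrained informative
  pi <- stats::rbeta(1, a_pi, b_pi)
  sc <- draw_sc_constrained(aS, bS, aC, bC)
  sens <- sc$sens; spec <- sc$spec

  n_kept <- floor((n_iter - burn_in) / thin)
  out <- matrix(NA_real_, n_kept, 2L * k + 1L)
  colnames(out) <- c("pi", paste0("S_", seq_len(k)), paste0("C_", seq_len(k)))
  fallbacks <- 0L
  row <- 0L
  eps <- 1e-300
  for (it in seq_len(n_iter)) {
    cp <- lca_cell_probs(k, pi, sens, spec)
    w <- (pi * cp$pd) / pmax(cp$cell, eps)
    # latent true-case count within each observed pattern
    z <- stats::rbinom(length(cnt), cnt, w)
    nd <- sum(z)
    pi <- stats::rbeta(1, a_pi + nd, b_pi + n - nd)
    # latent-class-specific test outcome counts
    pos_d <- as.numeric(crossprod(pm, z))
    neg_d <- nd - pos_d
    pos_h <- as.numeric(crossprod(pm, cnt - z))
    neg_h <- (n - nd) - pos_h
    sc <- draw_sc_constrained(aS + pos_d, bS + neg_d, aC + neg_h, bC + pos_h)
    sens <- sc$sens; spec <- sc$spec
    fallbacks <- fallbacks + sc$fallbacks
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      row <- row + 1L
      out[row, ] <- c(pi, sens, spec)
    }
  }
  list(draws = out, fallbacks = fallbacks)
}

# shared driver for the single- and multi-test Gibbs samplers
gibbs_driver <- function(panel, priors, config, model) {
  stopifnot(inherits(panel, "test_panel"), inherits(config, "mcmc_config"))
  if (!inherits(priors, "model_priors")) {
    stop("'priors' must be a model_priors object", call. = FALSE)
  }
  if (priors$k != panel$k) {
    stop(sprintf("priors are for k = %d tests but the panel has k = %d",
                 priors$k, panel$k), call. = FALSE)
  }
  if (panel$n < 1L) stop("panel has no observations", call. = FALSE)
  chains <- lapply(seq_len(config$n_chains), function(c) {
    run_lca_chain(panel, priors, config$n_iter, config$burn_in, config$thin,
                  chain_seed = derive_seed(config$seed, c))
  })
  arr <- array(NA_real_,
               dim = c(config$n_kept, 2L * panel$k + 1L, config$n_chains),
               dimnames = list(NULL, colnames(chains[[1]]$draws), NULL))
  for (c in seq_along(chains)) arr[, , c] <- chains[[c]]$draws
  posterior_draws(arr, config, model,
                  details = list(
                    relabel_fallbacks = sum(vapply(chains, `[[`, numeric(1),
                                                   "fallbacks"))))
}

#' Bayesian single-test prevalence model (non-identifiable)
#'
#' Gibbs sampler for prevalence, sensitivity and specificity from a single
#' binary test: three parameters but only one degree of freedom in the data,
#' so the posterior is driven by the priors on S and C — informative priors
#' (e.g. from a validation study of the diagnostic code) are essential for
#' useful inference, and with flat priors the prevalence posterior remains
#' wide no matter how large n is.
#'
#' The sampler augments the data with the latent counts of true cases among
#' the test-positives and among the test-negatives (each drawn from its
#' conditional binomial), after which all three parameters have conjugate
#' beta updates. Draws are constrained to the informative-test labeling
#' \eqn{S + C > 1}, which removes the mirror mode of the likelihood.
#'
#' @param panel a \code{\link{test_panel}} with \code{k = 1}.
#' @param priors a \code{\link{model_priors}} for one test; default flat.
#' @param config an \code{\link{mcmc_config}} (the seed is required).
#' @return A \code{\link{posterior_draws}} object with parameters
#'   \code{pi}, \code{S_1}, \code{C_1}.
#' @examples
#' pan <- test_panel(c(99000, 1000), k = 1)  # 1% apparent prevalence
#' pr <- model_priors(1, sens = beta_prior_from_mean(0.995, 50000),
#'                       spec = beta_prior_from_mean(0.995, 50000))
#' fit <- single_test_gibbs(pan, pr, mcmc_config(seed = 1, n_iter = 2000,
#'                                               burn_in = 500, n_chains = 2))
#' posterior_summary(fit)
#' @export
single_test_gibbs <- function(panel, priors = model_priors(1), config) {
  stopifnot(inherits(panel, "test_panel"))
  if (panel$k != 1L) {
    stop("single_test_gibbs() requires a single-test panel (k = 1); ",
         "use lca_gibbs() for multi-test panels", call. = FALSE)
  }
  gibbs_driver(panel, priors, config, model = "single_test")
}

#' Bayesian latent class model for k tests
#'
#' Data-augmentation Gibbs sampler for the two-class conditional-independence
#' latent class model. Each iteration draws, for every outcome pattern, the
#' latent number of true cases from its conditional binomial, then updates
#' the prevalence and every sensitivity/specificity from conjugate beta full
#' conditionals. For \eqn{k \ge 3} tests the model is identifiable and with
#' flat \code{Beta(1, 1)} "minimum information" priors the posterior means
#' agree numerically with the maximum-likelihood fit (\code{\link{lca_em}});
#' for \eqn{k < 3} informative priors carry the inference.
#'
#' Label switching (the mirror mode \eqn{S \to 1-C, C \to 1-S,
#' \pi \to 1-\pi}) is removed by constraining every draw to
#' \eqn{S_j + C_j > 1} via rejection at each update, with a mirrored-pair
#' fallback after 1000 rejections (counted in
#' \code{$details$relabel_fallbacks}).
#'
#' @inheritParams single_test_gibbs
#' @param panel a \code{\link{test_panel}} with \code{k >= 1} tests.
#' @param priors a \code{\link{model_priors}} of matching dimension;
#'   default flat on every parameter.
#' @return A \code{\link{posterior_draws}} object with parameters \code{pi},
#'   \code{S_1..S_k}, \code{C_1..C_k}.
#' @examples
#' truth <- misclass_params(0.1, c(0.9, 0.85, 0.8), c(0.95, 0.9, 0.97))
#' pan <- simulate_panel(truth, n = 5000, seed = 3)
#' fit <- lca_gibbs(pan, config = mcmc_config(seed = 1, n_iter = 2000,
#'                                            burn_in = 500, n_chains = 2))
#' posterior_summary(fit)
#' @export
lca_gibbs <- function(panel, priors = model_priors(panel$k), config) {
  stopifnot(inherits(panel, "test_panel"))
  gibbs_driver(panel, priors, config, model = "lca")
}
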