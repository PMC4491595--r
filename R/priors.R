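#' Beta prior
#'
#' @param shape1,shape2 positive beta shape parameters (often written
#'   \eqn{\alpha} and \eqn{\beta}); \code{beta_prior(1, 1)} is the flat
#'   "minimum information" prior.
#' @return An object of class \code{"beta_prior"}.
#' @examples
#' beta_prior(1, 1)                     # flat
#' beta_prior_from_mean(0.995, 10000)   # tight around 99.5%
#' @export
beta_prior <- function(shape1, shape2) {
  if (!is.numeric(shape1) || !is.numeric(shape2) ||
      length(shape1) != 1L || length(shape2) != 1L ||
      is.na(shape1) || is.na(shape2) || shape1 <= 0 || shape2 <= 0) {
    stop("beta prior shapes must be single positive numbers", call. = FALSE)
  }
  structure(list(shape1 = as.numeric(shape1), shape2 = as.numeric(shape2)),
            class = "beta_prior")
}

#' @rdname beta_prior
#' @param mean prior mean in (0, 1).
#' @param size prior "sample size" \eqn{\alpha + \beta}; larger is tighter.
#' @export
beta_prior_from_mean <- function(mean, size) {
  stopifnot(is.numeric(mean), length(mean) == 1L, mean > 0, mean < 1,
            is.numeric(size), length(size) == 1L, size > 0)
  beta_prior(mean * size, (1 - mean) * size)
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) prior, mean %.4g\n", x$shape1, x$shape2,
              x$shape1 / (x$shape1 + x$shape2)))
  invisible(x)
}

#' Prior specification for a k-test latent class model
#'
#' Bundles beta priors for the prevalence and for each test's sensitivity
#' and specificity. The default for every parameter is the flat
#' \code{Beta(1, 1)} minimum-information prior; informative priors (e.g.
#' from a validation sub-study of the diagnostic code against chart review)
#' are entered as beta densities, not point estimates, so the posterior
#' reflects the uncertainty in those quantities.
#'
#' @param k number of tests.
#' @param pi \code{\link{beta_prior}} for the prevalence.
#' @param sens a single \code{beta_prior} (recycled) or a list of k of them.
#' @param spec as \code{sens}, for specificities.
#' @return An object of class \code{"model_priors"} with elements \code{pi}
#'   (a \code{beta_prior}), \code{sens} and \code{spec} (lists of k
#'   \code{beta_prior}), and \code{k}.
#' @examples
#' model_priors(3)  # flat on everything
#' model_priors(1, sens = beta_prior_from_mean(0.995, 20000),
#'                 spec = beta_prior_from_mean(0.995, 20000))
#' @export
model_priors <- function(k, pi = beta_prior(1, 1),
                         sens = beta_prior(1, 1),
                         spec = beta_prior(1, 1)) {
  stopifnot(length(k) == 1L, k >= 1, k == round(k))
  k <- as.integer(k)
  as_prior_list <- function(x, name) {
    if (inherits(x, "beta_prior")) x <- rep(list(x), k)
    if (!is.list(x) || length(x) != k ||
        !all(vapply(x, inherits, logical(1), "beta_prior"))) {
      stop(sprintf("'%s' must be a beta_prior or a list of %d of them",
                   name, k), call. = FALSE)
    }
    x
  }
  if (!inherits(pi, "beta_prior")) {
    stop("'pi' must be a beta_prior", call. = FALSE)
  }
  structure(list(pi = pi, sens = as_prior_list(sens, "sens"),
                 spec = as_prior_list(spec, "spec"), k = k),
            class = "model_priors")
}

#' MCMC run configuration
#'
#' @param seed integer RNG seed; required, with no silent default, so every
#'   run is reproducible. Chain c uses a sub-seed derived deterministically
#'   from \code{seed} and c (see \code{\link{derive_seed}}).
#' @param n_iter total iterations per chain.
#' @param burn_in iterations discarded from the start of each chain
#'   (\code{< n_iter}).
#' @param n_chains number of independent chains.
#' @param thin keep every \code{thin}-th post-burn-in draw.
#' @return An object of class \code{"mcmc_config"}.
#' @examples
#' mcmc_config(seed = 1)
#' mcmc_config(seed = 1, n_iter = 2000, burn_in = 500, n_chains = 1)
#' @export
mcmc_config <- function(seed, n_iter = 20000L, burn_in = 5000L,
                        n_chains = 4L, thin = 1L) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' is required and must be a single integer", call. = FALSE)
  }
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter,
            n_chains >= 1, thin >= 1)
  kept <- floor((n_iter - burn_in) / thin)
  if (kept < 1) stop("configuration retains no draws", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains), thin = as.integer(thin),
                 seed = as.integer(seed), n_kept = as.integer(kept)),
            class = "mcmc_config")
}

#' Deterministic sub-stream seed derivation
#'
#' Maps a master seed and a non-negative stream index (chain number, region
#' number, replicate number) to a sub-seed, so that parallel streams are
#' reproducible and distinct. The rule is
#' \code{(seed * 1009 + index * 9176 + 1) mod (2^31 - 1)}: an integer-valued
#' affine map computed exactly in double precision (all intermediates are
#' far below 2^53).
#'
#' @param seed master integer seed.
#' @param index non-negative integer stream index.
#' @return A single integer seed in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  as.integer((abs(as.numeric(seed)) * 1009 + as.numeric(index) * 9176 + 1) %%
               2147483647)
}

#' Priors for the hierarchical multi-region model
#'
#' Region prevalences are modeled as logit-normal draws from a population
#' distribution: \eqn{logit(\pi_i) \sim N(\mu, \tau^2)}. The hypermean
#' \eqn{\mu} gets a (diffuse) normal prior and the spread \eqn{\tau} a
#' half-normal prior; sensitivities and specificities get beta priors shared
#' across regions by default.
#'
#' @param k number of tests.
#' @param mu_mean,mu_sd mean and standard deviation of the normal prior on
#'   the logit-scale hypermean (defaults: 0 and 5 — effectively flat over
#'   plausible prevalences).
#' @param tau_scale scale of the half-normal prior on the logit-scale
#'   spread (default 1, generous for between-region prevalence variation).
#' @param sens,spec beta priors for the shared test parameters, as in
#'   \code{\link{model_priors}}.
#' @return An object of class \code{"hier_priors"}.
#' @examples
#' hier_priors(3)
#' @export
hier_priors <- function(k, mu_mean = 0, mu_sd = 5, tau_scale = 1,
                        sens = beta_prior(1, 1), spec = beta_prior(1, 1)) {
  stopifnot(is.numeric(mu_mean), length(mu_mean) == 1L,
            is.numeric(mu_sd), length(mu_sd) == 1L, mu_sd > 0,
            is.numeric(tau_scale), length(tau_scale) == 1L, tau_scale > 0)
  mp <- model_priors(k, sens = sens, spec = spec)
  structure(list(mu_mean = as.numeric(mu_mean), mu_sd = as.numeric(mu_sd),
                 tau_scale = as.numeric(tau_scale),
                 sens = mp$sens, spec = mp$spec, k = mp$k),
            class = "hier_priors")
}
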