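#' Simulate a cross-classified test panel
#'
#' Generates data with exactly the statistical structure the latent class
#' estimators assume: each of n subjects is a true case with probability
#' \code{params$pi}; given true status, test j is positive with probability
#' \eqn{S_j} (case) or \eqn{1 - C_j} (non-case), independently across tests.
#' Results are tabulated into the fixed pattern order (test 1 = most
#' significant bit, 1 = positive).
#'
#' The default \code{method = "individual"} simulates subject by subject
#' (status vector, then a Bernoulli per test), which keeps the door open for
#' per-individual extensions. \code{method = "multinomial"} draws the
#' pattern table directly from the model's cell probabilities — the same
#' distribution, much faster at large n.
#'
#' @param params a \code{\link{misclass_params}} (truth).
#' @param n number of subjects.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param method \code{"individual"} (default) or \code{"multinomial"}.
#' @return A \code{\link{test_panel}}.
#' @examples
#' truth <- misclass_params(0.1, c(0.9, 0.85, 0.8), c(0.95, 0.9, 0.97))
#' simulate_panel(truth, n = 1000, seed = 42)
#' @export
simulate_panel <- function(params, n, seed,
                           method = c("individual", "multinomial")) {
  stopifnot(inherits(params, "misclass_params"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop("'n' must be a single integer >= 1", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' is required and must be a single integer", call. = FALSE)
  }
  method <- match.arg(method)
  k <- params$k
  set.seed(as.integer(seed))
  if (method == "multinomial") {
    cell <- lca_cell_probs(k, params$pi, params$sens, params$spec)$cell
    cnt <- as.integer(stats::rmultinom(1, n, cell))
  } else {
    status <- stats::rbinom(n, 1L, params$pi)
    # n x k matrix of test results; P(positive) depends on true status
    pmat <- matrix(rep(params$sens, each = n) * status +
                     rep(1 - params$spec, each = n) * (1 - status),
                   nrow = n, ncol = k)
    res <- matrix(stats::rbinom(n * k, 1L, as.vector(pmat)), nrow = n, ncol = k)
    # pattern index with test 1 as the most significant bit
    idx <- as.integer(res %*% 2^((k - 1):0))
    cnt <- tabulate(idx + 1L, nbins = 2^k)
  }
  test_panel(cnt, k = k)
}

#' Simulate a multi-region collection of panels
#'
#' Region prevalences are drawn from a logit-normal population
#' distribution, \eqn{logit(\pi_i) \sim N(hypermean, hyperspread^2)}, then
#' each region's panel is simulated with \code{\link{simulate_panel}} using
#' a sub-seed derived deterministically from \code{seed} and the region
#' index (\code{\link{derive_seed}}), so the whole collection is
#' reproducible. Sensitivities and specificities are shared across regions,
#' matching the default assumption of the hierarchical model.
#'
#' @param hypermean population mean of the logit-scale prevalences.
#' @param hyperspread population standard deviation on the logit scale,
#'   \code{>= 0} (0 gives every region the identical prevalence).
#' @param sens,spec per-test sensitivity and specificity vectors (length k).
#' @param n_per_region integer vector of region sample sizes; its length
#'   sets the number of regions.
#' @param seed master integer seed.
#' @param region_ids optional character vector of labels; default
#'   \code{"region_01"}, \code{"region_02"}, ...
#' @return A list of \code{\link{region_panel}} objects, with the true
#'   region prevalences attached as \code{attr(, "true_pi")}.
#' @examples
#' simulate_regions(-2.2, 0.5, sens = c(0.9, 0.85, 0.8),
#'                  spec = c(0.95, 0.9, 0.97),
#'                  n_per_region = rep(1000, 4), seed = 9)
#' @export
simulate_regions <- function(hypermean, hyperspread, sens, spec,
                             n_per_region, seed, region_ids = NULL) {
  stopifnot(is.numeric(hypermean), length(hypermean) == 1L,
            is.numeric(hyperspread), length(hyperspread) == 1L,
            hyperspread >= 0)
  check_prob(sens, "sens"); check_prob(spec, "spec")
  if (length(sens) != length(spec)) {
    stop("'sens' and 'spec' must have the same length", call. = FALSE)
  }
  if (!is.numeric(n_per_region) || length(n_per_region) < 1L ||
      any(n_per_region < 1) || any(n_per_region != round(n_per_region))) {
    stop("'n_per_region' must be positive integers", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' is required and must be a single integer", call. = FALSE)
  }
  m <- length(n_per_region)
  if (is.null(region_ids)) {
    region_ids <- sprintf("region_%02d", seq_len(m))
  }
  if (length(region_ids) != m || anyDuplicated(region_ids)) {
    stop("'region_ids' must be unique and match length(n_per_region)",
         call. = FALSE)
  }
  set.seed(derive_seed(seed, 0L))
  pi_r <- stats::plogis(stats::rnorm(m, hypermean, hyperspread))
  out <- vector("list", m)
  for (i in seq_len(m)) {
    pan <- simulate_panel(misclass_params(pi_r[i], sens, spec),
                          n = n_per_region[i],
                          seed = derive_seed(seed, i))
    out[[i]] <- region_panel(region_ids[i], pan)
  }
  attr(out, "true_pi") <- stats::setNames(pi_r, region_ids)
  out
}
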