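# Per-pattern cell probabilities of the two-class conditional-independence
# model. Returns a list with the diseased-class pattern probabilities pd,
# healthy-class probabilities ph, and the mixture cell probabilities.
lca_cell_probs <- function(k, pi, sens, spec) {
  pm <- pattern_matrix(k)
  # prod_j S_j^bit (1-S_j)^(1-bit) per pattern, and the healthy analogue;
  # exact products (no log trick) so boundary parameters give exact zeros
  pd <- rep(1, nrow(pm))
  ph <- rep(1, nrow(pm))
  for (j in seq_len(k)) {
    bit <- pm[, j] == 1L
    pd <- pd * ifelse(bit, sens[j], 1 - sens[j])
    ph <- ph * ifelse(bit, 1 - spec[j], spec[j])
  }
  list(pd = pd, ph = ph, cell = pi * pd + (1 - pi) * ph)
}

#' Log-likelihood of a latent class model for a test panel
#'
#' Multinomial log-likelihood of the cross-classified counts under the
#' two-class conditional-independence model: given true status, the k test
#' results are independent, each positive with probability \eqn{S_j} for a
#' case and \eqn{1 - C_j} for a non-case. The cell probability of pattern r
#' is \deqn{\pi \prod_j p_j(r) + (1 - \pi) \prod_j q_j(r)}
#' with \eqn{p_j(r) = S_j} or \eqn{1 - S_j} and \eqn{q_j(r) = 1 - C_j} or
#' \eqn{C_j} according to the r-th pattern's j-th bit.
#'
#' @param panel a \code{\link{test_panel}}.
#' @param params a \code{\link{misclass_params}} with matching k.
#' @return The log-likelihood (constant multinomial coefficient omitted).
#'   If some pattern has probability zero but a positive count, returns
#'   \code{-Inf} with attribute \code{zero_pattern = TRUE}.
#' @examples
#' pan <- test_panel(c(90, 10), k = 1)
#' lca_loglik(pan, misclass_params(0.005, 0.995, 0.995))
#' @export
lca_loglik <- function(panel, params) {
  stopifnot(inherits(panel, "test_panel"), inherits(params, "misclass_params"))
  if (params$k != panel$k) {
    stop(sprintf("parameter dimension k = %d does not match panel k = %d",
                 params$k, panel$k), call. = FALSE)
  }
  cell <- lca_cell_probs(panel$k, params$pi, params$sens, params$spec)$cell
  pos <- panel$counts > 0
  if (any(pos & cell == 0)) {
    out <- -Inf
    attr(out, "zero_pattern") <- TRUE
    return(out)
  }
  sum(panel$counts[pos] * log(cell[pos]))
}

#' Maximum-likelihood latent class fit by EM
#'
#' Fits the two-class conditional-independence latent class model by
#' expectation-maximization. The E-step computes, for each outcome pattern,
#' the posterior probability that a subject with that pattern is a true
#' case; the M-step re-estimates the prevalence and each test's sensitivity
#' and specificity as weighted proportions. The likelihood can be multimodal,
#' so by default the moment-based starting point is supplemented with
#' jittered restarts and the best solution by log-likelihood is kept. The
#' returned solution is relabeled, if necessary, to the conventional mode
#' where tests are informative (\eqn{S_j + C_j > 1}; the mirror solution
#' \eqn{S \to 1 - C, C \to 1 - S, \pi \to 1 - \pi} has identical
#' likelihood).
#'
#' With fewer than three tests the model is not identifiable and the MLE is
#' not unique; a warning is emitted (the fit still runs, for use as a
#' likelihood probe).
#'
#' @param panel a \code{\link{test_panel}}.
#' @param init optional \code{\link{misclass_params}} starting point,
#'   strictly inside (0, 1). Default: moment-based start from the marginal
#'   positivity rates.
#' @param tol stop when the log-likelihood improves by less than this.
#' @param max_iter iteration cap per start.
#' @param n_starts number of additional jittered starting points.
#' @param seed integer seed for the jittered starts.
#' @return A list of class \code{"lca_em_fit"}: \code{params}
#'   (\code{misclass_params} at the optimum), \code{loglik}, \code{n_iter},
#'   \code{converged}, and \code{loglik_trace} for the winning start.
#' @examples
#' set.seed(1)
#' truth <- misclass_params(0.1, c(0.9, 0.85, 0.8), c(0.95, 0.9, 0.97))
#' pan <- simulate_panel(truth, n = 5000, seed = 7)
#' lca_em(pan)
#' @export
lca_em <- function(panel, init = NULL, tol = 1e-8, max_iter = 10000L,
                   n_starts = 5L, seed = 1L) {
  stopifnot(inherits(panel, "test_panel"))
  k <- panel$k
  if (k < 3L) {
    warning("latent class model with k < 3 tests is not identifiable; ",
            "the EM solution is not unique", call. = FALSE)
  }
  if (!is.null(init)) {
    stopifnot(inherits(init, "misclass_params"))
    if (init$k != k) stop("init dimension mismatch", call. = FALSE)
    if (init$pi <= 0 || init$pi >= 1 || any(init$sens <= 0) ||
        any(init$sens >= 1) || any(init$spec <= 0) || any(init$spec >= 1)) {
      stop("'init' must be strictly inside (0, 1)", call. = FALSE)
    }
  }

  starts <- list(if (is.null(init)) em_moment_start(panel) else init)
  if (is.null(init) && n_starts > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(derive_seed(seed, 977L))
    base <- starts[[1L]]
    for (s in seq_len(n_starts)) {
      jit <- function(x) pmin(0.98, pmax(0.02, x + stats::runif(length(x), -0.15, 0.15)))
      sj <- jit(base$sens); cj <- jit(base$spec)
      bad <- sj + cj <= 1
      sj[bad] <- 1 - cj[bad] + 0.05
      starts[[s + 1L]] <- misclass_params(jit(base$pi), pmin(sj, 0.98), cj)
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  best <- NULL
  for (st in starts) {
    fit <- em_run(panel, st, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$params <- relabel_informative(best$params)
  class(best) <- "lca_em_fit"
  best
}

#' @export
print.lca_em_fit <- function(x, ...) {
  cat(sprintf("Latent class EM fit: loglik = %.4f after %d iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

# moment-based start: prevalence from the mean marginal positivity rate,
# sensitivities above it, specificities near one minus it
em_moment_start <- function(panel) {
  pm <- pattern_matrix(panel$k)
  marg <- as.numeric(crossprod(pm, panel$counts) / panel$n)
  pi0 <- min(0.9, max(0.02, mean(marg)))
  s0 <- pmin(0.95, pmax(0.55, 0.5 + marg))
  c0 <- pmin(0.98, pmax(0.55, 1 - marg / 2))
  misclass_params(pi0, s0, c0)
}

em_run <- function(panel, start, tol, max_iter) {
  pm <- pattern_matrix(panel$k)
  cnt <- as.numeric(panel$counts)
  n <- panel$n
  pi <- start$pi; sens <- start$sens; spec <- start$spec
  eps <- 1e-12
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    cp <- lca_cell_probs(panel$k, pi, sens, spec)
    cell <- pmax(cp$cell, eps)
    # E-step: posterior case probability per pattern
    w <- pi * cp$pd / cell
    # M-step: weighted proportions
    nd <- sum(cnt * w)
    nh <- n - nd
    pi <- nd / n
    sens <- as.numeric(crossprod(pm, cnt * w)) / max(nd, eps)
    spec <- as.numeric(crossprod(1 - pm, cnt * (1 - w))) / max(nh, eps)
    pi <- min(1 - eps, max(eps, pi))
    sens <- pmin(1 - eps, pmax(eps, sens))
    spec <- pmin(1 - eps, pmax(eps, spec))
    ll <- sum(cnt * log(pmax(lca_cell_probs(panel$k, pi, sens, spec)$cell, eps)))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      ll_old <- max(ll, ll_old)
      break
    }
    ll_old <- ll
  }
  list(params = misclass_params(pi, sens, spec), loglik = ll_old,
       n_iter = it, converged = converged, loglik_trace = ll_trace)
}

# map a parameter set to the informative-test labeling (S_j + C_j > 1):
# if the majority of tests violate the constraint, apply the global mirror
# transform pi -> 1 - pi, S -> 1 - C, C -> 1 - S
relabel_informative <- function(params) {
  if (mean(params$sens + params$spec > 1) < 0.5) {
    misclass_params(1 - params$pi, 1 - params$spec, 1 - params$sens)
  } else {
    params
  }
}
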