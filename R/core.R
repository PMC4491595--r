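#' Apparent prevalence under imperfect testing
#'
#' Forward misclassification relation. A positive code arises either from a
#' true case detected (probability \eqn{\pi S}) or a non-case falsely coded
#' (probability \eqn{(1-\pi)(1-C)}), so the observable positivity rate is
#' \deqn{P = \pi S + (1 - \pi)(1 - C).}
#'
#' @param pi true prevalence, in \code{[0, 1]}.
#' @param sens test sensitivity S, in \code{[0, 1]}.
#' @param spec test specificity C, in \code{[0, 1]}.
#' @return The apparent prevalence P, in \code{[0, 1]}. Vectorized over its
#'   arguments under the usual recycling rules.
#' @seealso \code{\link{correct_prevalence}} for the inversion.
#' @examples
#' apparent_prevalence(0.005, sens = 0.995, spec = 0.995)
#' @export
apparent_prevalence <- function(pi, sens, spec) {
  check_prob(pi, "pi")
  check_prob(sens, "sens")
  check_prob(spec, "spec")
  pi * sens + (1 - pi) * (1 - spec)
}

#' Misclassification-corrected (Rogan-Gladen) prevalence
#'
#' Inverts the forward relation \eqn{P = \pi S + (1-\pi)(1-C)} to recover the
#' true prevalence from an observed positivity proportion:
#' \deqn{\pi = (P + C - 1) / (S + C - 1).}
#' When sensitivity and specificity are both 1 this reduces to \eqn{\pi = P},
#' the usual naive estimate. The raw inversion can fall outside \code{[0, 1]}
#' when the observed P lies outside the feasible interval
#' \code{[1 - C, S]} (possible by sampling noise alone); the result is then
#' clamped to \code{[0, 1]} with a warning. For a coherent treatment of that
#' situation use the Bayesian samplers instead
#' (\code{\link{single_test_gibbs}}).
#'
#' @param p observed (apparent) positivity proportion, in \code{[0, 1]}.
#' @param sens assumed sensitivity S.
#' @param spec assumed specificity C. Requires \code{sens + spec > 1}
#'   (an informative test); \code{S + C <= 1} is an error because the
#'   estimand is undefined there.
#' @return Corrected prevalence in \code{[0, 1]}. Vectorized.
#' @examples
#' # observed 1% positive with a test that is 99.5% sensitive and specific:
#' correct_prevalence(0.01, 0.995, 0.995)  # ~0.00505, i.e. 0.5%
#' @export
correct_prevalence <- function(p, sens, spec) {
  check_prob(p, "p")
  check_prob(sens, "sens")
  check_prob(spec, "spec")
  denom <- sens + spec - 1
  if (any(denom <= 0)) {
    stop("degenerate test: requires sens + spec > 1 (the correction is ",
         "undefined for an uninformative test)", call. = FALSE)
  }
  raw <- (p + spec - 1) / denom
  out <- pmin(1, pmax(0, raw))
  if (any(raw < 0 | raw > 1)) {
    warning("observed proportion outside the feasible interval [1 - spec, ",
            "sens]; corrected prevalence clamped to [0, 1]", call. = FALSE)
  }
  out
}

#' Identifiability accounting for a k-test latent class model
#'
#' A two-class latent class model for k conditionally independent binary
#' tests has \eqn{2k + 1} free parameters (one sensitivity and one
#' specificity per test, plus the prevalence), while the multinomial over the
#' \eqn{2^k} outcome patterns supplies \eqn{2^k - 1} degrees of freedom. The
#' model is identifiable from the data alone when the degrees of freedom are
#' at least the parameter count, i.e. for \eqn{k \ge 3}: three tests give
#' seven parameters and seven degrees of freedom, while a single test gives
#' three parameters but only one degree of freedom and requires external
#' (prior) information.
#'
#' @param k number of binary tests, integer \code{>= 1}.
#' @return An object of class \code{"identifiability_report"}: a list with
#'   \code{k}, \code{n_params}, \code{n_df} and logical \code{identifiable}.
#' @examples
#' identifiability(3)  # 7 parameters, 7 df, identifiable
#' identifiability(1)  # 3 parameters, 1 df, not identifiable
#' @export
identifiability <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != round(k)) {
    stop("'k' must be a single integer >= 1", call. = FALSE)
  }
  k <- as.integer(k)
  n_params <- 2L * k + 1L
  n_df <- 2^k - 1
  if (k <= 30L) n_df <- as.integer(n_df)  # exact integer when representable
  structure(list(k = k, n_params = n_params, n_df = n_df,
                 identifiable = n_df >= n_params),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat(sprintf(
    "k = %d tests: %d parameters, %d degrees of freedom -> %s\n",
    x$k, x$n_params, x$n_df,
    if (x$identifiable) "identifiable" else
      "NOT identifiable (external prior information required)"))
  invisible(x)
}
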