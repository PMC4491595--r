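#' Summarize posterior draws
#'
#' Per-parameter posterior summaries over all chains: mean, median,
#' standard deviation, an equal-tailed credible interval, the
#' Gelman-Rubin potential scale reduction factor (R-hat, from the
#' between/within chain variance decomposition) and an effective sample
#' size (autocorrelation sum truncated at the first negative pair, per
#' chain, summed over chains and capped at the number of retained draws).
#' With a single chain R-hat is reported as \code{NA}, not fabricated.
#'
#' @param draws a \code{\link{posterior_draws}} object.
#' @param level credible level in (0, 1); default 0.95 (equal-tailed).
#' @return A data.frame of class \code{"posterior_summary"} with one row
#'   per parameter: \code{mean}, \code{median}, \code{sd}, \code{lower},
#'   \code{upper}, \code{rhat}, \code{ess}.
#' @export
posterior_summary <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"),
            is.numeric(level), length(level) == 1L, level > 0, level < 1)
  d <- dim(draws$draws)
  if (d[1] * d[3] < 2L) {
    stop("need at least 2 retained draws to summarize", call. = FALSE)
  }
  a <- (1 - level) / 2
  pars <- dimnames(draws$draws)[[2]]
  rows <- lapply(seq_along(pars), function(p) {
    chain_mat <- draws$draws[, p, , drop = FALSE][, 1, , drop = TRUE]
    chain_mat <- matrix(chain_mat, nrow = d[1], ncol = d[3])
    x <- as.vector(chain_mat)
    q <- stats::quantile(x, c(a, 0.5, 1 - a), names = FALSE)
    data.frame(parameter = pars[p], mean = mean(x), median = q[2],
               sd = stats::sd(x), lower = q[1], upper = q[3],
               rhat = gelman_rhat(chain_mat),
               ess = ess_geyer(chain_mat),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "level") <- level
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' @export
print.posterior_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Posterior summary (%.0f%% equal-tailed intervals)\n",
              100 * attr(x, "level")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) R-hat from the between-chain variance of chain
#' means, B, and the mean within-chain variance, W:
#' \eqn{\hat{R} = \sqrt{((n-1)/n \cdot W + B/n)/W}}. Values near 1
#' indicate the chains agree; a common convergence rule of thumb is
#' R-hat < 1.1. Returns \code{NA} for a single chain (the statistic is
#' undefined) and 1 when all chains are constant.
#'
#' @param chain_mat numeric matrix, iterations by chains.
#' @return A single number, or \code{NA} for one chain.
#' @export
gelman_rhat <- function(chain_mat) {
  chain_mat <- as.matrix(chain_mat)
  m <- ncol(chain_mat); n <- nrow(chain_mat)
  if (m < 2L || n < 2L) return(NA_real_)
  W <- mean(apply(chain_mat, 2L, stats::var))
  B <- n * stats::var(colMeans(chain_mat))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size (initial positive sequence)
#'
#' Per-chain effective sample size n / (1 + 2 sum rho_t), with the
#' autocorrelation sum truncated at the first lag pair
#' (rho_{2t} + rho_{2t+1}) that is negative, summed over chains and
#' capped at the total number of draws.
#'
#' @param chain_mat numeric matrix, iterations by chains.
#' @return A single number \code{<=} the total number of draws.
#' @export
ess_geyer <- function(chain_mat) {
  chain_mat <- as.matrix(chain_mat)
  n <- nrow(chain_mat)
  if (n < 2L) return(length(chain_mat))
  per_chain <- vapply(seq_len(ncol(chain_mat)), function(c) {
    x <- chain_mat[, c]
    if (stats::sd(x) == 0) return(as.numeric(n))
    rho <- stats::acf(x, lag.max = min(n - 1L, 2000L), plot = FALSE,
                      demean = TRUE)$acf[-1L]
    s <- 0
    t <- 1L
    while (t + 1L <= length(rho)) {
      pair <- rho[t] + rho[t + 1L]
      if (is.na(pair) || pair < 0) break
      s <- s + pair
      t <- t + 2L
    }
    n / (1 + 2 * s)
  }, numeric(1))
  min(sum(per_chain), length(chain_mat))
}
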