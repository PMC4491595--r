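#' Cross-classified test panel counts
#'
#' Container for the counts of the \eqn{2^k} outcome patterns of \eqn{k}
#' binary diagnostic tests (or database "clues") applied to the same
#' population. Pattern indexing is fixed package-wide: test 1 is the most
#' significant bit and a bit value of 1 means a positive result, so for
#' \eqn{k = 3} the patterns run \code{"000", "001", ..., "111"} and
#' \code{"100"} means only test 1 positive.
#'
#' @param counts integer vector of \eqn{2^k} non-negative counts, ordered by
#'   the pattern convention above. Names, if present, are checked against the
#'   expected pattern strings.
#' @param k number of tests; defaults to \code{log2(length(counts))}.
#'
#' @return An object of class \code{"test_panel"}: a list with elements
#'   \code{k}, \code{counts} (named integer vector) and \code{n} (total).
#'
#' @examples
#' # 100 subjects screened with one test, 30 positive
#' test_panel(c(70, 30), k = 1)
#'
#' # a 2 x 2 x 2 table for three tests
#' test_panel(c(50, 4, 6, 2, 5, 3, 2, 28))
#' @export
test_panel <- function(counts, k = NULL) {
  if (is.null(k)) {
    k <- as.integer(round(log2(length(counts))))
  }
  if (length(k) != 1L || is.na(k) || k < 1L || k != round(k)) {
    stop("'k' must be a single integer >= 1", call. = FALSE)
  }
  k <- as.integer(k)
  if (length(counts) != 2^k) {
    stop(sprintf("'counts' must have length 2^k = %d, got %d",
                 2^k, length(counts)), call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("'counts' must be non-negative integers", call. = FALSE)
  }
  pat <- pattern_labels(k)
  if (!is.null(names(counts)) && !identical(names(counts), pat)) {
    stop("names of 'counts' do not match the fixed pattern order (test 1 = ",
         "most significant bit, 1 = positive)", call. = FALSE)
  }
  counts <- as.integer(round(counts))
  names(counts) <- pat
  structure(list(k = k, counts = counts, n = sum(counts)),
            class = "test_panel")
}

#' @export
print.test_panel <- function(x, ...) {
  cat(sprintf("Test panel: k = %d tests, n = %d subjects\n", x$k, x$n))
  print(x$counts)
  invisible(x)
}

#' Pattern labels and design matrix for k binary tests
#'
#' \code{pattern_labels} returns the \eqn{2^k} outcome-pattern strings in
#' canonical order; \code{pattern_matrix} returns the corresponding
#' \eqn{2^k \times k} 0/1 matrix (row r, column j = result of test j in
#' pattern r). Test 1 is the most significant bit; 1 = positive.
#'
#' @param k number of tests.
#' @return A character vector of length \eqn{2^k}, or a 0/1 matrix.
#' @examples
#' pattern_labels(2)   # "00" "01" "10" "11"
#' pattern_matrix(2)
#' @export
pattern_labels <- function(k) {
  apply(pattern_matrix(k), 1L, paste, collapse = "")
}

#' @rdname pattern_labels
#' @export
pattern_matrix <- function(k) {
  stopifnot(length(k) == 1L, k >= 1, k == round(k))
  k <- as.integer(k)
  r <- 0:(2^k - 1)
  m <- sapply(seq_len(k), function(j) bitwAnd(r, bitwShiftL(1L, k - j)) > 0L)
  m <- matrix(as.integer(m), nrow = 2^k, ncol = k)
  colnames(m) <- paste0("test_", seq_len(k))
  m
}

#' Apparent (observed) positivity proportion of a single-test panel
#'
#' For a one-test panel this is the observed proportion coded positive,
#' the quantity the misclassification correction operates on.
#'
#' @param panel a \code{\link{test_panel}} with \code{k = 1}.
#' @return The proportion of positives, \code{counts["1"]/n}.
#' @export
observed_proportion <- function(panel) {
  stopifnot(inherits(panel, "test_panel"))
  if (panel$k != 1L) {
    stop("observed_proportion() is defined for single-test panels (k = 1)",
         call. = FALSE)
  }
  unname(panel$counts["1"] / panel$n)
}

#' Misclassification parameters of a test panel
#'
#' Bundles the true prevalence \eqn{\pi} with the per-test sensitivities
#' \eqn{S_j} (probability a true case is coded positive) and specificities
#' \eqn{C_j} (probability a true non-case is coded negative).
#'
#' @param pi true prevalence, in \code{[0, 1]}.
#' @param sens numeric vector of k sensitivities, each in \code{[0, 1]}.
#' @param spec numeric vector of k specificities, same length as \code{sens}.
#' @return An object of class \code{"misclass_params"} with elements
#'   \code{pi}, \code{sens}, \code{spec}, \code{k}.
#' @examples
#' misclass_params(0.01, sens = c(0.9, 0.85, 0.8), spec = c(0.95, 0.9, 0.97))
#' @export
misclass_params <- function(pi, sens, spec) {
  check_prob(pi, "pi")
  check_prob(sens, "sens")
  check_prob(spec, "spec")
  if (length(pi) != 1L) stop("'pi' must be a single probability", call. = FALSE)
  if (length(sens) != length(spec)) {
    stop("'sens' and 'spec' must have the same length", call. = FALSE)
  }
  if (length(sens) < 1L) stop("need at least one test", call. = FALSE)
  structure(list(pi = pi, sens = as.numeric(sens), spec = as.numeric(spec),
                 k = length(sens)),
            class = "misclass_params")
}

#' @export
print.misclass_params <- function(x, ...) {
  cat(sprintf("Misclassification parameters (k = %d tests)\n", x$k))
  cat(sprintf("  prevalence pi = %.6g\n", x$pi))
  cat("  sensitivity:", format(x$sens, digits = 6), "\n")
  cat("  specificity:", format(x$spec, digits = 6), "\n")
  invisible(x)
}

#' A region label paired with its test panel
#'
#' @param region_id character scalar naming the region.
#' @param counts a \code{\link{test_panel}}.
#' @return An object of class \code{"region_panel"}.
#' @export
region_panel <- function(region_id, counts) {
  stopifnot(is.character(region_id), length(region_id) == 1L,
            inherits(counts, "test_panel"))
  structure(list(region_id = region_id, counts = counts),
            class = "region_panel")
}

#' @export
print.region_panel <- function(x, ...) {
  cat(sprintf("Region '%s':\n", x$region_id))
  print(x$counts)
  invisible(x)
}

# internal: validate probability arguments, naming the offender
check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be numeric in [0, 1]", name), call. = FALSE)
  }
  invisible(TRUE)
}

# internal: validate a list of region panels sharing one k
check_region_panels <- function(panels) {
  if (!is.list(panels) || length(panels) < 1L ||
      !all(vapply(panels, inherits, logical(1), "region_panel"))) {
    stop("'panels' must be a non-empty list of region_panel objects",
         call. = FALSE)
  }
  ks <- vapply(panels, function(p) p$counts$k, integer(1))
  if (length(unique(ks)) != 1L) {
    stop("all region panels must share the same number of tests k",
         call. = FALSE)
  }
  ids <- vapply(panels, function(p) p$region_id, character(1))
  if (anyDuplicated(ids)) {
    stop("region_id values must be unique", call. = FALSE)
  }
  invisible(ks[1L])
}
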