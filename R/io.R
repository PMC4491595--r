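#' Read cross-classified counts from CSV or JSON
#'
#' Two fixed dialects, matching what \code{\link{write_counts}} produces.
#' CSV: columns \code{test_1 .. test_k} holding 0/1 results plus a
#' \code{count} column, one row per observed pattern; an optional leading
#' \code{region} column turns the file into a multi-region collection.
#' JSON: an object mapping pattern strings (test 1 leftmost, "1" =
#' positive) to counts, e.g. \code{{"111": 10, "000": 90}}; for regions, an
#' object mapping region ids to such objects.
#'
#' Patterns absent from the file are filled in as zero counts with a
#' warning (sparse tables are expected at small n). Negative, non-integer
#' or duplicated patterns, or rows of inconsistent width, are parse errors.
#'
#' @param path file to read.
#' @param format \code{"csv"} or \code{"json"}; default inferred from the
#'   file extension.
#' @return A \code{\link{test_panel}}, or a list of
#'   \code{\link{region_panel}} when the file is region-keyed.
#' @export
read_counts <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- infer_format(path, format)
  if (format == "csv") read_counts_csv(path) else read_counts_json(path)
}

#' Write cross-classified counts to CSV or JSON
#'
#' @param x a \code{\link{test_panel}} or a list of
#'   \code{\link{region_panel}} objects.
#' @param path output file.
#' @param format \code{"csv"} or \code{"json"}; default inferred from the
#'   file extension.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{read_counts}} for the dialect; files written here
#'   always round-trip through it.
#' @export
write_counts <- function(x, path, format = NULL) {
  format <- infer_format(path, format)
  if (inherits(x, "test_panel")) {
    if (format == "csv") {
      df <- cbind(as.data.frame(pattern_matrix(x$k)),
                  count = as.integer(x$counts))
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    } else {
      obj <- as.list(as.integer(x$counts))
      names(obj) <- names(x$counts)
      jsonlite::write_json(obj, path, auto_unbox = TRUE)
    }
  } else if (is.list(x) && length(x) > 0 &&
             all(vapply(x, inherits, logical(1), "region_panel"))) {
    if (format == "csv") {
      dfs <- lapply(x, function(p) {
        cbind(region = p$region_id,
              as.data.frame(pattern_matrix(p$counts$k)),
              count = as.integer(p$counts$counts))
      })
      utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE,
                       quote = FALSE)
    } else {
      obj <- lapply(x, function(p) {
        o <- as.list(as.integer(p$counts$counts))
        names(o) <- names(p$counts$counts)
        o
      })
      names(obj) <- vapply(x, function(p) p$region_id, character(1))
      jsonlite::write_json(obj, path, auto_unbox = TRUE)
    }
  } else {
    stop("'x' must be a test_panel or a list of region_panel objects",
         call. = FALSE)
  }
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) {
    if (!format %in% c("csv", "json")) {
      stop("unsupported format '", format, "'; use \"csv\" or \"json\"",
           call. = FALSE)
    }
    return(format)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) return(ext)
  stop("cannot infer format from extension '", ext,
       "'; pass format = \"csv\" or \"json\"", call. = FALSE)
}

read_counts_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  has_region <- "region" %in% names(df)
  test_cols <- grep("^test_[0-9]+$", names(df), value = TRUE)
  k <- length(test_cols)
  if (k < 1L || !("count" %in% names(df)) ||
      !identical(sort(test_cols), sort(paste0("test_", seq_len(k))))) {
    stop("CSV must have columns test_1..test_k and count", call. = FALSE)
  }
  test_cols <- paste0("test_", seq_len(k))
  build <- function(sub, where) {
    bits <- as.matrix(sub[, test_cols, drop = FALSE])
    if (anyNA(bits) || !all(bits %in% c(0, 1))) {
      stop("test columns must be 0/1", if (nzchar(where)) paste0(" (", where, ")"),
           call. = FALSE)
    }
    cnt <- sub$count
    if (anyNA(cnt) || !is.numeric(cnt) || any(cnt < 0) ||
        any(cnt != round(cnt))) {
      stop("counts must be non-negative integers",
           if (nzchar(where)) paste0(" (", where, ")"), call. = FALSE)
    }
    idx <- as.integer(bits %*% 2^((k - 1):0)) + 1L
    if (anyDuplicated(idx)) {
      stop("duplicated outcome pattern in counts file",
           if (nzchar(where)) paste0(" (", where, ")"), call. = FALSE)
    }
    full <- integer(2^k)
    full[idx] <- as.integer(cnt)
    if (length(idx) < 2^k) {
      warning(sprintf("%d of %d patterns missing%s; filled with zero counts",
                      2^k - length(idx), 2^k,
                      if (nzchar(where)) paste0(" (", where, ")") else ""),
              call. = FALSE)
    }
    test_panel(full, k = k)
  }
  if (!has_region) return(build(df, ""))
  ids <- unique(df$region)
  lapply(ids, function(r) {
    region_panel(as.character(r), build(df[df$region == r, , drop = FALSE],
                                        paste0("region ", r)))
  })
}

read_counts_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(obj) || is.null(names(obj)) || length(obj) == 0L) {
    stop("JSON counts file must be a non-empty object", call. = FALSE)
  }
  nested <- all(vapply(obj, is.list, logical(1)))
  build <- function(o, where) {
    keys <- names(o)
    if (is.null(keys) || !all(grepl("^[01]+$", keys))) {
      stop("JSON keys must be 0/1 pattern strings",
           if (nzchar(where)) paste0(" (", where, ")"), call. = FALSE)
    }
    k <- unique(nchar(keys))
    if (length(k) != 1L) {
      stop("inconsistent pattern lengths (k) in JSON counts",
           if (nzchar(where)) paste0(" (", where, ")"), call. = FALSE)
    }
    vals <- unlist(o, use.names = FALSE)
    if (!is.numeric(vals) || anyNA(vals) || any(vals < 0) ||
        any(vals != round(vals))) {
      stop("counts must be non-negative integers",
           if (nzchar(where)) paste0(" (", where, ")"), call. = FALSE)
    }
    idx <- strtoi(keys, base = 2L) + 1L
    if (anyDuplicated(idx)) {
      stop("duplicated outcome pattern in counts file",
           if (nzchar(where)) paste0(" (", where, ")"), call. = FALSE)
    }
    full <- integer(2^k)
    full[idx] <- as.integer(vals)
    if (length(idx) < 2^k) {
      warning(sprintf("%d of %d patterns missing%s; filled with zero counts",
                      2^k - length(idx), 2^k,
                      if (nzchar(where)) paste0(" (", where, ")") else ""),
              call. = FALSE)
    }
    test_panel(full, k = as.integer(k))
  }
  if (!nested) return(build(obj, ""))
  panels <- lapply(names(obj), function(r) {
    region_panel(r, build(obj[[r]], paste0("region ", r)))
  })
  ks <- vapply(panels, function(p) p$counts$k, integer(1))
  if (length(unique(ks)) != 1L) {
    stop("regions declare inconsistent numbers of tests (k)", call. = FALSE)
  }
  panels
}

#' Write posterior draws to CSV
#'
#' Long-format draws table: columns \code{chain}, \code{iteration}, then
#' one column per parameter. Readable back with
#' \code{\link{read_draws}}.
#'
#' @param draws a \code{\link{posterior_draws}} object.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  d <- dim(draws$draws)
  tabs <- lapply(seq_len(d[3]), function(c) {
    m <- draws$draws[, , c, drop = FALSE][, , 1, drop = FALSE]
    dim(m) <- d[1:2]
    colnames(m) <- dimnames(draws$draws)[[2]]
    cbind(data.frame(chain = c, iteration = seq_len(d[1])), as.data.frame(m))
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read posterior draws written by \code{\link{write_draws}}
#'
#' @param path CSV file of draws.
#' @return A \code{\link{posterior_draws}} object (the stored draws with a
#'   reconstructed configuration stub).
#' @export
read_draws <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("chain", "iteration") %in% names(df))) {
    stop("draws file must have 'chain' and 'iteration' columns",
         call. = FALSE)
  }
  pars <- setdiff(names(df), c("chain", "iteration"))
  chains <- sort(unique(df$chain))
  n_kept <- max(df$iteration)
  arr <- array(NA_real_, dim = c(n_kept, length(pars), length(chains)),
               dimnames = list(NULL, pars, NULL))
  for (ci in seq_along(chains)) {
    sub <- df[df$chain == chains[ci], , drop = FALSE]
    sub <- sub[order(sub$iteration), , drop = FALSE]
    arr[, , ci] <- as.matrix(sub[, pars, drop = FALSE])
  }
  cfg <- mcmc_config(seed = 0L, n_iter = n_kept, burn_in = 0L,
                     n_chains = length(chains), thin = 1L)
  posterior_draws(arr, cfg, model = "stored")
}
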