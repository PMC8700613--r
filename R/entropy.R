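#' AAPE configuration
#'
#' Bundles the two tunable parameters of amplitude-aware permutation entropy:
#' the embedding dimension `m` (window length, so there are `factorial(m)`
#' possible ordinal patterns) and the amplitude-mix coefficient `K` in
#' \[0, 1\] weighting mean absolute amplitude (AA) against mean absolute
#' successive difference (RA) in each window's weight `K*AA + (1-K)*RA`.
#'
#' Defaults `m = 4`, `K = 0.5` are the values used for 190-sample BOLD
#' series, where the recommended series-length condition `N > 5*m!`
#' (190 > 120) holds. `m` outside 3..7, or a series shorter than `5*m!`,
#' triggers a warning, not an error.
#'
#' @param m integer embedding dimension, >= 2.
#' @param K amplitude-mix coefficient in \[0, 1\].
#' @return an object of class `aape_config`.
#' @examples
#' cfg <- aape_config()          # m = 4, K = 0.5
#' aape(rnorm(190), cfg)
#' @export
aape_config <- function(m = 4L, K = 0.5) {
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 2L)
    stop("m must be a single integer >= 2")
  if (length(K) != 1L || !is.finite(K) || K < 0 || K > 1)
    stop("K must be a single number in [0, 1]")
  if (m < 3L || m > 7L)
    warning("embedding dimension m = ", m,
            " is outside the recommended range 3..7")
  structure(list(m = m, K = K), class = "aape_config")
}

#' @export
print.aape_config <- function(x, ...) {
  cat(sprintf("AAPE config: m = %d (%d ordinal patterns), K = %g\n",
              x$m, factorial(x$m), x$K))
  invisible(x)
}

check_series <- function(x, m, what = "series") {
  if (!is.numeric(x)) stop(what, " must be numeric")
  bad <- which(!is.finite(x))
  if (length(bad))
    stop("non-finite value in ", what, " at index ", bad[1L])
  if (length(x) < m)
    stop(what, " length (", length(x), ") must be >= m (", m, ")")
  if (length(x) <= 5 * factorial(m))
    warning("series length ", length(x), " does not satisfy N > 5*m! = ",
            5 * factorial(m), "; entropy estimates may be unreliable")
  invisible(x)
}

#' Ordinal pattern of a window
#'
#' Returns the permutation of 0-based time offsets that sorts the window
#' ascending by value. Ties are broken by ascending time offset (stable
#' sort), so equal amplitudes keep their temporal order.
#'
#' @param window numeric vector of m finite samples.
#' @return integer vector: a permutation of `0:(m-1)`.
#' @examples
#' ordinal_pattern(c(2, 2, 1, 3))  # 2 0 1 3
#' @export
ordinal_pattern <- function(window) {
  if (!is.numeric(window)) stop("window must be numeric")
  bad <- which(!is.finite(window))
  if (length(bad))
    stop("non-finite value in window at index ", bad[1L])
  order(window, seq_along(window)) - 1L
}

#' Window amplitude summaries
#'
#' Mean absolute amplitude (AA) and mean absolute successive difference
#' (RA) of a window; these enter the window weight as `K*AA + (1-K)*RA`.
#' Magnitudes are used throughout so weights are non-negative and the
#' weighted pattern frequencies are valid probabilities.
#'
#' @param window numeric vector of m >= 2 finite samples.
#' @return list with elements `AA` and `RA`.
#' @examples
#' window_amplitudes(1:4)  # AA = 2.5, RA = 1
#' @export
window_amplitudes <- function(window) {
  if (length(window) < 2L)
    stop("window must have at least 2 samples (RA undefined for m < 2)")
  bad <- which(!is.finite(window))
  if (length(bad))
    stop("non-finite value in window at index ", bad[1L])
  list(AA = mean(abs(window)), RA = mean(abs(diff(window))))
}

pattern_label <- function(perm) paste(perm, collapse = "")

#' Weighted ordinal-pattern distribution
#'
#' Slides a window of length `m` along the series, assigns each window its
#' ordinal pattern, and accumulates the amplitude weight `K*AA + (1-K)*RA`
#' per pattern. Weights are normalized to a probability distribution over
#' the observed patterns.
#'
#' For an identically-zero series every weight is zero; the function then
#' returns the degenerate distribution putting mass 1 on the single
#' (identity) pattern and sets the `degenerate` attribute.
#'
#' @param x numeric series of length N >= m.
#' @param config an [aape_config].
#' @return data.frame with columns `pattern` (offsets concatenated, e.g.
#'   `"0213"`) and `p`, ordered by decreasing `p`; attribute `degenerate`
#'   is `TRUE` for the zero-weight case.
#' @examples
#' pattern_distribution(c(1, 3, 2, 4, 2), aape_config(m = 3))
#' @export
pattern_distribution <- function(x, config = aape_config()) {
  m <- config$m; K <- config$K
  suppressWarnings(check_series(x, m))
  n <- length(x)
  nwin <- n - m + 1L
  # rows = windows in time order, cols = offsets 0..m-1
  W <- matrix(x[outer(seq_len(nwin), 0:(m - 1L), `+`)], nrow = nwin)
  R <- matrix(0L, nwin, m)
  for (j in seq_len(m)) for (k in seq_len(m)) {
    if (k == j) next
    R[, j] <- R[, j] + (W[, k] < W[, j]) + if (k < j) (W[, k] == W[, j]) else 0L
  }
  code <- as.vector(R %*% m^(0:(m - 1L)))
  AA <- rowMeans(abs(W))
  RA <- rowMeans(abs(W[, -1L, drop = FALSE] - W[, -m, drop = FALSE]))
  w <- K * AA + (1 - K) * RA
  tot <- sum(w)
  degenerate <- tot == 0
  if (degenerate) {
    # zero series: every window is the identity pattern
    out <- data.frame(pattern = pattern_label(0:(m - 1L)), p = 1)
  } else {
    agg <- rowsum(w, group = code)
    codes <- as.integer(rownames(agg))
    perms <- vapply(codes, function(cd) {
      ranks <- (cd %/% m^(0:(m - 1L))) %% m
      pattern_label(order(ranks) - 1L)
    }, character(1L))
    out <- data.frame(pattern = perms, p = as.vector(agg) / tot)
    out <- out[order(-out$p, out$pattern), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "degenerate") <- degenerate
  attr(out, "m") <- m
  out
}

#' Amplitude-aware permutation entropy
#'
#' Shannon entropy (nats) of the amplitude-weighted ordinal-pattern
#' distribution, with the convention `0*log(0) = 0`. Values lie in
#' `[0, log(factorial(m))]`; 0 means a single pattern carries all weight
#' (e.g. a monotone series), the upper bound is approached by long
#' i.i.d. noise. AAPE is invariant to positive rescaling of the series.
#'
#' The degenerate identically-zero series yields 0 with a warning.
#'
#' @param x numeric series (length N >= m) or a matrix with one series per
#'   row (all rows share the config).
#' @param config an [aape_config].
#' @param normalized if `TRUE`, divide by `log(factorial(m))` so the result
#'   lies in \[0, 1\]. Default `FALSE` (raw nats).
#' @return numeric entropy value, or a vector (one per row) for matrix
#'   input.
#' @examples
#' aape(sin(2 * pi * 0.05 * 3 * (1:190)))   # regular: low entropy
#' aape(rnorm(190))                         # noise: near log(24)
#' @export
aape <- function(x, config = aape_config(), normalized = FALSE) {
  entropy_dispatch(x, config, weighted = TRUE, normalized = normalized)
}

#' Permutation entropy (unweighted baseline)
#'
#' Shannon entropy (nats) of the plain ordinal-pattern relative
#' frequencies: every window counts with weight 1. Equal to [aape] whenever
#' all windows share the same amplitude weight.
#'
#' @inheritParams aape
#' @param m embedding dimension.
#' @return numeric entropy value, or a vector for matrix input.
#' @export
permutation_entropy <- function(x, m = 4L, normalized = FALSE) {
  entropy_dispatch(x, aape_config(m = m), weighted = FALSE,
                   normalized = normalized)
}

entropy_dispatch <- function(x, config, weighted, normalized) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (!is.numeric(X)) stop("input must be numeric")
  if (ncol(X) < config$m)
    stop("series length (", ncol(X), ") must be >= m (", config$m, ")")
  if (ncol(X) <= 5 * factorial(config$m))
    warning("series length ", ncol(X), " does not satisfy N > 5*m! = ",
            5 * factorial(config$m), "; entropy estimates may be unreliable")
  res <- .aape_engine(X, config$m, config$K, weighted)
  if (any(res$degenerate))
    warning(sum(res$degenerate),
            " series had zero total weight (identically zero);",
            " entropy reported as 0")
  h <- res$entropy
  if (normalized) h <- h / log(factorial(config$m))
  if (is.matrix(x)) h else h[[1L]]
}

#' Read time series from a delimited table
#'
#' Reads a CSV/TSV file with a header row and one series per column, for
#' standalone entropy analysis outside the imaging pipeline.
#'
#' @param path file path; delimiter inferred from the extension (`.csv` =
#'   comma, otherwise tab).
#' @return named list of numeric vectors, one per column.
#' @export
read_series_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  lapply(as.list(df), as.numeric)
}
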