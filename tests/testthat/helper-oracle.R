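# Brute-force transcription of the AAPE definition, kept deliberately
# naive (explicit window loop, per-window sums, named accumulation) and
# independent of the package's vectorized/C++ path. Used as the oracle.

`%||%` <- function(a, b) if (is.null(a)) b else a

aape_oracle_dist <- function(x, m, K) {
  N <- length(x)
  acc <- list()
  for (i in 1:(N - m + 1)) {
    v <- x[i:(i + m - 1)]
    AA <- sum(abs(v)) / m
    RA <- 0
    for (l in 2:m) RA <- RA + abs(v[l] - v[l - 1])
    RA <- RA / (m - 1)
    w <- K * AA + (1 - K) * RA
    # stable ascending order: value, then time offset
    key <- paste(order(v, seq_along(v)) - 1L, collapse = "")
    acc[[key]] <- (acc[[key]] %||% 0) + w
  }
  ws <- unlist(acc)
  tot <- sum(ws)
  if (tot == 0) return(NULL)
  ws / tot
}

aape_oracle <- function(x, m, K) {
  p <- aape_oracle_dist(x, m, K)
  if (is.null(p)) return(0)
  p <- p[p > 0]
  -sum(p * log(p))
}

pe_oracle <- function(x, m) {
  N <- length(x)
  keys <- character(N - m + 1)
  for (i in 1:(N - m + 1)) {
    v <- x[i:(i + m - 1)]
    keys[i] <- paste(order(v, seq_along(v)) - 1L, collapse = "")
  }
  p <- table(keys) / length(keys)
  -sum(p * log(p))
}
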