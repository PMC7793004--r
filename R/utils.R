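## Small numerical utilities shared across modules.

.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Row-wise logsumexp of a matrix; returns vector of length nrow.
.rowLogSumExp <- function(m) {
  mx <- apply(m, 1L, max)
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(m - mx)))
  out[bad] <- mx[bad]
  out
}

## Deterministic sub-seed derivation, kept below 2^31.
.subSeed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629
}

## Centred frequency values for side N: index i (1-based) -> i - 1 - N/2.
.freqValues <- function(n) seq_len(n) - 1 - n %/% 2

## fftshift for even side: swap halves along each of the first `ndim` axes.
## For even N the forward and inverse shifts coincide.
.centerShift <- function(a, ndim = length(dim(a))) {
  d <- dim(a)
  idx <- lapply(seq_along(d), function(i) {
    if (i <= ndim) {
      n <- d[i]
      c((n %/% 2 + 1):n, 1:(n %/% 2))
    } else seq_len(d[i])
  })
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}
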