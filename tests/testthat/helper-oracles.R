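# Brute-force oracles: naive loop implementations of the Hankel embedding,
# anti-diagonal averaging and rank-selected reconstruction, kept deliberately
# independent of the package's vectorized/FFT-based code paths.

oracle_hankel <- function(x) {
  n <- length(x)
  L <- ceiling(n / 2)
  K <- n - L + 1L
  H <- matrix(NA_real_, L, K)
  for (i in seq_len(L)) {
    for (j in seq_len(K)) H[i, j] <- x[i + j - 1L]
  }
  H
}

oracle_antidiag_average <- function(M) {
  L <- nrow(M); K <- ncol(M); n <- L + K - 1L
  out <- numeric(n)
  for (t in seq_len(n)) {
    vals <- c()
    for (i in seq_len(L)) {
      j <- t - i + 1L
      if (j >= 1L && j <= K) vals <- c(vals, M[i, j])
    }
    out[t] <- mean(vals)
  }
  out
}

# reconstruction from an explicit sum of rank-1 terms of svd(H), looped
oracle_reconstruct <- function(x, kept) {
  H <- oracle_hankel(x)
  s <- svd(H)
  M <- matrix(0, nrow(H), ncol(H))
  for (i in kept) M <- M + s$d[i] * s$u[, i] %*% t(s$v[, i])
  oracle_antidiag_average(M)
}

# the pipeline's pre-filter, for tests that feed windows to the quality gate
# the way process_record() does
prefilter <- function(x, fs = 125) hankelppg:::bandpass_filter(x, fs, c(0.4, 10))

make_peak_set <- function(n_peaks, n_valleys, fs = 125) {
  structure(list(peak_indices = seq_len(n_peaks) * 100L,
                 valley_indices = seq_len(n_valleys) * 100L + 50L,
                 intervals_s = rep(100 / fs, max(0L, n_peaks - 1L))),
            class = "peak_set")
}
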