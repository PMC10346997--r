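# Motion-artifact removal by Hankel embedding + SVD (singular spectrum
# analysis with an accelerometer-referenced component-rejection rule).
#
# A window of N samples is embedded into the L x K trajectory (Hankel) matrix
# with L = ceiling(N/2), K = N - L + 1 (so an even N = 2n gives n x (n+1),
# covering every sample), decomposed by SVD, and mapped back to time series
# per component by anti-diagonal averaging. Components whose time courses
# correlate with the acceleration channels are discarded before
# reconstruction.

#' Build the Hankel (trajectory) matrix of a series
#'
#' `H[i, j] = x[i + j - 1]`, with `L = ceiling(N/2)` rows and
#' `K = N - L + 1` columns so that every sample of the series appears.
#'
#' @param series numeric vector, length >= 4.
#' @return An `L x K` numeric matrix.
#' @examples
#' build_hankel(1:4)   # 2 x 3
#' @export
build_hankel <- function(series) {
  n <- length(series)
  if (n < 4L) stop("series too short for Hankel embedding: need >= 4 samples")
  L <- ceiling(n / 2)
  K <- n - L + 1L
  matrix(series[outer(seq_len(L), seq_len(K) - 1L, "+")], L, K)
}

#' Anti-diagonal averaging (Hankelization) of a matrix
#'
#' Maps an arbitrary `L x K` matrix back to a series of length `L + K - 1` by
#' averaging each anti-diagonal; the exact inverse of [build_hankel()] for
#' Hankel matrices, and the standard recovery step for rank-truncated
#' reconstructions.
#'
#' @param M numeric matrix.
#' @return Numeric vector of length `nrow(M) + ncol(M) - 1`.
#' @export
hankel_to_series <- function(M) {
  idx <- as.vector(row(M) + col(M)) - 1L          # anti-diagonal id: 1..L+K-1
  sums <- rowsum(as.vector(M), idx)
  counts <- tabulate(idx, nbins = nrow(M) + ncol(M) - 1L)
  as.vector(sums) / counts
}

#' Hankel-SVD decomposition of a channel
#'
#' Builds the trajectory matrix of the series and takes its singular value
#' decomposition `H = U diag(S) V'` with singular values sorted
#' non-increasing; rank `r = min(L, K)`.
#'
#' @param series numeric vector, length >= 4.
#' @param channel_name label used in error messages and reports.
#' @return A list of class `hankel_svd`: `u` (L x r), `d` (singular values),
#'   `v` (K x r), `L`, `K`, `n_samples`, `series`, `channel_name`.
#' @export
hankel_decompose <- function(series, channel_name = "ppg") {
  H <- build_hankel(series)
  dec <- tryCatch(svd(H), error = function(e) {
    stop("SVD failed on channel '", channel_name, "': ", conditionMessage(e))
  })
  structure(list(u = dec$u, d = dec$d, v = dec$v,
                 L = nrow(H), K = ncol(H), n_samples = length(series),
                 series = as.numeric(series), channel_name = channel_name),
            class = "hankel_svd")
}

#' @export
print.hankel_svd <- function(x, ...) {
  e <- x$d^2 / sum(x$d^2)
  cat(sprintf("<hankel_svd '%s'> %d samples -> %d x %d, rank %d\n",
              x$channel_name, x$n_samples, x$L, x$K, length(x$d)))
  cat(sprintf("  top singular values: %s (energy of first 4: %.1f%%)\n",
              paste(sprintf("%.3g", head(x$d, 4L)), collapse = ", "),
              100 * sum(head(e, 4L))))
  invisible(x)
}

# all component series at once: anti-diagonal averaging of each rank-1 term
# s_i * u_i v_i' reduces to the convolution u_i * v_i, done batched via FFT
component_matrix <- function(hsvd) {
  L <- hsvd$L; K <- hsvd$K; n <- hsvd$n_samples
  m <- stats::nextn(L + K - 1L, 2L)
  U <- rbind(hsvd$u, matrix(0, m - L, ncol(hsvd$u)))
  V <- rbind(hsvd$v, matrix(0, m - K, ncol(hsvd$v)))
  conv <- Re(stats::mvfft(stats::mvfft(U) * stats::mvfft(V),
                          inverse = TRUE))[seq_len(n), , drop = FALSE] / m
  counts <- pmin(seq_len(n), L, K, n - seq_len(n) + 1L)
  sweep(conv, 2L, hsvd$d, `*`) / counts
}

#' Time series of one SVD component
#'
#' Anti-diagonal averaging of the rank-1 term `S[i] * U[, i] V[, i]'`. The
#' component series sum to the original series (SVD completeness).
#'
#' @param hsvd a [hankel_decompose()] result.
#' @param i component index, 1-based, `1 <= i <= length(hsvd$d)`.
#' @return Numeric vector of length `hsvd$n_samples`.
#' @export
component_series <- function(hsvd, i) {
  stopifnot(inherits(hsvd, "hankel_svd"))
  if (i < 1L || i > length(hsvd$d)) {
    stop("component index out of range: ", i, " (rank ", length(hsvd$d), ")")
  }
  M <- hsvd$d[i] * tcrossprod(hsvd$u[, i], hsvd$v[, i])
  hankel_to_series(M)
}

#' Pearson correlation with degenerate-input handling
#'
#' Standard product-moment correlation; if either input has zero variance the
#' coefficient is undefined and is reported as 0 with attribute
#' `degenerate = TRUE` (a constant component carries no motion information).
#'
#' @param x,y equal-length numeric vectors, length >= 2.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (sd(x) == 0 || sd(y) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  cor(x, y)
}

# column-standardize, mapping zero-variance columns to all-zero columns so
# that their correlations come out 0 rather than NA
safe_scale <- function(M) {
  S <- scale(M)
  S[!is.finite(S)] <- 0
  S
}

# reference series set per accel axis used for component rejection:
# raw_accel mode uses the raw axis; accel_components mode uses the dominant
# Hankel-SVD component series of that axis (singular value >= 5% of its
# largest, capped), which separates cadence harmonics and quadrature pairs
# into near-pure reference tones.
accel_references <- function(accel, mode, max_ref = 12L) {
  lapply(seq_len(ncol(accel)), function(a) {
    ax <- accel[, a]
    if (mode == "raw_accel" || sd(ax) == 0) {
      return(matrix(ax, ncol = 1L))
    }
    dec <- hankel_decompose(ax, channel_name = c("ax", "ay", "az")[a])
    keep <- which(dec$d >= 0.05 * dec$d[1L])
    keep <- head(keep, max_ref)
    component_matrix(dec)[, keep, drop = FALSE]
  })
}

#' Select PPG components correlated with the accelerometer
#'
#' Computes, for every PPG component, its Pearson correlation against each
#' acceleration axis (raw axis, or the axis's dominant Hankel-SVD component
#' series, see `mode`) and removes the components whose maximal absolute
#' correlation reaches `threshold` - strongest correlations first, at most
#' `max_remove` of them, and always keeping at least one component.
#'
#' @param hsvd [hankel_decompose()] of the PPG window.
#' @param accel n x 3 matrix of acceleration samples aligned with the window.
#' @param threshold correlation cutoff in (0, 1); default 0.5.
#' @param max_remove cap on removed components; default rank - 1.
#' @param mode `"accel_components"` (default) correlates against each axis's
#'   dominant component series, which is robust to the quadrature-pair phase
#'   of oscillatory components and to multi-harmonic cadence spectra;
#'   `"raw_accel"` correlates against the raw axes.
#' @return A list of class `component_selection`: `kept`, `removed` (1-based
#'   index vectors), `corr_matrix` (rank x 3, the signed correlation whose
#'   magnitude is maximal for that axis), `threshold`.
#' @export
select_components <- function(hsvd, accel, threshold = 0.5,
                              max_remove = NULL,
                              mode = c("accel_components", "raw_accel")) {
  stopifnot(inherits(hsvd, "hankel_svd"))
  mode <- match.arg(mode)
  accel <- as.matrix(accel)
  if (nrow(accel) != hsvd$n_samples || ncol(accel) != 3L) {
    stop("accel must be a ", hsvd$n_samples, " x 3 matrix aligned with the window")
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("correlation threshold must lie strictly between 0 and 1")
  }
  r <- length(hsvd$d)
  if (is.null(max_remove)) max_remove <- r - 1L

  comp <- component_matrix(hsvd)
  n <- nrow(comp)
  compS <- safe_scale(comp)
  refs <- accel_references(accel, mode)
  corr_matrix <- matrix(0, r, 3L, dimnames = list(NULL, c("ax", "ay", "az")))
  for (a in 1:3) {
    refS <- safe_scale(refs[[a]])
    cc <- crossprod(compS, refS) / (n - 1L)       # r x n_ref correlations
    pick <- max.col(abs(cc), ties.method = "first")
    corr_matrix[, a] <- cc[cbind(seq_len(r), pick)]
  }

  strength <- apply(abs(corr_matrix), 1L, max)
  cand <- which(strength >= threshold)
  cand <- cand[order(strength[cand], decreasing = TRUE)]
  removed <- head(cand, max_remove)
  if (length(removed) == r) {                      # never drop everything
    removed <- removed[-length(removed)]
  }
  removed <- sort(removed)
  structure(list(kept = setdiff(seq_len(r), removed), removed = removed,
                 corr_matrix = corr_matrix, threshold = threshold,
                 mode = mode),
            class = "component_selection")
}

#' @export
print.component_selection <- function(x, ...) {
  cat(sprintf("<component_selection> removed %d of %d components (|rho| >= %.2f, mode %s)\n",
              length(x$removed), nrow(x$corr_matrix), x$threshold, x$mode))
  invisible(x)
}

#' Reconstruct a series from selected components
#'
#' Sums the anti-diagonal-averaged series of the kept components; with all
#' components kept this reproduces the original series (to numerical
#' round-off).
#'
#' @param hsvd a [hankel_decompose()] result.
#' @param selection a [select_components()] result, or an integer vector of
#'   kept component indices.
#' @return Numeric vector of length `hsvd$n_samples`.
#' @export
reconstruct_series <- function(hsvd, selection) {
  stopifnot(inherits(hsvd, "hankel_svd"))
  kept <- if (inherits(selection, "component_selection")) selection$kept
          else as.integer(selection)
  r <- length(hsvd$d)
  if (length(kept) == 0L) stop("cannot reconstruct from an empty component set")
  if (any(kept < 1L | kept > r)) stop("kept indices out of range 1..", r)
  M <- hsvd$u[, kept, drop = FALSE] %*%
    (hsvd$d[kept] * t(hsvd$v[, kept, drop = FALSE]))
  hankel_to_series(M)
}
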