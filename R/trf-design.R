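# Lagged design matrix: the discrete convolution R(t) = sum_l TRF(l) S(t-l)
# written as a linear system. Columns are ordered feature-major (all lags of
# feature 1, then feature 2, ...), lags ascending.

#' Specify the TRF lag axis
#'
#' @param lag_min_ms,lag_max_ms Lag range in ms (response relative to
#'   stimulus; positive = stimulus precedes response). The default -200 to
#'   800 ms brackets the 200-600 ms trough search window with margin.
#' @param fs Sampling rate the lags are realized on.
#' @return A `lag_window` with the realized sample lags and their ms values.
#' @export
lag_window <- function(lag_min_ms = -200, lag_max_ms = 800, fs = 128) {
  if (lag_min_ms >= lag_max_ms) stopf("lag_min_ms must be below lag_max_ms")
  lags <- seq(as.integer(round(lag_min_ms * fs / 1000)),
              as.integer(round(lag_max_ms * fs / 1000)))
  structure(list(lag_min_ms = lag_min_ms, lag_max_ms = lag_max_ms, fs = fs,
                 lags = lags, lag_ms = lags * 1000 / fs),
            class = "lag_window")
}

#' Build the lagged (sparse) design matrix
#'
#' Column (f, l) holds feature f delayed by l samples: `X[t, (f,l)] =
#' s_f[t - l]`, zero-padded outside the trial. Multiplying by a stacked
#' kernel vector reproduces the convolution of each feature with its kernel.
#'
#' @param features List of `feature_impulse_series` (same fs and length).
#' @param lags A [lag_window()] (or integer vector of sample lags).
#' @return Sparse dgCMatrix (samples x n_features * n_lags) with attributes
#'   `feature_names`, `n_lags`, `lags`.
#' @export
build_lagged_design <- function(features, lags) {
  if (inherits(features, "feature_impulse_series")) features <- list(features)
  lag_s <- if (inherits(lags, "lag_window")) lags$lags else as.integer(lags)
  n <- unique(vapply(features, function(f) length(f$values), 0L))
  if (length(n) != 1L) stopf("features have mismatched lengths")
  if (length(lag_s) >= n) stopf("lag window (%d samples) exceeds trial length (%d)",
                                length(lag_s), n)
  nf <- length(features)
  nl <- length(lag_s)

  ii <- list(); jj <- list(); xx <- list()
  for (f in seq_len(nf)) {
    nz <- which(features[[f]]$values != 0)
    v <- features[[f]]$values[nz]
    for (li in seq_len(nl)) {
      rows <- nz + lag_s[li]
      keep <- rows >= 1L & rows <= n
      ii[[length(ii) + 1L]] <- rows[keep]
      jj[[length(jj) + 1L]] <- rep.int((f - 1L) * nl + li, sum(keep))
      xx[[length(xx) + 1L]] <- v[keep]
    }
  }
  X <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, nf * nl))
  attr(X, "feature_names") <- vapply(features, function(f) f$name, "")
  attr(X, "n_lags") <- nl
  attr(X, "lags") <- lag_s
  attr(X, "fs") <- features[[1]]$fs
  X
}
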