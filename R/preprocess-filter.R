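# Temporal preprocessing: Butterworth band-pass (zero-phase, forward and
# backward) and anti-aliased resampling. Filter design follows the classic
# analog-prototype -> band transform -> bilinear route.

# analog Butterworth lowpass prototype poles (unit cutoff), order n
butter_prototype <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# zpk lowpass(1 rad/s) -> bandpass(w1..w2 rad/s), then bilinear at rate fs2
butter_bandpass_coef <- function(lo, hi, order, fs) {
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * lo / fs)        # prewarped band edges
  w2 <- fs2 * tan(pi * hi / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)

  p <- butter_prototype(order) * bw / 2
  pbp <- c(p + sqrt(p^2 - w0^2), p - sqrt(p^2 - w0^2))
  zbp <- rep(0 + 0i, order)
  kbp <- bw^order

  # bilinear transform
  zd <- (fs2 + zbp) / (fs2 - zbp)
  pd <- (fs2 + pbp) / (fs2 - pbp)
  kd <- kbp * Re(prod(fs2 - zbp) / prod(fs2 - pbp))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))

  poly_from_roots <- function(r) {
    p <- 1 + 0i
    for (rt in r) p <- c(p, 0) - c(0, p * rt)
    p
  }
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# direct-form II transposed IIR filter; x may be a matrix (filters columns)
iir_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b); na <- length(a)
  if (is.matrix(x)) {
    n <- nrow(x); m <- ncol(x)
    z <- matrix(0, max(na, nb) - 1, m)
    y <- matrix(0, n, m)
    for (t in seq_len(n)) {
      xt <- x[t, ]
      yt <- b[1] * xt + z[1, ]
      for (j in seq_len(nrow(z) - 1)) {
        z[j, ] <- (if (j + 1 <= nb) b[j + 1] * xt else 0) + z[j + 1, ] -
          (if (j + 1 <= na) a[j + 1] * yt else 0)
      }
      j <- nrow(z)
      z[j, ] <- (if (j + 1 <= nb) b[j + 1] * xt else 0) -
        (if (j + 1 <= na) a[j + 1] * yt else 0)
      y[t, ] <- yt
    }
    y
  } else {
    iir_filter(b, a, matrix(x, ncol = 1))[, 1]
  }
}

# zero-phase filtering: odd-symmetric edge padding, forward then reverse pass
filtfilt_mat <- function(b, a, x) {
  single <- !is.matrix(x)
  if (single) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  padlen <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 4L)
  pre <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
    x[seq(padlen + 1, 2), , drop = FALSE]
  post <- 2 * matrix(x[n, ], padlen, ncol(x), byrow = TRUE) -
    x[seq(n - 1, n - padlen), , drop = FALSE]
  ext <- rbind(pre, x, post)
  y <- iir_filter(b, a, ext)
  y <- iir_filter(b, a, y[rev(seq_len(nrow(y))), , drop = FALSE])
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y <- y[seq(padlen + 1, padlen + n), , drop = FALSE]
  if (single) y[, 1] else y
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-`order` Butterworth band-pass applied forward and backward
#' (two passes: zero phase shift, squared magnitude response). The default
#' 0.5-8 Hz band isolates the slow cortical dynamics word-level responses
#' live in while rejecting drift and alpha.
#'
#' @param rec An [eeg_recording()] (or numeric vector/matrix with `fs`).
#' @param lo,hi Band edges in Hz.
#' @param order Filter order per pass.
#' @param fs Sampling rate, required when `rec` is not an `eeg_recording`.
#' @return Same type as `rec`, filtered.
#' @export
bandpass <- function(rec, lo = 0.5, hi = 8, order = 4L, fs = NULL) {
  if (inherits(rec, "eeg_recording")) {
    out <- rec
    out$data <- t(bandpass(t(rec$data), lo, hi, order, fs = rec$fs))
    rownames(out$data) <- rec$channel_labels
    return(out)
  }
  if (is.null(fs)) stopf("fs must be given for plain numeric input")
  if (!(0 < lo && lo < hi && hi < fs / 2)) {
    stopf("invalid band [%g, %g] Hz at fs = %g", lo, hi, fs)
  }
  co <- butter_bandpass_coef(lo, hi, order, fs)
  filtfilt_mat(co$b, co$a, rec)
}

# Kaiser-windowed sinc lowpass FIR (for resampling anti-aliasing)
kaiser_sinc <- function(ntaps, cutoff, fs, beta = 8.6) {
  m <- ntaps - 1
  n <- seq(0, m)
  x <- 2 * n / m - 1
  win <- besselI(beta * sqrt(pmax(0, 1 - x^2)), 0) / besselI(beta, 0)
  fc <- cutoff / (fs / 2)              # normalized to Nyquist
  h <- fc * sinc_fn(fc * (n - m / 2)) * win
  h / sum(h)
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Anti-aliased downsampling
#'
#' Rational-rate polyphase-style resampling: zero-stuff by `p`, apply a
#' Kaiser-windowed sinc low-pass at the smaller of the two Nyquist rates,
#' then keep every `q`-th sample. Duration is preserved within one sample.
#'
#' @param rec An [eeg_recording()] (or numeric vector/matrix with `fs`).
#' @param target_fs Output rate (must not exceed `fs`).
#' @param fs Input rate for plain numeric input.
#' @export
downsample <- function(rec, target_fs = 128, fs = NULL) {
  if (inherits(rec, "eeg_recording")) {
    out <- rec
    out$data <- t(downsample(t(rec$data), target_fs, fs = rec$fs))
    rownames(out$data) <- rec$channel_labels
    out$fs <- target_fs
    return(out)
  }
  if (is.null(fs)) stopf("fs must be given for plain numeric input")
  if (target_fs > fs) stopf("target rate %g exceeds input rate %g", target_fs, fs)
  if (target_fs == fs) return(rec)
  single <- !is.matrix(rec)
  x <- if (single) matrix(rec, ncol = 1) else rec

  frac <- gcd_frac(target_fs, fs)
  p <- frac[1]; q <- frac[2]            # target/fs = p/q in lowest terms
  n <- nrow(x)
  if (p > 1) {
    up <- matrix(0, n * p, ncol(x))
    up[seq(1, n * p, by = p), ] <- x * p
    x <- up
  }
  fs_up <- fs * p
  cutoff <- 0.45 * min(fs, target_fs)   # guard band below output Nyquist
  ntaps <- 2L * as.integer(round(4 * fs_up / cutoff)) + 1L
  h <- kaiser_sinc(ntaps, cutoff, fs_up)
  delay <- (ntaps - 1L) / 2L
  y <- apply(x, 2, function(col) fft_convolve(col, h))
  y <- y[seq(delay + 1L, delay + nrow(x)), , drop = FALSE]
  out_n <- as.integer(ceiling(n * p / q))
  idx <- 1L + q * (seq_len(out_n) - 1L)
  idx <- idx[idx <= nrow(y)]
  y <- y[idx, , drop = FALSE]
  if (single) y[, 1] else y
}

gcd_frac <- function(a, b) {
  # integerize rates (handles e.g. 62.5) then reduce
  k <- 1
  while (abs(a * k - round(a * k)) > 1e-9 || abs(b * k - round(b * k)) > 1e-9) {
    k <- k * 10
    if (k > 1e6) stopf("rates %g and %g are not rationally related", a, b)
  }
  ai <- round(a * k); bi <- round(b * k)
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  d <- g(ai, bi)
  c(ai / d, bi / d)
}

fft_convolve <- function(x, h) {
  n <- length(x); m <- length(h)
  N <- stats::nextn(n + m - 1L, 2)
  Re(stats::fft(stats::fft(c(x, numeric(N - n))) *
                stats::fft(c(h, numeric(N - m))), inverse = TRUE))[seq_len(n + m - 1L)] / N
}
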