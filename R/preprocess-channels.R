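# Spatial preprocessing: noisy-channel detection, spherical-spline
# interpolation over a unit-sphere sensor layout, and mastoid referencing.

#' Detect noisy channels by the leave-one-out standard-deviation rule
#'
#' A channel is flagged when its standard deviation is more than `factor`
#' times the mean standard deviation of all other channels, or less than that
#' mean divided by `factor`. Applied per trial; the rule is channel-count
#' agnostic.
#'
#' @param rec An [eeg_recording()] (scalp channels only are examined; mastoid
#'   channels are never flagged).
#' @param factor Spread factor (2.5 is the conventional choice).
#' @return Logical per-channel mask.
#' @export
detect_bad_channels <- function(rec, factor = 2.5) {
  sds <- apply(rec$data, 1, stats::sd)
  scalp <- which(rec$channel_roles == "scalp")
  if (length(scalp) < 3L) stopf("need at least 3 scalp channels")
  bad <- rep(FALSE, nrow(rec$data))
  for (i in scalp) {
    others <- mean(sds[setdiff(scalp, i)])
    bad[i] <- sds[i] > factor * others || sds[i] < others / factor
  }
  if (all(bad[scalp])) stopf("all channels flagged noisy: unusable trial")
  bad
}

# g(cos angle) kernel of the spherical spline (order-m Legendre series)
spline_g <- function(cosang, m = 4L, nterms = 7L) {
  cosang <- as.matrix(cosang)
  cosang[] <- pmin(1, pmax(-1, cosang))
  out <- matrix(0, nrow(cosang), ncol(cosang))
  Pn_1 <- matrix(1, nrow(cosang), ncol(cosang))   # P_0
  Pn <- cosang                                    # P_1
  for (n in seq_len(nterms)) {
    out <- out + (2 * n + 1) / (n * (n + 1))^m * Pn
    Pn1 <- ((2 * n + 1) * cosang * Pn - n * Pn_1) / (n + 1)
    Pn_1 <- Pn
    Pn <- Pn1
  }
  out / (4 * pi)
}

#' Spherical-spline interpolation of flagged channels
#'
#' Bad channels are reconstructed from the clean channels with the classic
#' spherical-spline interpolator on the unit sphere (order-4 Legendre kernel,
#' series truncated at 7 terms). Clean channels are untouched.
#'
#' @param rec An [eeg_recording()].
#' @param layout A [channel_layout()] matching the recording's channels.
#' @param bad_mask Logical mask (defaults to `rec$bad_mask`).
#' @param reg Diagonal regularization added to the clean-channel kernel
#'   matrix (small smoothing; 0 interpolates exactly through the nodes).
#' @param m,nterms Spline order and Legendre truncation.
#' @return The recording with bad channels replaced and `bad_mask` cleared.
#' @export
interpolate_channels <- function(rec, layout, bad_mask = NULL, reg = 1e-5,
                                 m = 4L, nterms = 7L) {
  bad_mask <- bad_mask %||% rec$bad_mask
  if (!any(bad_mask)) return(rec)
  pos <- as.matrix(layout[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  clean <- which(!bad_mask & rec$channel_roles == "scalp")
  bad <- which(bad_mask)
  if (length(clean) < 4L) stopf("need at least 4 clean channels to interpolate")

  Gcc <- spline_g(pos[clean, ] %*% t(pos[clean, ]), m, nterms)
  Gbc <- spline_g(pos[bad, , drop = FALSE] %*% t(pos[clean, ]), m, nterms)
  nc <- length(clean)
  A <- rbind(cbind(Gcc + reg * diag(nc), rep(1, nc)), c(rep(1, nc), 0))
  # solve for [c; c0] against [y; 0]; linear in y, so precompute the map
  M <- solve(A)[, seq_len(nc), drop = FALSE]
  W <- Gbc %*% M[seq_len(nc), , drop = FALSE] +
    matrix(M[nc + 1, ], length(bad), nc, byrow = TRUE)

  out <- rec
  out$data[bad, ] <- W %*% rec$data[clean, , drop = FALSE]
  out$bad_mask <- rep(FALSE, nrow(rec$data))
  out
}

#' Canonical single-recording preprocessing chain
#'
#' Applies the stages in the conventional order: downsample to `target_fs`,
#' zero-phase band-pass, bad-channel detection and spherical-spline
#' interpolation, then mastoid referencing. Group-level MCCA denoising
#' ([mcca_fit()] / [mcca_denoise()]) follows across subjects.
#'
#' @param rec An [eeg_recording()].
#' @param layout A [channel_layout()] matching the recording.
#' @param target_fs Output sampling rate (Hz).
#' @param band Band-pass edges in Hz.
#' @param filter_order Butterworth order per pass.
#' @param bad_factor Spread factor of the bad-channel rule.
#' @return The preprocessed recording (bad channels interpolated and mask
#'   cleared, mastoid-mean zero).
#' @export
preprocess_chain <- function(rec, layout, target_fs = 128, band = c(0.5, 8),
                             filter_order = 4L, bad_factor = 2.5) {
  rec <- downsample(rec, target_fs)
  rec <- bandpass(rec, band[1], band[2], filter_order)
  rec$bad_mask <- detect_bad_channels(rec, bad_factor)
  rec <- interpolate_channels(rec, layout)
  rereference(rec)
}

#' Re-reference to the mastoid average
#'
#' Subtracts the mean of the two mastoid channels from every channel; the
#' mastoid mean of the output is identically zero, and the operation is
#' idempotent.
#'
#' @param rec An [eeg_recording()] with exactly two channels of role
#'   "mastoid".
#' @export
rereference <- function(rec) {
  m <- which(rec$channel_roles == "mastoid")
  if (length(m) != 2L) {
    stopf("mastoid referencing needs exactly 2 mastoid channels (found %d)",
          length(m))
  }
  ref <- colMeans(rec$data[m, , drop = FALSE])
  out <- rec
  out$data <- sweep(rec$data, 2, ref)
  out
}
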