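# Model-comparison and waveform metrics: permutation-null prediction deltas
# and trough (N400) latency extraction from TRF weights.

#' Permutation-null prediction delta for one feature
#'
#' In each test fold the target feature's impulse heights are shuffled across
#' its own onsets (positions fixed) while all other regressors stay intact;
#' the fold's trained TRF predicts the response to this permuted input. The
#' delta is the per-channel true accuracy minus the mean accuracy over
#' `n_perm` permutations, averaged across folds.
#'
#' @param cv A [cross_validate()] result.
#' @param target_feature Feature name to permute.
#' @param n_perm Number of permutations (5 is the conventional default).
#' @param seed Base seed; each (fold, perm) draw is independently derived
#'   from it for exact reproducibility.
#' @return A `permutation_delta`: per-channel delta, true and null accuracy,
#'   n_perm, seed.
#' @export
permutation_delta <- function(cv, target_feature, n_perm = 5L, seed = 1L) {
  stopifnot(inherits(cv, "cv_result"))
  fi <- match(target_feature, cv$feature_names)
  if (is.na(fi)) stopf("feature '%s' not in the fitted model", target_feature)
  K <- length(cv$fold_models)
  nl <- cv$n_lags
  cols <- ((fi - 1L) * nl + 1L):(fi * nl)
  nch <- ncol(cv$responses[[1]])

  true_r <- matrix(0, K, nch)
  null_r <- array(0, dim = c(n_perm, K, nch))
  for (k in seq_len(K)) {
    model <- cv$fold_models[[k]]
    X <- cv$designs[[k]]
    pre <- pearson_precomp(cv$responses[[k]])
    d <- dim(model$weights)
    W <- matrix(aperm(model$weights, c(2, 1, 3)), nrow = d[1] * d[2])
    pred_true <- as.matrix(X %*% W)     # intercept dropped: r is shift-invariant
    true_r[k, ] <- pearson_fast(pred_true, pre)

    feat <- cv$trial_features[[k]][[fi]]
    nz <- which(feat$values != 0)
    if (length(nz) < 2L) stopf("feature '%s' has fewer than 2 impulses in fold %d",
                               target_feature, k)
    Wf <- W[cols, , drop = FALSE]
    Xf <- build_lagged_design(list(feat), cv$lags)
    base <- pred_true - as.matrix(Xf %*% Wf)
    # impulse onsets are distinct samples, so each stored design value maps
    # to exactly one impulse; permuting heights = rewriting the value slot
    fidx <- feat
    fidx$values[nz] <- seq_along(nz)
    imp_of <- build_lagged_design(list(fidx), cv$lags)@x
    heights <- feat$values[nz]
    for (p in seq_len(n_perm)) {
      vperm <- with_seed(mix_seed(seed, fi, k, p), sample(heights))
      Xp <- Xf
      Xp@x <- vperm[imp_of]
      pred <- base + as.matrix(Xp %*% Wf)
      null_r[p, k, ] <- pearson_fast(pred, pre)
    }
  }
  delta <- colMeans(true_r) - apply(null_r, 3, mean)
  structure(list(feature_name = target_feature, delta = delta,
                 true_accuracy = true_r, null_accuracy = null_r,
                 n_perm = as.integer(n_perm), seed = seed),
            class = "permutation_delta")
}

#' @exportS3Method base::print
print.permutation_delta <- function(x, ...) {
  cat(sprintf("<permutation_delta> '%s': mean delta = %.5f over %d channels (%d perms)\n",
              x$feature_name, mean(x$delta), length(x$delta), x$n_perm))
  invisible(x)
}

#' Trough latency of a TRF component
#'
#' Averages the weights of one feature over a channel set and returns the lag
#' (ms) of the minimum weight within the search window - the negative-going
#' trough of an N400-like response. Ties break to the earliest lag. When the
#' minimum sits on the window edge (no interior trough) the value is returned
#' with attribute `boundary = TRUE` and a warning.
#'
#' @param model A `trf_model`.
#' @param feature Feature name (default: first feature).
#' @param channel_set Integer channel indices to average (default all).
#' @param window_ms Search window after lag zero, default 200-600 ms.
#' @return Latency in ms (with `boundary` attribute).
#' @export
peak_latency <- function(model, feature = NULL, channel_set = NULL,
                         window_ms = c(200, 600)) {
  feature <- feature %||% model$feature_names[1]
  fi <- match(feature, model$feature_names)
  if (is.na(fi)) stopf("feature '%s' not in model", feature)
  lag_ms <- model$lag_ms
  sel <- which(lag_ms >= window_ms[1] & lag_ms <= window_ms[2])
  if (length(sel) == 0L) stopf("search window outside the modelled lag range")
  w <- model$weights[fi, , , drop = FALSE]
  chans <- channel_set %||% seq_len(dim(w)[3])
  trace <- apply(w[1, , chans, drop = FALSE], 2, mean)
  i <- sel[which.min(trace[sel])]      # which.min: earliest among ties
  boundary <- i == sel[1] || i == sel[length(sel)]
  if (boundary) warnf("trough latency lies on the search-window boundary")
  structure(lag_ms[i], boundary = boundary)
}
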