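# Ridge estimation of the temporal response function and its
# cross-validated evaluation. The estimator is the closed form
# (S'S + lambda I)^-1 S'r, solved per channel from shared normal equations;
# an unpenalized intercept column absorbs the response mean.

#' Fit a TRF by ridge regression
#'
#' @param design Design matrix from [build_lagged_design()] (sparse or dense),
#'   or precomputed normal equations (see `xtx`/`xty`).
#' @param response Numeric matrix samples x channels (a vector is treated as
#'   one channel).
#' @param lambda Ridge parameter (>= 0; 0 requires a full-rank design).
#' @param intercept Include an unpenalized intercept (default TRUE).
#' @return A `trf_model`: weights array (feature x lag x channel), per-channel
#'   intercept, lambda, lag and feature metadata.
#' @export
fit_ridge <- function(design, response, lambda, intercept = TRUE) {
  if (lambda < 0 || !is.finite(lambda)) stopf("lambda must be finite and >= 0")
  if (!is.matrix(response)) response <- matrix(response, ncol = 1)
  ne <- normal_equations(design, response, intercept)
  W <- solve_ridge(ne, lambda)
  trf_from_weights(W, design, lambda, intercept)
}

# X'X and X'y augmented with an intercept column (kept unpenalized)
normal_equations <- function(design, response, intercept = TRUE) {
  p <- ncol(design)
  xtx <- as.matrix(Matrix::crossprod(design))
  xty <- as.matrix(Matrix::crossprod(design, response))
  if (intercept) {
    cs <- as.numeric(Matrix::colSums(design))
    n <- nrow(design)
    xtx <- rbind(cbind(xtx, cs), c(cs, n))
    xty <- rbind(xty, colSums(response))
  }
  list(xtx = xtx, xty = xty, p = p, intercept = intercept,
       n = nrow(design))
}

# add two normal-equation objects (training folds accumulate trials)
ne_add <- function(a, b) {
  list(xtx = a$xtx + b$xtx, xty = a$xty + b$xty, p = a$p,
       intercept = a$intercept, n = a$n + b$n)
}

solve_ridge <- function(ne, lambda) {
  pen <- c(rep(1, ne$p), if (ne$intercept) 0)
  A <- ne$xtx + lambda * diag(pen, nrow(ne$xtx))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    stopf("normal equations singular at lambda = %g; use lambda > 0", lambda)
  }
  backsolve(ch, backsolve(ch, ne$xty, transpose = TRUE))
}

trf_from_weights <- function(W, design, lambda, intercept) {
  p <- ncol(design)
  fn <- attr(design, "feature_names") %||% "feature"
  nl <- attr(design, "n_lags") %||% p
  lags <- attr(design, "lags") %||% seq_len(nl)
  fs <- attr(design, "fs") %||% 1000
  nch <- ncol(W)
  b0 <- if (intercept) W[p + 1L, ] else rep(0, nch)
  wt <- array(W[seq_len(p), , drop = FALSE], dim = c(nl, length(fn), nch))
  wt <- aperm(wt, c(2, 1, 3))   # feature x lag x channel
  dimnames(wt) <- list(fn, NULL, NULL)
  structure(list(weights = wt, intercept = b0, lambda = lambda,
                 lags = lags, fs = fs, lag_ms = lags * 1000 / fs,
                 feature_names = fn),
            class = "trf_model")
}

#' @exportS3Method base::print
print.trf_model <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("<trf_model> %d feature(s) x %d lags x %d channel(s), lambda = %g\n",
              d[1], d[2], d[3], x$lambda))
  invisible(x)
}

#' Predict a response from a fitted TRF
#'
#' @param object A `trf_model`.
#' @param design Design matrix built with the same lag window and features.
#' @param ... Unused.
#' @return Matrix samples x channels.
#' @export
predict.trf_model <- function(object, design, ...) {
  d <- dim(object$weights)
  W <- matrix(aperm(object$weights, c(2, 1, 3)), nrow = d[1] * d[2])
  out <- as.matrix(design %*% W)
  sweep(out, 2, object$intercept, `+`)
}

pearson_by_channel <- function(pred, obs) {
  pearson_fast(as.matrix(pred), pearson_precomp(as.matrix(obs)))
}

# centered copy + sum of squares of the observed block, reusable across
# many predictions against the same data
pearson_precomp <- function(obs) {
  n <- nrow(obs)
  oc <- obs - matrix(colMeans(obs), n, ncol(obs), byrow = TRUE)
  list(oc = oc, ss = colSums(oc^2), n = n)
}

pearson_fast <- function(pred, pre) {
  pm <- colMeans(pred)
  num <- colSums(pred * pre$oc)        # oc is centered: equals cov * n
  ssp <- colSums(pred^2) - pre$n * pm^2
  den <- sqrt(pmax(ssp, 0) * pre$ss)
  unname(ifelse(den > 0, num / den, 0))
}

#' Cross-validated TRF estimation with ridge-parameter selection
#'
#' Leave-one-trial-out over `n_trials` folds (fourfold for the canonical
#' four-trial session): for each lambda on the grid, train on the other
#' trials, predict the held-out trial, and record the per-channel Pearson
#' correlation. The lambda maximizing accuracy averaged across trials and
#' channels is selected (ties break to the smaller lambda, i.e. less
#' smoothing), one lambda per subject; the final model is refit on all
#' trials at the selected value.
#'
#' @param trial_features List over trials; each element a list of
#'   `feature_impulse_series`.
#' @param trial_responses List over trials of response matrices
#'   (samples x channels) or [eeg_recording()]s.
#' @param lags A [lag_window()].
#' @param lambda_grid Candidate ridge parameters (default 10^seq(-1, 3, 0.5),
#'   spanning 0.1 ... 1000).
#' @return A `cv_result`: selected_lambda, accuracy (lambda x fold x channel),
#'   mean_accuracy per lambda, final `model`, per-fold models at the selected
#'   lambda, and the per-trial designs/responses for reuse.
#' @export
cross_validate <- function(trial_features, trial_responses, lags,
                           lambda_grid = 10^seq(-1, 3, by = 0.5)) {
  K <- length(trial_features)
  if (K < 2L) stopf("cross-validation needs at least 2 trials")
  stopifnot(length(trial_responses) == K)
  lambda_grid <- sort(lambda_grid)

  designs <- lapply(trial_features, build_lagged_design, lags = lags)
  resps <- lapply(trial_responses, function(r) {
    if (inherits(r, "eeg_recording")) t(r$data) else as.matrix(r)
  })
  nes <- lapply(seq_len(K), function(k) normal_equations(designs[[k]], resps[[k]]))

  nch <- ncol(resps[[1]])
  acc <- array(NA_real_, dim = c(length(lambda_grid), K, nch))
  fold_W <- vector("list", K)
  for (k in seq_len(K)) {
    ne_train <- Reduce(ne_add, nes[-k])
    fold_W[[k]] <- vector("list", length(lambda_grid))
    pre <- pearson_precomp(resps[[k]])
    for (li in seq_along(lambda_grid)) {
      W <- solve_ridge(ne_train, lambda_grid[li])
      fold_W[[k]][[li]] <- W
      # intercept omitted: Pearson r is invariant to constant shifts
      pred <- as.matrix(designs[[k]] %*% W[seq_len(ncol(designs[[k]])), , drop = FALSE])
      acc[li, k, ] <- pearson_fast(pred, pre)
    }
  }
  mean_acc <- apply(acc, 1, mean)
  best <- which(mean_acc >= max(mean_acc) - 1e-15)[1]   # ties -> smaller lambda
  sel <- lambda_grid[best]

  ne_all <- Reduce(ne_add, nes)
  W_all <- solve_ridge(ne_all, sel)
  model <- trf_from_weights(W_all, designs[[1]], sel, intercept = TRUE)
  fold_models <- lapply(seq_len(K), function(k) {
    trf_from_weights(fold_W[[k]][[best]], designs[[1]], sel, intercept = TRUE)
  })

  structure(list(selected_lambda = sel, lambda_grid = lambda_grid,
                 accuracy = acc, mean_accuracy = mean_acc,
                 model = model, fold_models = fold_models,
                 designs = designs, responses = resps, lags = lags,
                 feature_names = attr(designs[[1]], "feature_names"),
                 n_lags = attr(designs[[1]], "n_lags"),
                 trial_features = trial_features),
            class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, lambda* = %g, mean r = %.4f\n",
              dim(x$accuracy)[2], x$selected_lambda,
              max(x$mean_accuracy)))
  invisible(x)
}
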