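# small helper: random impulse features on a short trial
rand_feat <- function(name, seed, fs = 64, dur = 20, n_imp = 40) {
  set.seed(seed)
  tok <- toy_tokens(rep("w", n_imp), onsets = sort(runif(n_imp, 0.5, dur - 1.5)))
  suppressWarnings(build_impulse_series(tok, runif(n_imp, 0.2, 0.8), fs,
                                        fs * dur, name = name))
}

test_that("lagged design realizes the convolution as a linear system", {
  fs <- 64; n <- fs * 5
  # single unit impulse: identity band across lags
  tok <- toy_tokens("w", onsets = 2)
  f <- build_impulse_series(tok, 1, fs, n, name = "f")
  lw <- lag_window(-100, 300, fs)
  X <- build_lagged_design(list(f), lw)
  t0 <- round(2 * fs) + 1
  for (li in seq_along(lw$lags)) {
    expect_equal(X[t0 + lw$lags[li], li], 1)
  }
  expect_equal(sum(X != 0), length(lw$lags))

  # lag window {0}: the design is the feature itself
  X0 <- build_lagged_design(list(f), 0L)
  expect_equal(as.numeric(X0), f$values)

  # conv-equivalence oracle on random features and an arbitrary kernel
  fr <- rand_feat("f", 31)
  lwp <- lag_window(0, 400, fs)
  Xr <- build_lagged_design(list(fr), lwp)
  set.seed(32)
  kern <- rnorm(length(lwp$lags))
  expect_equal(as.numeric(Xr %*% kern),
               naive_conv(fr$values, kern)[seq_along(fr$values)],
               tolerance = 1e-12)

  expect_error(build_lagged_design(list(f), seq(-10, 400)), "exceeds|lag")
})

test_that("ridge fit matches an independent dense solve across the grid", {
  set.seed(7)
  for (rep in 1:4) {
    X <- matrix(rnorm(40 * 12), 40, 12)
    y <- rnorm(40)
    for (lam in c(0.1, 1, 10, 100, 1000)) {
      m <- fit_ridge(X, y, lam)
      w_or <- dense_ridge(X, y, lam)
      got <- c(as.numeric(m$weights[1, , 1]), m$intercept)
      expect_lt(max(abs(got - w_or)) / max(abs(w_or)), 1e-8)
    }
  }
  # lambda = 0 on a full-rank design equals OLS
  X <- matrix(rnorm(50 * 6), 50, 6); y <- rnorm(50)
  m0 <- fit_ridge(X, y, 0)
  ols <- coef(lm(y ~ X))
  expect_equal(as.numeric(m0$weights[1, , 1]), unname(ols[-1]), tolerance = 1e-8)
  # huge lambda shrinks weights to zero
  mbig <- fit_ridge(X, y, 1e12)
  expect_lt(max(abs(mbig$weights)), 1e-6 * sd(y))
  # rank-deficient system at lambda = 0 is refused with advice
  Xs <- cbind(X[, 1], X[, 1], X[, 2])
  expect_error(fit_ridge(Xs, y, 0), "lambda > 0")
})

test_that("weight norm shrinks monotonically in lambda", {
  set.seed(8)
  f <- rand_feat("f", 41)
  lw <- lag_window(-100, 400, 64)
  X <- build_lagged_design(list(f), lw)
  y <- as.numeric(X %*% rnorm(ncol(X))) + rnorm(nrow(X))
  norms <- vapply(10^seq(-2, 4), function(l) {
    sqrt(sum(fit_ridge(X, y, l)$weights^2))
  }, 0)
  expect_true(all(diff(norms) < 1e-10))
})

test_that("cross-validation selects lambda and recovers kernels", {
  fs <- 64; dur <- 30; n <- fs * dur
  lw <- lag_window(-100, 600, fs)
  topo <- c(1, 0.6)
  kern <- kernel_spec("f", 350, 110, -1, topo, support_ms = 600)
  ks <- eval_kernel(kern, fs)
  make_trial <- function(seed, noise_sd) {
    f <- rand_feat("f", seed, fs, dur, 60)
    clean <- sapply(topo, function(g) g * naive_conv(f$values, ks)[seq_len(n)])
    set.seed(seed + 500)
    list(feats = list(f), resp = clean + matrix(rnorm(n * 2, 0, noise_sd), n, 2))
  }
  # noiseless: r -> 1 at the smallest lambda
  tr0 <- lapply(1:3, make_trial, noise_sd = 0)
  cv0 <- cross_validate(lapply(tr0, `[[`, "feats"), lapply(tr0, `[[`, "resp"),
                        lw, lambda_grid = c(0.01, 1, 100))
  expect_gt(max(cv0$mean_accuracy), 0.999)
  expect_equal(cv0$selected_lambda, 0.01)

  # SNR 0.25: kernel recovered, selected lambda strictly inside the grid
  sig_sd <- sd(sapply(tr0, function(t) t$resp[, 1]))
  tr1 <- lapply(1:4, make_trial, noise_sd = 2 * sig_sd)
  cv1 <- cross_validate(lapply(tr1, `[[`, "feats"), lapply(tr1, `[[`, "resp"),
                        lw, lambda_grid = 10^seq(-1, 3, 0.5))
  est <- apply(cv1$model$weights["f", , ], 1, mean)
  iv <- which(lw$lag_ms >= 0 & lw$lag_ms <= 600)
  expect_gt(cor(est[iv], ks[lw$lags[iv] + 1]), 0.9)

  # tie-break: equal accuracies pick the smaller lambda
  accs <- cv0$mean_accuracy
  expect_equal(cv0$selected_lambda, cv0$lambda_grid[which.max(accs)])
  expect_error(cross_validate(tr0[1], list(tr0[[1]]$resp), lw), "2 trials")
})

test_that("feature order does not change predictions", {
  fs <- 64
  f1 <- rand_feat("a", 51); f2 <- rand_feat("b", 52)
  lw <- lag_window(-100, 400, fs)
  set.seed(53)
  y <- rnorm(length(f1$values))
  Xab <- build_lagged_design(list(f1, f2), lw)
  Xba <- build_lagged_design(list(f2, f1), lw)
  mab <- fit_ridge(Xab, y, 1)
  mba <- fit_ridge(Xba, y, 1)
  expect_equal(predict(mab, Xab), predict(mba, Xba), tolerance = 1e-10)
  expect_equal(mab$weights["a", , 1], mba$weights["a", , 1], tolerance = 1e-10)
})

test_that("permutation deltas are zero for constant heights and positive for real kernels", {
  fs <- 64; dur <- 30; n <- fs * dur
  lw <- lag_window(-100, 600, fs)
  topo <- c(1, 0.7)
  kern <- kernel_spec("t", 350, 110, -1, topo, support_ms = 600)
  ks <- eval_kernel(kern, fs)

  # constant impulse heights: every permutation identical -> delta exactly 0
  mk_const <- function(seed) {
    set.seed(seed)
    # distinct samples: no collisions, so every height is exactly equal
    tok <- toy_tokens(rep("w", 50), onsets = 0.5 + (1:50) * 0.55)
    f <- suppressWarnings(build_impulse_series(tok, rep(0.5, 50), fs, n, "t"))
    clean <- sapply(topo, function(g) g * naive_conv(f$values, ks)[seq_len(n)])
    set.seed(seed + 100)
    list(feats = list(f), resp = clean + matrix(rnorm(2 * n, 0, 0.1), n, 2))
  }
  trc <- lapply(1:3, mk_const)
  cvc <- cross_validate(lapply(trc, `[[`, "feats"), lapply(trc, `[[`, "resp"),
                        lw, lambda_grid = c(1, 10))
  pd <- permutation_delta(cvc, "t", n_perm = 3, seed = 9L)
  expect_equal(pd$delta, rep(0, 2), tolerance = 1e-12)

  # strong kernel: delta positive on the high-gain channel
  mk_real <- function(seed) {
    f <- rand_feat("t", seed, fs, dur, 60)
    clean <- sapply(topo, function(g) g * naive_conv(f$values, ks)[seq_len(n)])
    set.seed(seed + 200)
    list(feats = list(f), resp = clean + matrix(rnorm(2 * n, 0, sd(clean[, 1])), n, 2))
  }
  trr <- lapply(1:3, mk_real)
  cvr <- cross_validate(lapply(trr, `[[`, "feats"), lapply(trr, `[[`, "resp"),
                        lw, lambda_grid = 10^seq(-1, 3, 1))
  pdr <- permutation_delta(cvr, "t", n_perm = 5, seed = 10L)
  expect_gt(pdr$delta[1], 0)
  # reproducible given the seed
  pdr2 <- permutation_delta(cvr, "t", n_perm = 5, seed = 10L)
  expect_identical(pdr$null_accuracy, pdr2$null_accuracy)
  expect_error(permutation_delta(cvr, "nope", 5, 1), "not in")
})

test_that("trough latency extraction honors window, ties and boundaries", {
  fs <- 128
  lw <- lag_window(-200, 800, fs)
  nlag <- length(lw$lags)
  mk_model <- function(trace) {
    w <- array(rep(trace, 2), dim = c(1, nlag, 2))
    dimnames(w) <- list("f", NULL, NULL)
    structure(list(weights = w, intercept = c(0, 0), lambda = 1,
                   lags = lw$lags, fs = fs, lag_ms = lw$lag_ms,
                   feature_names = "f"), class = "trf_model")
  }
  # trough at 400 ms: returns the nearest representable lag (half a sample)
  tr <- -exp(-(lw$lag_ms - 400)^2 / (2 * 50^2))
  lat <- as.numeric(peak_latency(mk_model(tr), "f"))
  expect_lt(abs(lat - 400), 1000 / fs / 2 + 1e-9)
  # a trough placed exactly on the grid is returned exactly
  on_grid <- lw$lag_ms[which.min(abs(lw$lag_ms - 400))]
  tr_g <- -exp(-(lw$lag_ms - on_grid)^2 / (2 * 50^2))
  expect_equal(as.numeric(peak_latency(mk_model(tr_g), "f")), on_grid)
  # +74 ms shift detected within one sample (7.8125 ms at 128 Hz)
  tr2 <- -exp(-(lw$lag_ms - 474)^2 / (2 * 50^2))
  d <- as.numeric(peak_latency(mk_model(tr2), "f")) -
    as.numeric(peak_latency(mk_model(tr), "f"))
  expect_lt(abs(d - 74), 1000 / fs)
  # two equal minima: earliest wins
  tr3 <- numeric(nlag)
  tr3[which.min(abs(lw$lag_ms - 300))] <- -1
  tr3[which.min(abs(lw$lag_ms - 500))] <- -1
  expect_equal(as.numeric(peak_latency(mk_model(tr3), "f")),
               lw$lag_ms[which.min(abs(lw$lag_ms - 300))])
  # monotone weights: boundary argmin flagged with a warning
  tr4 <- -seq_len(nlag)
  expect_warning(lat4 <- peak_latency(mk_model(tr4), "f"), "boundary")
  expect_true(attr(lat4, "boundary"))
  expect_error(peak_latency(mk_model(tr), "f", window_ms = c(2000, 3000)),
               "window")
})
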