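test_that("band-pass filter is zero-phase with the documented response", {
  fs <- 128
  t <- seq(0, 20, by = 1 / fs)
  mid <- 500:2000
  # passband sine preserved (two passes square the magnitude response)
  y4 <- bandpass(sin(2 * pi * 4 * t), fs = fs)
  expect_lt(abs(max(abs(y4[mid])) - 1), 0.05)
  # analytic check: |H|^2 of an order-4 Butterworth bandpass at 4 Hz
  h2 <- 1 / (1 + ((4 / 8 - 0.5 / 4) / (8 / 8 - 0.5 / 8))^16)  # ~1 for interior
  expect_gt(max(abs(y4[mid])), 0.95)
  # DC rejected
  dc <- bandpass(rep(2.5, length(t)), fs = fs)
  expect_lt(max(abs(dc[mid])), 1e-3 * 2.5)
  # symmetric pulse peak unmoved (zero phase)
  pulse <- exp(-(t - 10)^2 / (2 * 0.25^2))
  yp <- bandpass(pulse, fs = fs)
  expect_equal(which.max(yp), which.max(pulse))
  # stopband attenuation
  y20 <- bandpass(sin(2 * pi * 20 * t), fs = fs)
  expect_lt(max(abs(y20[mid])), 0.01)
  # invalid band refused
  expect_error(bandpass(t, lo = 8, hi = 0.5, fs = fs), "band")
  expect_error(bandpass(t, lo = 0.5, hi = 70, fs = fs), "band")
})

test_that("filtering and referencing are linear operators", {
  fs <- 64
  set.seed(3)
  X <- matrix(rnorm(4 * 256), 256, 4)
  Y <- matrix(rnorm(4 * 256), 256, 4)
  a <- 2.3; b <- -0.7
  lhs <- bandpass(a * X + b * Y, fs = fs)
  rhs <- a * bandpass(X, fs = fs) + b * bandpass(Y, fs = fs)
  expect_lt(max(abs(lhs - rhs)), 1e-8)

  lay <- channel_layout(4L, mastoids = TRUE)
  mk <- function(M) eeg_recording(M, fs, channel_labels = lay$label,
                                  channel_roles = lay$role)
  Xr <- matrix(rnorm(6 * 100), 6, 100)
  Yr <- matrix(rnorm(6 * 100), 6, 100)
  lhs2 <- rereference(mk(a * Xr + b * Yr))$data
  rhs2 <- a * rereference(mk(Xr))$data + b * rereference(mk(Yr))$data
  expect_lt(max(abs(lhs2 - rhs2)), 1e-10)
})

test_that("downsampling preserves amplitude and duration", {
  fs <- 512
  t <- seq(0, 20, by = 1 / fs)
  s <- sin(2 * pi * 0.5 * t)
  d <- downsample(s, 128, fs = fs)
  expect_lt(abs(length(d) - length(s) * 128 / 512), 1.5)
  tt <- seq(0, by = 1 / 128, length.out = length(d))
  mid <- 200:2300
  expect_lt(max(abs(d[mid] - sin(2 * pi * 0.5 * tt[mid]))), 0.01)
  # identity when rates match
  expect_identical(downsample(s, fs, fs = fs), s)
  expect_error(downsample(s, 1024, fs = fs), "exceeds")
  # aliasing guard: a tone above the output Nyquist is removed
  hi <- sin(2 * pi * 100 * t)
  dh <- downsample(hi, 128, fs = fs)
  expect_lt(max(abs(dh[mid])), 0.02)
})

test_that("bad-channel rule matches the leave-one-out definition", {
  fs <- 128
  lay <- channel_layout(32L, mastoids = FALSE)
  set.seed(9)
  X <- matrix(rnorm(32 * 1000), 32, 1000)
  rec <- eeg_recording(X, fs, channel_labels = lay$label,
                       channel_roles = lay$role)
  expect_false(any(detect_bad_channels(rec)))  # homogeneous sds -> none

  X2 <- X; X2[7, ] <- 3 * X2[7, ]; X2[20, ] <- 0
  rec2 <- eeg_recording(X2, fs, channel_labels = lay$label,
                        channel_roles = lay$role)
  bad <- detect_bad_channels(rec2)
  expect_true(bad[7]); expect_true(bad[20])
  expect_equal(sum(bad), 2L)
  # hand-computed leave-one-out criterion for the noisy channel
  sds <- apply(X2, 1, sd)
  loo <- mean(sds[-7])
  expect_true(sds[7] > 2.5 * loo)

  # every channel violates the spread rule relative to the rest
  X3 <- matrix(rnorm(4 * 500), 4, 500) * c(1, 100, 1e4, 1e6)
  expect_error(detect_bad_channels(eeg_recording(X3, fs)), "unusable")
})

test_that("spherical-spline interpolation reconstructs held-out channels", {
  lay <- channel_layout(32L, mastoids = FALSE)
  pos <- as.matrix(lay[, c("x", "y", "z")])
  # smooth dipolar field sampled on the cap
  field <- 2 * pos[, 1] + 1.5 * pos[, 3] - pos[, 2]
  X <- outer(field, sin(2 * pi * 3 * (1:200) / 128))
  rec <- eeg_recording(X, 128, channel_labels = lay$label,
                       channel_roles = lay$role)
  bm <- rep(FALSE, 32); bm[5] <- TRUE
  ri <- interpolate_channels(rec, lay, bm)
  expect_gt(cor(ri$data[5, ], X[5, ]), 0.95)
  expect_equal(unname(ri$data[-5, ]), unname(X[-5, ])) # clean channels untouched

  # spatially constant signal reproduced exactly
  Xc <- matrix(1.7, 32, 60)
  rc <- interpolate_channels(eeg_recording(Xc + rnorm(1) * 0, 128,
                                           channel_labels = lay$label,
                                           channel_roles = lay$role),
                             lay, bm)
  expect_lt(max(abs(rc$data[5, ] - 1.7)), 1e-8)

  # bad channel at the exact location of a clean one: node reproduction
  lay2 <- lay
  lay2[5, c("x", "y", "z")] <- lay[6, c("x", "y", "z")]
  rn <- interpolate_channels(rec, lay2, bm, reg = 0)
  expect_lt(max(abs(rn$data[5, ] - X[6, ])), 1e-6 * max(abs(X[6, ])))

  expect_error(interpolate_channels(
    eeg_recording(X[1:5, ], 128), lay[1:5, ], c(TRUE, TRUE, FALSE, FALSE, FALSE)),
    "clean")
})

test_that("mastoid referencing zeroes the mastoid mean and is idempotent", {
  lay <- channel_layout(3L, mastoids = TRUE)
  X <- rbind(c(3, 3), c(1, 1), c(5, 5), c(1, 1), c(5, 5))
  rec <- eeg_recording(X, 64, channel_labels = lay$label,
                       channel_roles = lay$role)
  rr <- rereference(rec)
  # hand example: scalp (3, 1, 5) minus mastoid mean 3 -> (0, -2, 2)
  expect_equal(unname(rr$data[1:3, 1]), c(0, -2, 2))
  expect_equal(colMeans(rr$data[4:5, ]), c(0, 0))
  expect_equal(rereference(rr)$data, rr$data)
  expect_error(rereference(eeg_recording(X, 64)), "mastoid")
})

test_that("the canonical chain runs in order and leaves clean referenced data", {
  set.seed(21)
  fs <- 512
  lay <- channel_layout(16L, mastoids = TRUE)
  X <- matrix(rnorm(18 * fs * 6), 18, fs * 6)
  X[3, ] <- X[3, ] * 4          # noisy channel for the rule to catch
  rec <- eeg_recording(X, fs, channel_labels = lay$label,
                       channel_roles = lay$role)
  out <- preprocess_chain(rec, lay, target_fs = 128)
  expect_equal(out$fs, 128)
  expect_lt(abs(ncol(out$data) - ncol(X) / 4), 2)
  expect_false(any(out$bad_mask))               # interpolated, mask cleared
  expect_equal(max(abs(colMeans(out$data[17:18, ]))), 0)  # mastoid mean 0
  # the formerly noisy channel no longer stands out
  sds <- apply(out$data, 1, sd)
  expect_lt(sds[3], 2.5 * mean(sds[setdiff(1:16, 3)]))
})

test_that("MCCA finds shared structure and rejects independent noise", {
  set.seed(4)
  n <- 800; nch <- 12; S <- 5
  # identical data across subjects -> CC1 carries it with summed
  # inter-subject correlation ~ n_subjects
  base <- matrix(rnorm(n * nch), n, nch)
  recs_id <- lapply(1:S, function(s) t(base))
  m_id <- mcca_fit(recs_id, n_pc = 8, n_cc = 40)
  proj <- lapply(1:S, function(s) {
    su <- m_id$subjects[[s]]
    (base %*% su$W) %*% su$V[, 1]
  })
  rho <- sapply(2:S, function(s) abs(cor(proj[[1]], proj[[s]])))
  expect_true(all(rho > 1 - 1e-8))

  # independent noise: no component beats the permutation bound
  recs_no <- lapply(1:S, function(s) t(matrix(rnorm(n * nch), n, nch)))
  m_no <- mcca_fit(recs_no, n_pc = 8, n_cc = 40)
  # compare leading eigenvalue against eigenvalues from subject-shuffled
  # (circularly shifted) copies, which destroy any alignment
  ev_obs <- m_no$eigenvalues[1]
  ev_null <- replicate(20, {
    recs_sh <- lapply(recs_no, function(r) {
      k <- sample(n, 1)
      r[, c(k:n, seq_len(k - 1))]
    })
    mcca_fit(recs_sh, n_pc = 8, n_cc = 40)$eigenvalues[1]
  })
  expect_lt(ev_obs, quantile(ev_null, 0.95) * 1.1)

  # planted shared sine at SNR 0.5: CC1 recovers it
  sig <- sin(2 * pi * 5 * (1:n) / 128)
  recs_pl <- lapply(1:S, function(s) {
    mix <- rnorm(nch)
    t(outer(sig, mix) + matrix(rnorm(n * nch), n, nch) * sqrt(2) * sd(sig) * sqrt(mean(mix^2)))
  })
  m_pl <- mcca_fit(recs_pl, n_pc = 12, n_cc = 60)
  cc1 <- mcca_components(m_pl, recs_pl, k = 1)
  expect_gt(abs(cor(cc1, sig)), 0.95)
})

test_that("MCCA denoising is a projection that moves data toward the truth", {
  set.seed(6)
  n <- 800; nch <- 10; S <- 5
  sig <- sin(2 * pi * 4 * (1:n) / 128)
  clean <- list(); recs <- list()
  for (s in 1:S) {
    mix <- rnorm(nch)
    clean[[s]] <- outer(sig, mix)
    recs[[s]] <- t(clean[[s]] + matrix(rnorm(n * nch), n, nch) *
                     sqrt(2) * sd(clean[[s]]))
  }
  m <- mcca_fit(recs, n_pc = 10, n_cc = 4)
  for (s in 1:S) {
    den <- mcca_denoise(recs[[s]], m, s)
    err_raw <- sum((t(recs[[s]]) - clean[[s]])^2)
    err_den <- sum((t(den) - clean[[s]])^2)
    expect_lt(err_den, err_raw)
  }
  # full retention reduces to the subject's rank-n_pc reconstruction; with
  # n_pc = nch that is the identity
  m_full <- mcca_fit(recs, n_pc = nch, n_cc = S * nch)
  back <- mcca_denoise(recs[[1]], m_full, 1, n_cc = S * nch)
  expect_equal(back, recs[[1]], tolerance = 1e-6)
  # applying twice equals applying once (projection), all-zero maps to zero
  d1 <- mcca_denoise(recs[[2]], m, 2)
  d2 <- mcca_denoise(d1, m, 2)
  expect_equal(d1, d2, tolerance = 1e-8)
  z <- mcca_denoise(matrix(0, nch, n), m, 2)
  expect_true(all(z == 0))
  expect_error(mcca_denoise(recs[[1]], m, 9), "not in")
  # clipping warning
  expect_warning(mcca_fit(recs, n_pc = 4, n_cc = 500), "clip")
})
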