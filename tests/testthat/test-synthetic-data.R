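test_that("embedding generation respects the category structure", {
  # degenerate spec: similarity ~ 1, no idiosyncratic noise -> identical
  # vectors within a category, dissimilarity 0
  lex1 <- lexicon_spec(vocab_size = 10L, embed_dim = 8L, n_categories = 2L,
                       within_category_similarity = 0.999,
                       function_word_fraction = 0, seed = 1L)
  E1 <- generate_embeddings(lex1, noise = 0)
  cats <- attr(E1, "categories")
  same <- which(cats == cats[1])
  expect_equal(E1[same[1], ], E1[same[2], ], tolerance = 1e-12)
  expect_equal(1 - cor(E1[same[1], ], E1[same[2], ]), 0, tolerance = 1e-12)

  # V=100, K=5: within-category cosine exceeds between-category cosine,
  # checked by exhaustive pairwise computation
  lex2 <- lexicon_spec(vocab_size = 100L, embed_dim = 30L, n_categories = 5L,
                       within_category_similarity = 0.7,
                       function_word_fraction = 0, seed = 1L)
  E2 <- generate_embeddings(lex2)
  cats <- attr(E2, "categories")
  S <- E2 %*% t(E2)
  within <- between <- c()
  for (i in 1:99) for (j in (i + 1):100) {
    if (cats[i] == cats[j]) within <- c(within, S[i, j])
    else between <- c(between, S[i, j])
  }
  expect_gt(mean(within), mean(between))
  expect_gt(mean(within), 0.5)

  expect_error(lexicon_spec(vocab_size = 3L, n_categories = 5L), "invalid")
  # determinism
  expect_identical(generate_embeddings(lex2), generate_embeddings(lex2))
})

test_that("corpus generation: determinism, temperature-0 limit, 5-gram recount", {
  w <- tiny_world()
  expect_identical(generate_corpus(w$E, 20L, seed = 5L),
                   generate_corpus(w$E, 20L, seed = 5L))
  expect_error(generate_corpus(w$E, 0L), "n_sentences")

  # temperature 0, single start word, no function words -> one sentence
  # repeated; every observed 5-gram occurs n_sentences times
  det <- generate_corpus(w$E, 12L, transition_temperature = 0,
                         function_word_prob = 0,
                         start_words = "w0010", seed = 1L)
  expect_length(unique(vapply(det, paste, "", collapse = " ")), 1L)
  grams <- table(vapply(1:(length(det[[1]]) - 4), function(i) {
    paste(det[[1]][i:(i + 4)], collapse = " ")
  }, ""))
  counts <- table(unlist(lapply(det, function(s) {
    vapply(seq_len(length(s) - 4), function(i) paste(s[i:(i + 4)], collapse = " "), "")
  })))
  expect_true(all(counts == 12L))

  # 5-gram counts in the trained model equal a brute-force sliding recount
  lm <- w$lm
  co <- w$corpus
  recount <- new.env(parent = emptyenv())
  for (s in co) {
    pad <- c(rep("<s>", 4), s, "</s>")
    for (i in seq_len(length(pad) - 4)) {
      k <- paste(pad[i:(i + 4)], collapse = "\x1f")
      recount[[k]] <- (if (is.null(recount[[k]])) 0 else recount[[k]]) + 1
    }
  }
  top <- lm$tables[[5]]
  expect_setequal(ls(top), ls(recount))
  for (k in ls(recount)) expect_identical(top[[k]], recount[[k]])
})

test_that("transcripts hit the documented speech statistics", {
  w <- tiny_world()
  spec <- transcript_spec(duration_s = 720, seed = 3L)
  tok <- generate_transcript(spec, w$corpus)
  # 190 wpm over 12 minutes ~ 2280 words, within 10%
  expect_lt(abs(nrow(tok) - 2280) / 2280, 0.1)
  expect_true(all(diff(tok$onset_s) > 0))
  expect_true(all(diff(tok$sentence_id) >= 0))
  expect_true(all(tok$offset_s > tok$onset_s))
  # mean content-word duration near 334 ms (truncation inflates it slightly;
  # allow 2 sd-of-mean around the truncated-normal mean)
  durs <- (tok$offset_s - tok$onset_s)[tok$is_content]
  expect_gt(length(durs), 500)
  expect_lt(abs(mean(durs) - 0.334), 0.02 + 2 * 0.140 / sqrt(length(durs)))
  expect_true(all(durs >= 0.05))
  # determinism
  expect_identical(tok, generate_transcript(spec, w$corpus))
})

test_that("forward model reproduces kernels exactly in the noiseless limit", {
  fs <- 64
  lay <- channel_layout(8L, mastoids = TRUE)
  topo <- parietal_topography(lay)
  k <- kernel_spec("f", trough_latency_ms = 300, trough_width_ms = 100,
                   amplitude = -2, topography = topo, support_ms = 600)
  tok <- toy_tokens("w", onsets = 2.0)
  vals <- 1.0
  rec <- simulate_subject_eeg(tok, list(f = vals), list(f = k),
                              fs = fs, layout = lay, duration_s = 5, seed = 1L)
  ks <- eval_kernel(k, fs)
  onset_i <- round(2.0 * fs) + 1
  for (ch in seq_len(nrow(lay))) {
    seg <- rec$data[ch, onset_i:(onset_i + length(ks) - 1)]
    expect_equal(seg, topo[ch] * ks, tolerance = 1e-12)
  }

  # two impulses closer than the kernel support: explicit shifted-kernel sum
  tok2 <- toy_tokens(c("w", "v"), onsets = c(1.0, 1.25))
  rec2 <- simulate_subject_eeg(tok2, list(f = c(0.7, -0.4)), list(f = k),
                               fs = fs, layout = lay, duration_s = 4, seed = 1L)
  imp <- numeric(4 * fs)
  imp[round(1.0 * fs) + 1] <- 0.7
  imp[round(1.25 * fs) + 1] <- -0.4
  oracle <- naive_conv(imp, ks)[seq_len(4 * fs)]
  expect_equal(rec2$data[3, ], topo[3] * oracle, tolerance = 1e-10)

  # energy bookkeeping: noiseless variance equals the convolution sum's
  expect_equal(var(as.numeric(rec2$data)),
               var(as.numeric(outer(topo, oracle))), tolerance = 1e-10)

  # zero kernels -> pure noise, uncorrelated with the impulse train
  k0 <- kernel_spec("f", 300, 100, 0, topo, support_ms = 600)
  rec0 <- simulate_subject_eeg(tok2, list(f = c(0.7, -0.4)), list(f = k0),
                               noise = list(white_sd = 1, pink_sd = 0.5,
                                            shared_artifact_sd = 0),
                               fs = fs, layout = lay, duration_s = 4, seed = 2L)
  robs <- abs(cor(rec0$data[1, ], imp))
  null <- replicate(1000, abs(cor(rec0$data[1, ], sample(imp))))
  expect_lt(robs, quantile(null, 0.95) + 1e-12)
})

test_that("cohort generation applies group shifts, gains and the fluency link", {
  w <- tiny_world()
  tok <- list(w$tokens)
  fv <- list(suppressWarnings(compute_word_features(w$tokens, w$E, w$lm)))
  spec <- cohort_spec(n_per_group = 2L, n_channels = 8L, n_trials = 1L,
                      trial_duration_s = 30, fs = 64,
                      gain_sd = 0, latency_jitter_ms = 0,
                      fluency_link = list(intercept = 20, slope = 10,
                                          noise_sd = 0),
                      noise = list(white_sd = 0.1, pink_sd = 0.1,
                                   shared_artifact_sd = 0.1),
                      seed = 5L)
  out <- generate_cohort(spec, tok, fv)
  gt <- out$ground_truth$table
  # older kernels delayed by the group shift, deterministic jitter off
  expect_equal(gt$latency_ms[gt$group == "older"] -
                 gt$latency_ms[gt$group == "younger"], c(74, 74))
  # zero-noise fluency link is a strict function of the dissimilarity gain
  expect_equal(gt$fluency_semantic, 20 + 10 * gt$dissimilarity_gain,
               tolerance = 1e-12)
  # exchangeable groups when the manipulation is off
  spec2 <- spec
  spec2$group_params$older$latency_shift_ms <- 0
  out2 <- generate_cohort(spec2, tok, fv)
  gt2 <- out2$ground_truth$table
  expect_equal(unique(gt2$latency_ms), gt2$latency_ms[1])

  # shift pushing the trough outside the lag support is refused
  spec3 <- spec
  spec3$group_params$older$latency_shift_ms <- 900
  expect_error(generate_cohort(spec3, tok, fv), "outside")

  # determinism at the recording level
  out3 <- generate_cohort(spec, tok, fv)
  expect_identical(out$subjects[[1]]$recordings[[1]]$data,
                   out3$subjects[[1]]$recordings[[1]]$data)
  # shared artifact is the same temporal component for every subject
  expect_identical(attr(out$subjects[[1]]$recordings[[1]], "shared_artifact"),
                   attr(out$subjects[[3]]$recordings[[1]], "shared_artifact"))
})

test_that("fluency is strictly increasing in dissimilarity gain when noise-free", {
  w <- tiny_world()
  tok <- list(w$tokens)
  fv <- list(suppressWarnings(compute_word_features(w$tokens, w$E, w$lm)))
  spec <- cohort_spec(n_per_group = 4L, n_channels = 6L, n_trials = 1L,
                      trial_duration_s = 30, fs = 64, gain_sd = 0.4,
                      fluency_link = list(intercept = 20, slope = 10,
                                          noise_sd = 0),
                      noise = list(white_sd = 0, pink_sd = 0,
                                   shared_artifact_sd = 0),
                      seed = 11L)
  gt <- generate_cohort(spec, tok, fv)$ground_truth$table
  o <- order(gt$dissimilarity_gain)
  expect_true(all(diff(gt$fluency_semantic[o]) > 0))
})

test_that("noiseless forward/inverse round trip recovers the kernel", {
  # with noise -> 0 and small lambda, TRF estimation returns the generating
  # kernel (correlation > 0.999 over the lag support)
  w <- tiny_world()
  fs <- 64
  lay <- channel_layout(6L, mastoids = FALSE)
  topo <- rep(1, 6)
  k <- kernel_spec("dissimilarity", 400, 120, -1, topo)
  tok <- w$tokens
  content <- tok[tok$is_content, ]
  fv <- suppressWarnings(compute_word_features(tok, w$E, w$lm))
  n <- 30 * fs
  trials <- lapply(1:2, function(tr) {
    tt <- generate_transcript(transcript_spec(duration_s = 30, seed = tr), w$corpus)
    vv <- suppressWarnings(compute_word_features(tt, w$E, w$lm))
    rec <- simulate_subject_eeg(tt, list(dissimilarity = vv$dissimilarity),
                                list(dissimilarity = k), fs = fs, layout = lay,
                                duration_s = 30, seed = tr)
    imp <- build_impulse_series(tt[tt$is_content, ],
                                as.numeric(vv$dissimilarity), fs, n,
                                name = "dissimilarity")
    list(feats = list(imp), resp = t(rec$data))
  })
  lw <- lag_window(-100, 700, fs)
  cv <- suppressWarnings(cross_validate(lapply(trials, `[[`, "feats"),
                                        lapply(trials, `[[`, "resp"), lw,
                                        lambda_grid = c(1e-4, 1e-2)))
  est <- apply(cv$model$weights["dissimilarity", , ], 1, mean)
  iv <- which(lw$lag_ms >= 0 & lw$lag_ms <= 700)
  ks <- eval_kernel(k, fs)
  truth <- ks[lw$lags[iv] + 1]
  expect_gt(cor(est[iv], truth), 0.999)
})
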