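# End-to-end orchestration: simulate -> features -> preprocess -> TRF ->
# statistics. The stimulus side (lexicon, corpus, language model, transcripts,
# word features) and the TRF estimation context (shared design matrices and
# Cholesky factorizations - every subject hears the same trials, so the
# penalized normal-equation matrix is subject-independent) are built once and
# can be reused across seeded cohort replicates.

#' Build the stimulus world for an experiment
#'
#' Stages 1-3 of the pipeline: synthetic embeddings, Markov corpus, 5-gram
#' language model, per-trial time-aligned transcripts and the word-level
#' dissimilarity/surprisal values. Deterministic given the config; reusable
#' across cohort replicates (one stimulus, many cohorts).
#'
#' @param config An [experiment_config()].
#' @return A `stimulus_world` list: embeddings, corpus, lm, trial_tokens,
#'   trial_values.
#' @export
build_world <- function(config) {
  embeddings <- generate_embeddings(config$lexicon)
  corpus <- generate_corpus(embeddings, config$corpus$n_sentences,
                            transition_temperature = config$corpus$temperature,
                            seed = mix_seed(config$seed, 21L))
  lm <- train_kneser_ney(corpus, order = 5L)

  n_trials <- config$cohort$n_trials
  trial_tokens <- vector("list", n_trials)
  trial_values <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    ts <- config$transcript
    ts$seed <- mix_seed(config$seed, 22L, tr)
    tok <- generate_transcript(ts, corpus)
    trial_tokens[[tr]] <- tok
    trial_values[[tr]] <- compute_word_features(tok, embeddings, lm,
                                                context = config$context)
  }
  structure(list(embeddings = embeddings, corpus = corpus, lm = lm,
                 trial_tokens = trial_tokens, trial_values = trial_values),
            class = "stimulus_world")
}

#' Run the full synthetic experiment
#'
#' Stages, in order: stimulus world (or reuse), forward-modelled cohort EEG,
#' optional band-pass and MCCA denoising, cross-validated TRF per subject
#' with permutation deltas and trough latencies, then the group statistics.
#'
#' @param config An [experiment_config()].
#' @param world Optional prebuilt [build_world()] result (for many cohorts of
#'   one stimulus).
#' @param context Optional prebuilt TRF context from [trf_context()].
#' @param out_dir Optional directory for JSON/TSV outputs. When it already
#'   holds a report with the same config hash the run is reloaded instead of
#'   recomputed; a different hash is refused.
#' @return An `experiment_report`: `metrics` (one row per subject), `tests`,
#'   `recovery` diagnostics against the simulation ground truth, `config_hash`.
#' @export
run_experiment <- function(config, world = NULL, context = NULL,
                           out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  hash <- config_hash(config)
  if (!is.null(out_dir) && file.exists(file.path(out_dir, "report.json"))) {
    old <- jsonlite::read_json(file.path(out_dir, "report.json"),
                               simplifyVector = TRUE)
    if (!identical(old$config_hash, hash)) {
      stopf("out_dir holds a report for config %s, not %s: refusing to resume",
            old$config_hash, hash)
    }
    return(read_report(out_dir))
  }
  world <- world %||% build_world(config)
  cohort <- generate_cohort(config$cohort, world$trial_tokens,
                            world$trial_values)
  context <- context %||% trf_context(world, config)
  fits <- fit_cohort(cohort, config, context)
  report <- summarize_experiment(world, cohort, fits, config, hash)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# per-trial regressor set: dissimilarity + surprisal + onset nuisance
trial_feature_series <- function(tokens, values, fs, n_samples) {
  content <- tokens[tokens$is_content, , drop = FALSE]
  diss <- build_impulse_series(content, as.numeric(values$dissimilarity),
                               fs, n_samples, name = "dissimilarity")
  sur <- build_impulse_series(content, as.numeric(values$surprisal),
                              fs, n_samples, name = "surprisal")
  ons <- suppressWarnings(
    build_onset_regressor(content, as.numeric(values$dissimilarity),
                          as.numeric(values$surprisal), fs, n_samples))
  list(diss, sur, ons)
}

#' Precompute the subject-independent part of TRF estimation
#'
#' Impulse regressors, sparse lagged designs, normal-equation matrices and
#' per-(fold, lambda) Cholesky factorizations for one stimulus world. All of
#' it is shared by every subject and every cohort replicate.
#'
#' @param world A [build_world()] result.
#' @param config The matching [experiment_config()].
#' @return A `trf_context` (opaque; pass to [run_experiment()]).
#' @export
trf_context <- function(world, config) {
  fs <- config$cohort$fs
  n_samp <- as.integer(round(config$cohort$trial_duration_s * fs))
  feats <- lapply(seq_along(world$trial_tokens), function(tr) {
    trial_feature_series(world$trial_tokens[[tr]], world$trial_values[[tr]],
                         fs, n_samp)
  })
  lags <- lag_window(config$trf$lag_min_ms, config$trf$lag_max_ms, fs)
  designs <- lapply(feats, build_lagged_design, lags = lags)
  lambda_grid <- sort(config$trf$lambda_grid)

  K <- length(designs)
  grams <- lapply(designs, function(X) {
    xtx <- as.matrix(Matrix::crossprod(X))
    cs <- as.numeric(Matrix::colSums(X))
    rbind(cbind(xtx, cs), c(cs, nrow(X)))
  })
  pen <- c(rep(1, ncol(designs[[1]])), 0)
  chols <- vector("list", K)
  for (k in seq_len(K)) {
    A <- Reduce(`+`, grams[-k])
    chols[[k]] <- lapply(lambda_grid, function(l) chol(A + l * diag(pen)))
  }
  A_all <- Reduce(`+`, grams)
  chol_all <- lapply(lambda_grid, function(l) chol(A_all + l * diag(pen)))
  structure(list(feats = feats, lags = lags, designs = designs,
                 lambda_grid = lambda_grid, chols = chols,
                 chol_all = chol_all, n_samp = n_samp, fs = fs),
            class = "trf_context")
}

# stages 4-5: optional preprocessing, shared-design CV fit, per-subject metrics
fit_cohort <- function(cohort, config, ctx, with_deltas = TRUE) {
  subjects <- cohort$subjects
  gt <- cohort$ground_truth
  scalp <- gt$layout$role == "scalp"

  resp <- lapply(subjects, function(su) {
    lapply(su$recordings, function(r) {
      x <- t(r$data[scalp, seq_len(ctx$n_samp), drop = FALSE])
      if (isTRUE(config$preprocess$bandpass)) {
        x <- bandpass(x, config$preprocess$band[1], config$preprocess$band[2],
                      config$preprocess$filter_order, fs = ctx$fs)
      }
      x
    })
  })
  if (isTRUE(config$preprocess$mcca)) {
    groups <- vapply(subjects, `[[`, "", "group")
    for (g in unique(groups)) {
      idx <- which(groups == g)
      stacked <- lapply(idx, function(s) do.call(rbind, resp[[s]]))
      mdl <- suppressWarnings(
        mcca_fit(lapply(stacked, t), n_pc = config$preprocess$n_pc,
                 n_cc = config$preprocess$n_cc))
      lens <- vapply(resp[[idx[1]]], nrow, 0L)
      splits <- rep(seq_along(lens), lens)
      for (j in seq_along(idx)) {
        den <- t(mcca_denoise(t(stacked[[j]]), mdl, subject = j))
        resp[[idx[j]]] <- lapply(seq_along(lens), function(tr) {
          den[splits == tr, , drop = FALSE]
        })
      }
    }
  }

  cvs <- lapply(resp, function(r) cv_subject(ctx, r))
  parietal <- which(gt$topography[scalp] >=
                      stats::quantile(gt$topography[scalp], 0.75))

  metrics <- vector("list", length(subjects))
  deltas <- vector("list", length(subjects))
  for (s in seq_along(subjects)) {
    su <- subjects[[s]]
    cv <- cvs[[s]]
    want <- if (isTRUE(with_deltas)) c("dissimilarity", "surprisal")
            else if (is.character(with_deltas)) with_deltas else character(0)
    na_delta <- list(delta = rep(NA_real_, sum(scalp)))
    d_dis <- if ("dissimilarity" %in% want) {
      permutation_delta(cv, "dissimilarity", config$trf$n_perm,
                        seed = mix_seed(config$seed, 31L, s))
    } else na_delta
    d_sur <- if ("surprisal" %in% want) {
      permutation_delta(cv, "surprisal", config$trf$n_perm,
                        seed = mix_seed(config$seed, 32L, s))
    } else na_delta
    lat_sur <- suppressWarnings(peak_latency(cv$model, "surprisal", parietal))
    lat_dis <- suppressWarnings(peak_latency(cv$model, "dissimilarity", parietal))
    metrics[[s]] <- data.frame(
      subject_id = su$id, group = su$group, age = su$age,
      fluency_semantic = su$fluency_semantic,
      fluency_letter = su$fluency_letter,
      lambda = cv$selected_lambda,
      mean_r = max(cv$mean_accuracy),
      delta_dissimilarity = mean(d_dis$delta[parietal]),
      delta_surprisal = mean(d_sur$delta[parietal]),
      latency_surprisal_ms = as.numeric(lat_sur),
      latency_dissimilarity_ms = as.numeric(lat_dis),
      stringsAsFactors = FALSE)
    deltas[[s]] <- list(dissimilarity = d_dis, surprisal = d_sur)
  }
  list(cvs = cvs, metrics = do.call(rbind, metrics), deltas = deltas,
       parietal = parietal, lags = ctx$lags, scalp = scalp)
}

# cross-validation for one subject against a prebuilt context
cv_subject <- function(ctx, resps) {
  K <- length(ctx$designs)
  lambda_grid <- ctx$lambda_grid
  xtys <- lapply(seq_len(K), function(k) {
    rbind(as.matrix(Matrix::crossprod(ctx$designs[[k]], resps[[k]])),
          colSums(resps[[k]]))
  })
  nch <- ncol(resps[[1]])
  acc <- array(NA_real_, dim = c(length(lambda_grid), K, nch))
  for (k in seq_len(K)) {
    b <- Reduce(`+`, xtys[-k])
    pre <- pearson_precomp(resps[[k]])
    for (li in seq_along(lambda_grid)) {
      ch <- ctx$chols[[k]][[li]]
      W <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
      # intercept column dropped: correlations are shift-invariant
      pred <- as.matrix(ctx$designs[[k]] %*% W[-nrow(W), , drop = FALSE])
      acc[li, k, ] <- pearson_fast(pred, pre)
    }
  }
  mean_acc <- apply(acc, 1, mean)
  best <- which(mean_acc >= max(mean_acc) - 1e-15)[1]  # ties -> smaller lambda
  sel <- lambda_grid[best]

  ch <- ctx$chol_all[[best]]
  b_all <- Reduce(`+`, xtys)
  W_all <- backsolve(ch, backsolve(ch, b_all, transpose = TRUE))
  model <- trf_from_weights(W_all, ctx$designs[[1]], sel, intercept = TRUE)
  fold_models <- lapply(seq_len(K), function(k) {
    chk <- ctx$chols[[k]][[best]]
    b <- Reduce(`+`, xtys[-k])
    trf_from_weights(backsolve(chk, backsolve(chk, b, transpose = TRUE)),
                     ctx$designs[[1]], sel, intercept = TRUE)
  })
  structure(list(selected_lambda = sel, lambda_grid = lambda_grid,
                 accuracy = acc, mean_accuracy = mean_acc, model = model,
                 fold_models = fold_models, designs = ctx$designs,
                 responses = resps, lags = ctx$lags,
                 feature_names = attr(ctx$designs[[1]], "feature_names"),
                 n_lags = attr(ctx$designs[[1]], "n_lags"),
                 trial_features = ctx$feats),
            class = "cv_result")
}

# stage 6: group statistics and ground-truth recovery diagnostics
summarize_experiment <- function(world, cohort, fits, config, hash) {
  m <- fits$metrics
  gt <- cohort$ground_truth

  tests <- figure2_contrasts(m, config$alpha)
  lat <- latency_contrast(data.frame(group = m$group,
                                     peak_latency_ms = m$latency_surprisal_ms))
  old <- m$group == "older"
  flu <- if (sum(old) >= 5) {
    partial_correlation(m$delta_dissimilarity[old], m$fluency_semantic[old],
                        m$age[old])
  } else NULL

  # recovery: estimated vs generating kernels, latencies, deltas vs gains
  gtab <- gt$table[match(m$subject_id, gt$table$subject_id), ]
  interior <- which(fits$lags$lag_ms >= 0 & fits$lags$lag_ms <= 750)
  kcor_for <- function(feature) {
    vapply(seq_len(nrow(m)), function(s) {
      mdl <- fits$cvs[[s]]$model
      tr <- apply(mdl$weights[feature, , fits$parietal, drop = FALSE], 2, mean)
      true_k <- eval_kernel(cohort$subjects[[s]]$kernels[[feature]],
                            config$cohort$fs)
      lag_t <- fits$lags$lag_ms[interior] / 1000 * config$cohort$fs + 1
      truth <- true_k[pmin(length(true_k), pmax(1, round(lag_t)))]
      safe_cor(tr[interior], truth)
    }, 0)
  }
  recovery <- data.frame(
    subject_id = m$subject_id,
    kernel_cor_surprisal = kcor_for("surprisal"),
    kernel_cor_dissimilarity = kcor_for("dissimilarity"),
    latency_error_ms = m$latency_surprisal_ms - gtab$latency_ms,
    stringsAsFactors = FALSE)
  delta_gain_cor <- safe_cor(m$delta_dissimilarity, gtab$dissimilarity_gain)

  structure(list(metrics = m, tests = tests, latency = lat,
                 fluency = flu, recovery = recovery,
                 delta_gain_cor = delta_gain_cor,
                 config_hash = hash,
                 version = as.character(utils::packageVersion("speechtrf"))),
            class = "experiment_report")
}

figure2_contrasts <- function(m, alpha = 0.05) {
  old <- m$group == "older"
  yng <- m$group == "younger"
  if (sum(old) < 2 || sum(yng) < 2) {
    stopf("contrasts need at least 2 subjects per group")
  }
  list(
    older_within = compare_samples(m$delta_surprisal[old],
                                   m$delta_dissimilarity[old], paired = TRUE),
    younger_within = compare_samples(m$delta_surprisal[yng],
                                     m$delta_dissimilarity[yng], paired = TRUE),
    between_dissimilarity = compare_samples(m$delta_dissimilarity[yng],
                                            m$delta_dissimilarity[old]),
    between_surprisal = compare_samples(m$delta_surprisal[yng],
                                        m$delta_surprisal[old]))
}

#' @exportS3Method base::print
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d subjects, config %s\n",
              nrow(x$metrics), x$config_hash))
  cat(sprintf("  latency delay %.1f ms (p = %.3g)\n", x$latency$delay_ms,
              x$latency$test$p_value))
  for (nm in names(x$tests)) {
    cat(sprintf("  %s: p = %.3g (%s)\n", nm, x$tests[[nm]]$p_value,
                x$tests[[nm]]$test_name))
  }
  if (!is.null(x$fluency)) {
    cat(sprintf("  fluency partial r = %.2f (p = %.3g)\n", x$fluency$r,
                x$fluency$p_value))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$metrics, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$recovery, file.path(out_dir, "recovery.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tests <- lapply(report$tests, unclass)
  jsonlite::write_json(
    list(config_hash = report$config_hash, version = report$version,
         tests = tests,
         latency = list(delay_ms = report$latency$delay_ms,
                        p_value = report$latency$test$p_value),
         fluency = report$fluency, delta_gain_cor = report$delta_gain_cor),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# reload a serialized report (tests arrive as plain lists, not test_result)
read_report <- function(out_dir) {
  js <- jsonlite::read_json(file.path(out_dir, "report.json"),
                            simplifyVector = TRUE)
  rep <- structure(
    list(metrics = utils::read.delim(file.path(out_dir, "metrics.tsv")),
         tests = js$tests,
         latency = list(delay_ms = js$latency$delay_ms,
                        test = list(p_value = js$latency$p_value)),
         fluency = js$fluency,
         recovery = utils::read.delim(file.path(out_dir, "recovery.tsv")),
         delta_gain_cor = js$delta_gain_cor,
         config_hash = js$config_hash, version = js$version),
    class = "experiment_report")
  attr(rep, "reloaded") <- TRUE
  rep
}
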