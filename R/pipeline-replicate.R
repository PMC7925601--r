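# Replication-style experiments on synthetic cohorts: the four-way contrast
# pattern, the context-window robustness check, and the fluency correlation.

#' Four-contrast accuracy pattern
#'
#' Runs (or reuses) an experiment and returns the four prediction-accuracy
#' contrasts: within-group surprisal vs dissimilarity for each group, and the
#' between-group comparison for each feature. With the canonical manipulation
#' (older group: delayed kernels, attenuated dissimilarity gain, intact
#' surprisal gain) the expected qualitative pattern is (significant, ns,
#' significant, ns).
#'
#' @param config An [experiment_config()], or an `experiment_report` from
#'   [run_experiment()].
#' @return List of four `test_result`s plus the per-subject metrics.
#' @export
replicate_figure2_pattern <- function(config) {
  report <- if (inherits(config, "experiment_report")) config else run_experiment(config)
  c(report$tests, list(metrics = report$metrics))
}

#' Context-window robustness of the dissimilarity contrast
#'
#' Computes dissimilarity under the sentence context and fixed windows of
#' 3, 5, 7, 9 and 11 words, refits the TRF per mode (surprisal and onset
#' regressors unchanged), and runs a Kruskal-Wallis omnibus test across
#' modes on the per-subject dissimilarity deltas, separately per group.
#'
#' @param config An [experiment_config()].
#' @param modes Context modes (default sentence + windows 3/5/7/9/11).
#' @return List: `deltas` (subject x mode data.frame per group), `tests`
#'   (per-group Kruskal-Wallis `test_result`).
#' @export
replicate_window_robustness <- function(config,
                                        modes = list("sentence", 3L, 5L, 7L,
                                                     9L, 11L)) {
  stopifnot(inherits(config, "experiment_config"))
  world <- build_world(config)
  # the cohort responds to the generative (config) context; only the
  # analysis features vary across modes
  cohort <- generate_cohort(config$cohort, world$trial_tokens,
                            world$trial_values)
  per_mode <- list()
  for (mo in modes) {
    w <- world
    for (tr in seq_along(w$trial_tokens)) {
      w$trial_values[[tr]] <- compute_word_features(
        w$trial_tokens[[tr]], w$embeddings, w$lm, context = mo)
    }
    cfg <- config
    cfg$context <- mo
    fits <- fit_cohort(cohort, cfg, trf_context(w, cfg))
    per_mode[[mode_label(mo)]] <- fits$metrics
  }
  groups <- unique(per_mode[[1]]$group)
  deltas <- list()
  tests <- list()
  for (g in groups) {
    D <- sapply(per_mode, function(m) m$delta_dissimilarity[m$group == g])
    deltas[[g]] <- as.data.frame(D)
    tests[[g]] <- compare_samples(lapply(as.data.frame(D), identity))
  }
  list(deltas = deltas, tests = tests)
}

mode_label <- function(mo) {
  if (identical(mo, "sentence")) "sentence" else sprintf("window%d", as.integer(mo))
}

#' Age-controlled fluency correlation in the older group
#'
#' Partial Pearson correlation (controlling for age) between each older
#' subject's dissimilarity prediction-accuracy delta and their semantic
#' verbal-fluency score.
#'
#' @param config An [experiment_config()] or an `experiment_report`.
#' @return List with `r`, `p_value`, `n`.
#' @export
replicate_fluency_correlation <- function(config) {
  report <- if (inherits(config, "experiment_report")) config else run_experiment(config)
  m <- report$metrics
  old <- m$group == "older"
  if (!any(old)) stopf("no older group in this cohort")
  if (all(is.na(m$fluency_semantic[old]))) stopf("fluency covariate missing")
  partial_correlation(m$delta_dissimilarity[old], m$fluency_semantic[old],
                      m$age[old])
}
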