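# Experiment configuration: one serializable object tying together the
# synthetic world, feature options, preprocessing, TRF estimation and the
# statistical contrasts, all traceable to a single master seed.

#' Build an experiment configuration
#'
#' Defaults give the continuous-integration scale documented in the methods
#' vignette: 8 subjects per group, 32 channels, 4 x 60 s trials at 128 Hz,
#' SNR 0.25. `profile = "paper-scale"` switches to 19 subjects per group,
#' 128 channels and 4 x 180 s trials.
#'
#' @param seed Master seed; every random draw in the run derives from it.
#' @param profile "ci" or "paper-scale".
#' @param lexicon,transcript,cohort Optional spec overrides.
#' @param corpus List: n_sentences, temperature.
#' @param context Dissimilarity context mode ("sentence" or window size).
#' @param trf List: lag_min_ms, lag_max_ms, lambda_grid, n_perm.
#' @param preprocess List: bandpass (logical), band (lo, hi), filter_order,
#'   mcca (logical), n_pc, n_cc.
#' @param alpha Test level for the reported contrasts.
#' @export
experiment_config <- function(seed = 1L, profile = c("ci", "paper-scale"),
                              lexicon = NULL, transcript = NULL, cohort = NULL,
                              corpus = list(n_sentences = 400L, temperature = 0.15),
                              context = "sentence",
                              trf = list(lag_min_ms = -200, lag_max_ms = 800,
                                         lambda_grid = 10^seq(-1, 3, by = 0.5),
                                         n_perm = 5L),
                              preprocess = list(bandpass = FALSE,
                                                band = c(0.5, 8),
                                                filter_order = 4L,
                                                mcca = FALSE,
                                                n_pc = 40L, n_cc = 110L),
                              alpha = 0.05) {
  profile <- match.arg(profile)
  seed <- as.integer(seed)
  big <- profile == "paper-scale"
  lexicon <- lexicon %||% lexicon_spec(seed = mix_seed(seed, 11L))
  transcript <- transcript %||% transcript_spec(
    duration_s = if (big) 180 else 60, seed = mix_seed(seed, 12L))
  cohort <- cohort %||% cohort_spec(
    n_per_group = if (big) 19L else 8L,
    n_channels = if (big) 128L else 32L,
    trial_duration_s = if (big) 180 else 60,
    noise = noise_for_snr(0.25),
    seed = mix_seed(seed, 13L))
  cfg <- structure(list(seed = seed, profile = profile, lexicon = lexicon,
                        transcript = transcript, cohort = cohort,
                        corpus = corpus, context = context, trf = trf,
                        preprocess = preprocess, alpha = alpha),
                   class = "experiment_config")
  cfg
}

#' Stable hash of a configuration
#'
#' Small rolling hash over the canonical JSON serialization; recorded in
#' every report so mismatched-config resumption can be refused.
#' @param config An `experiment_config`.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = 10)
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' Save / load a configuration as JSON
#'
#' Round-trips exactly: `load_config(save_config(cfg, p))` reproduces `cfg`.
#' @param config An `experiment_config`.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lex <- do.call(lexicon_spec, raw$lexicon)
  tra <- do.call(transcript_spec, raw$transcript)
  coh_args <- raw$cohort
  coh_args$group_params <- lapply(coh_args$group_params, as.list)
  coh <- do.call(cohort_spec, coh_args)
  experiment_config(seed = raw$seed, profile = raw$profile,
                    lexicon = lex, transcript = tra, cohort = coh,
                    corpus = as.list(raw$corpus), context = raw$context,
                    trf = as.list(raw$trf),
                    preprocess = as.list(raw$preprocess),
                    alpha = raw$alpha)
}
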