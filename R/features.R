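# Word-level regressors: semantic dissimilarity from an embedding table, and
# sample-rate impulse series whose heights carry the per-word values.

# lower-case and strip surrounding punctuation before any lexicon lookup
normalize_word <- function(w) {
  w <- tolower(w)
  gsub("^[^a-z0-9']+|[^a-z0-9']+$", "", w)
}

#' A small default function-word lexicon
#'
#' English closed-class words (determiners, pronouns, prepositions,
#' conjunctions, auxiliaries). Used by [flag_content_words()] when no lexicon
#' is supplied; synthetic lexica carry their own function-word list instead.
#' @export
function_word_lexicon <- function() {
  c("a", "an", "the", "this", "that", "these", "those", "some", "any", "no",
    "i", "you", "he", "she", "it", "we", "they", "me", "him", "her", "us",
    "them", "my", "your", "his", "its", "our", "their", "mine", "yours",
    "in", "on", "at", "by", "for", "with", "about", "against", "between",
    "into", "through", "during", "before", "after", "above", "below", "to",
    "from", "up", "down", "of", "off", "over", "under", "and", "but", "or",
    "nor", "so", "yet", "if", "then", "than", "because", "while", "as",
    "until", "although", "is", "am", "are", "was", "were", "be", "been",
    "being", "have", "has", "had", "do", "does", "did", "will", "would",
    "shall", "should", "may", "might", "must", "can", "could", "not", "there",
    "here", "when", "where", "who", "whom", "which", "what", "how", "why")
}

#' Flag content words against a function-word lexicon
#'
#' A token is a content word iff its normalized form (lower-cased, surrounding
#' punctuation stripped) is absent from the lexicon.
#'
#' @param tokens A `word_tokens` data.frame.
#' @param lexicon Character vector of lower-cased function words.
#' @return `tokens` with `is_content` set.
#' @export
flag_content_words <- function(tokens, lexicon = function_word_lexicon()) {
  if (nrow(tokens) == 0L) return(tokens)
  tokens$is_content <- !(normalize_word(tokens$word) %in% tolower(lexicon))
  tokens
}

#' Per-word semantic dissimilarity
#'
#' For each content word, 1 minus the Pearson correlation between its
#' embedding and the average embedding of its preceding context words.
#' Context words are preceding *content* words; in `"sentence"` mode all of
#' them within the same sentence, in window mode the `k` most recent ones
#' regardless of sentence boundary. Words with an empty context, or missing
#' from the embedding table, are left unscored (`NA`) and are dropped from
#' the impulse vector downstream.
#'
#' @param tokens `word_tokens` for one trial.
#' @param embeddings An `embedding_table` (matrix with word rownames).
#' @param context `"sentence"` or an integer window size k.
#' @return Numeric vector over content tokens (attribute `tokens` holds the
#'   corresponding token rows); values lie in [0, 2], NA where unscored.
#' @export
semantic_dissimilarity <- function(tokens, embeddings, context = "sentence") {
  windowed <- !identical(context, "sentence")
  if (windowed) {
    k <- as.integer(context)
    if (is.na(k) || k < 1L) stopf("context must be \"sentence\" or a positive window size")
  }
  content <- tokens[tokens$is_content, , drop = FALSE]
  n <- nrow(content)
  vals <- rep(NA_real_, n)
  words <- normalize_word(content$word)
  known <- words %in% rownames(embeddings)
  if (any(!known)) {
    warnf("%d content words missing from the embedding table were left unscored",
          sum(!known))
  }
  for (i in seq_len(n)) {
    if (!known[i]) next
    prev <- if (windowed) {
      idx <- which(seq_len(n) < i & known)
      utils::tail(idx, k)
    } else {
      which(seq_len(n) < i & known & content$sentence_id == content$sentence_id[i])
    }
    if (length(prev) == 0L) next
    ctx <- colMeans(embeddings[words[prev], , drop = FALSE])
    r <- safe_cor(embeddings[words[i], ], ctx)
    if (!is.na(r)) vals[i] <- 1 - r
  }
  attr(vals, "tokens") <- content
  vals
}

#' Rescale values to match a reference distribution's moments
#'
#' `values' = (values - mean) / sd * sd_ref + mean_ref`, the convention used
#' to put surprisal on the dissimilarity scale before joint regression.
#'
#' @param values Numeric vector (sd > 0 after dropping NAs).
#' @param reference_values Numeric vector, or a list/vector with elements
#'   `mean` and `sd` giving the target moments directly.
#' @export
normalize_match <- function(values, reference_values) {
  if (is.list(reference_values) ||
      (!is.null(names(reference_values)) &&
       all(c("mean", "sd") %in% names(reference_values)))) {
    m_ref <- reference_values[["mean"]]
    s_ref <- reference_values[["sd"]]
  } else {
    m_ref <- mean(reference_values, na.rm = TRUE)
    s_ref <- stats::sd(reference_values, na.rm = TRUE)
  }
  if (s_ref <= 0 || is.na(s_ref)) stopf("reference distribution has sd <= 0")
  s <- stats::sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0) stopf("cannot match distribution: input values are constant")
  (values - mean(values, na.rm = TRUE)) / s * s_ref + m_ref
}

#' Build a sample-rate impulse series from per-word values
#'
#' Each scored word contributes its value at sample `round(onset_s * fs)`
#' (0-based time, 1-based R index `round(onset_s * fs) + 1`). Colliding
#' onsets are summed with a warning; NA values are skipped.
#'
#' @param tokens Token rows aligned with `values`.
#' @param values Numeric per-token values (NA = unscored, omitted).
#' @param fs Sampling rate.
#' @param n_samples Series length.
#' @param name Feature label.
#' @return A `feature_impulse_series`: list(name, values, fs,
#'   word_index_map) where `word_index_map` maps sample index -> token row.
#' @export
build_impulse_series <- function(tokens, values, fs, n_samples, name = "feature") {
  stopifnot(nrow(tokens) == length(values))
  keep <- which(!is.na(values))
  x <- numeric(n_samples)
  idx_map <- integer(0)
  if (length(keep)) {
    samp <- as.integer(round(tokens$onset_s[keep] * fs)) + 1L
    late <- samp > n_samples | samp < 1L
    if (any(late)) {
      stopf("token '%s' at %.3f s falls outside the %d-sample trial",
            tokens$word[keep[late][1]], tokens$onset_s[keep[late][1]], n_samples)
    }
    if (anyDuplicated(samp)) {
      warnf("impulse collisions: %d onsets share a sample; heights summed",
            sum(duplicated(samp)))
    }
    for (j in seq_along(keep)) {
      x[samp[j]] <- x[samp[j]] + values[keep[j]]
    }
    idx_map <- stats::setNames(keep, samp)
  }
  structure(list(name = name, values = x, fs = fs, word_index_map = idx_map),
            class = "feature_impulse_series")
}

#' @exportS3Method base::print
print.feature_impulse_series <- function(x, ...) {
  cat(sprintf("<feature_impulse_series> '%s': %d samples @ %g Hz, %d impulses\n",
              x$name, length(x$values), x$fs, sum(x$values != 0)))
  invisible(x)
}

#' Onset nuisance regressor
#'
#' A constant-height impulse at every scored content-word onset; the height is
#' the mean of the trial's pooled dissimilarity and surprisal values, so the
#' regressor captures acoustic-onset variance at a comparable scale.
#'
#' @param tokens Token rows of the scored words.
#' @param dissimilarity,surprisal Per-token feature values (NA = unscored).
#' @param fs,n_samples As in [build_impulse_series()].
#' @export
build_onset_regressor <- function(tokens, dissimilarity, surprisal, fs, n_samples) {
  scored <- !is.na(dissimilarity) & !is.na(surprisal)
  if (!any(scored)) {
    warnf("no scored words: onset regressor is all zeros")
    return(build_impulse_series(tokens[0, , drop = FALSE], numeric(0), fs,
                                n_samples, name = "onset"))
  }
  h <- mean(c(dissimilarity[scored], surprisal[scored]))
  vals <- ifelse(scored, h, NA_real_)
  build_impulse_series(tokens, vals, fs, n_samples, name = "onset")
}

#' Compute the full word-feature set for one trial
#'
#' Convenience wrapper: dissimilarity (given context mode), surprisal under a
#' 5-gram model normalized to the dissimilarity distribution, and application
#' of the common-impulse rule (a word unscored in either feature is dropped
#' from both).
#'
#' @param tokens `word_tokens` for the trial.
#' @param embeddings An `embedding_table`.
#' @param model An `ngram_model` from [train_kneser_ney()].
#' @param context Dissimilarity context mode (`"sentence"` or window size).
#' @param reference_moments Optional list(mean, sd) for [normalize_match()];
#'   default matches surprisal to the trial's dissimilarity distribution.
#' @return Named list of per-token value vectors (`dissimilarity`,
#'   `surprisal`), each carrying the scored token rows in `attr(., "tokens")`.
#' @export
compute_word_features <- function(tokens, embeddings, model,
                                  context = "sentence",
                                  reference_moments = NULL) {
  diss <- semantic_dissimilarity(tokens, embeddings, context)
  content <- attr(diss, "tokens")
  sur_all <- surprisal(model, tokens)
  sur <- sur_all[tokens$is_content]
  # common-impulse rule: drop words unscored in either feature
  common <- !is.na(diss) & !is.na(sur)
  diss[!common] <- NA_real_
  sur[!common] <- NA_real_
  ref <- reference_moments %||%
    list(mean = mean(diss, na.rm = TRUE), sd = stats::sd(diss, na.rm = TRUE))
  sur[common] <- normalize_match(sur[common], ref)
  attr(sur, "tokens") <- content
  list(dissimilarity = diss, surprisal = sur)
}
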