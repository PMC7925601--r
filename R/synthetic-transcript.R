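# Synthetic time-aligned transcript: word tokens with onsets, offsets and
# sentence indices, emulating a narrated audiobook at a target speech rate.

#' Specify a synthetic transcript
#'
#' Defaults follow a natural single-speaker narration: 190 words per minute,
#' content-word durations 334 +/- 140 ms (truncated normal, floored at 50 ms).
#'
#' @param duration_s Trial duration in seconds.
#' @param words_per_minute Target speech rate.
#' @param word_dur_mean_s,word_dur_sd_s Content-word duration moments (s).
#' @param mean_sentence_len Mean words per sentence.
#' @param content_word_fraction Fraction of tokens that are content words.
#' @param seed Integer seed.
#' @export
transcript_spec <- function(duration_s = 180, words_per_minute = 190,
                            word_dur_mean_s = 0.334, word_dur_sd_s = 0.140,
                            mean_sentence_len = 10, content_word_fraction = 0.85,
                            seed = 1L) {
  if (duration_s <= 0 || words_per_minute <= 0 || word_dur_mean_s <= 0) {
    stopf("invalid transcript spec: duration, rate and mean duration must be positive")
  }
  structure(list(duration_s = duration_s, words_per_minute = words_per_minute,
                 word_dur_mean_s = word_dur_mean_s, word_dur_sd_s = word_dur_sd_s,
                 mean_sentence_len = mean_sentence_len,
                 content_word_fraction = content_word_fraction,
                 seed = as.integer(seed)),
            class = "transcript_spec")
}

# truncated normal by rejection with a hard floor
rtruncnorm_floor <- function(n, mean, sd, floor = 0.05) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < floor)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < floor]
  }
  x
}

#' Generate a time-aligned transcript
#'
#' Words are drawn sentence-by-sentence from the corpus sampler; inter-onset
#' intervals are jittered around `60 / words_per_minute` so the realized rate
#' stays within a few percent of the target, and onsets are strictly
#' increasing. A token is a content word iff it is not in the lexicon's
#' function-word list; the spec's `content_word_fraction` overrides the
#' sampler's function-word probability so the transcript hits the requested
#' density.
#'
#' @param spec A [transcript_spec()].
#' @param corpus A [generate_corpus()] result (used as a sentence sampler).
#' @return A `word_tokens` data.frame: word, onset_s, offset_s, sentence_id,
#'   is_content.
#' @export
generate_transcript <- function(spec, corpus) {
  stopifnot(inherits(spec, "transcript_spec"), inherits(corpus, "corpus"))
  n_words <- max(1L, as.integer(round(spec$duration_s * spec$words_per_minute / 60)))
  slen <- max(2L, as.integer(round(spec$mean_sentence_len)))
  n_sent <- as.integer(ceiling(n_words / slen)) + 1L

  with_seed(spec$seed, {
    sent_seed <- mix_seed(spec$seed, 7L)
    sents <- generate_corpus(attr(corpus, "embeddings"), n_sent,
                             transition_temperature = attr(corpus, "transition_temperature"),
                             sentence_length = slen,
                             function_word_prob = 1 - spec$content_word_fraction,
                             start_words = attr(corpus, "start_words"),
                             seed = sent_seed)
    words <- unlist(sents)[seq_len(n_words)]
    sentence_id <- rep(seq_along(sents), each = slen)[seq_len(n_words)]

    gap <- 60 / spec$words_per_minute
    gaps <- pmax(0.05, stats::rnorm(n_words, gap, 0.04 * gap))
    gaps <- gaps * (gap * n_words) / sum(gaps)   # pin realized rate to target
    onsets <- cumsum(c(0, gaps[-n_words]))
    durs <- rtruncnorm_floor(n_words, spec$word_dur_mean_s, spec$word_dur_sd_s)

    fun_words <- attr(attr(corpus, "embeddings"), "function_words") %||% character(0)
    tok <- data.frame(word = words,
                      onset_s = onsets,
                      offset_s = onsets + durs,
                      sentence_id = sentence_id,
                      is_content = !(words %in% fun_words),
                      stringsAsFactors = FALSE)
    class(tok) <- c("word_tokens", "data.frame")
    tok
  })
}

#' Write / read a transcript as TSV
#'
#' Columns: word, onset_s, offset_s, sentence_id, is_content.
#' @param tokens A `word_tokens` data.frame.
#' @param path Output path.
#' @export
write_transcript <- function(tokens, path) {
  utils::write.table(as.data.frame(tokens), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_transcript
#' @export
read_transcript <- function(path) {
  tok <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("word", "onset_s", "offset_s", "sentence_id", "is_content")
  if (!all(need %in% names(tok))) {
    stopf("transcript file %s lacks required columns (%s)", path,
          paste(setdiff(need, names(tok)), collapse = ", "))
  }
  tok$is_content <- as.logical(tok$is_content)
  class(tok) <- c("word_tokens", "data.frame")
  tok
}

#' Write / read embeddings in plain text (word + floats per line)
#'
#' The format is the whitespace-delimited one used by common pretrained
#' embedding distributions: one word per line followed by its vector.
#' @param embeddings Matrix with word rownames.
#' @param path File path.
#' @export
write_embeddings <- function(embeddings, path) {
  df <- data.frame(word = rownames(embeddings),
                   as.data.frame(unclass(embeddings)[, , drop = FALSE]))
  utils::write.table(df, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  E <- as.matrix(raw[, -1, drop = FALSE])
  if (anyNA(E)) stopf("embedding file %s contains non-numeric entries", path)
  dimnames(E) <- list(raw[[1]], NULL)
  structure(E, class = c("embedding_table", "matrix", "array"))
}
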