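# Synthetic lexicon: category-structured word embeddings and a Markov
# corpus generator. These stand in for a pretrained embedding table and the
# large text corpus an n-gram language model would normally be trained on,
# giving downstream feature code inputs with known semantic structure.

#' Specify a synthetic lexicon
#'
#' Words are organised into semantic categories; each word's embedding is a
#' convex mixture of its category centroid and an idiosyncratic direction, so
#' that within-category cosine similarity exceeds between-category similarity
#' by construction. A configurable fraction of the vocabulary is reserved as
#' function words (determiners, pronouns, ...), which carry embeddings but no
#' semantic category.
#'
#' @param vocab_size Number of words (content + function).
#' @param embed_dim Embedding dimensionality (300 mirrors common pretrained
#'   tables; tests use smaller values).
#' @param n_categories Number of semantic categories for content words.
#' @param within_category_similarity Target expected cosine similarity between
#'   two words of the same category, in (0, 1).
#' @param function_word_fraction Fraction of the vocabulary reserved as
#'   function words.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `lexicon_spec` list.
#' @export
lexicon_spec <- function(vocab_size = 600L, embed_dim = 300L,
                         n_categories = 12L,
                         within_category_similarity = 0.6,
                         function_word_fraction = 0.15,
                         seed = 1L) {
  vocab_size <- as.integer(vocab_size)
  n_categories <- as.integer(n_categories)
  if (vocab_size < n_categories || n_categories < 1L) {
    stopf("invalid lexicon spec: need vocab_size >= n_categories >= 1 (got %d, %d)",
          vocab_size, n_categories)
  }
  if (embed_dim < 2L) stopf("invalid lexicon spec: embed_dim must be >= 2")
  if (within_category_similarity <= 0 || within_category_similarity >= 1) {
    stopf("within_category_similarity must lie in (0, 1)")
  }
  structure(list(vocab_size = vocab_size, embed_dim = as.integer(embed_dim),
                 n_categories = n_categories,
                 within_category_similarity = within_category_similarity,
                 function_word_fraction = function_word_fraction,
                 seed = as.integer(seed)),
            class = "lexicon_spec")
}

#' Generate a category-structured embedding table
#'
#' Each content word's unit vector is `s * centroid + sqrt(1 - s^2) * noise`
#' with `s = sqrt(within_category_similarity)`, so the expected cosine between
#' two words of one category is the requested similarity and tends to 1 as the
#' similarity does. Function words get independent random directions.
#'
#' @param spec A [lexicon_spec()].
#' @param noise Scale of the idiosyncratic component; the default (`NULL`)
#'   derives it from the similarity target. `noise = 0` with similarity near 1
#'   collapses each category onto its centroid.
#' @return An `embedding_table`: numeric matrix (vocab x embed_dim) with word
#'   rownames and attributes `categories` (integer, NA for function words) and
#'   `function_words` (character).
#' @export
generate_embeddings <- function(spec, noise = NULL) {
  stopifnot(inherits(spec, "lexicon_spec"))
  with_seed(spec$seed, {
    V <- spec$vocab_size
    d <- spec$embed_dim
    n_fun <- max(0L, min(V - spec$n_categories,
                         as.integer(round(spec$function_word_fraction * V))))
    n_con <- V - n_fun
    words <- c(if (n_fun > 0) sprintf("f%03d", seq_len(n_fun)),
               sprintf("w%04d", seq_len(n_con)))
    cats <- c(rep(NA_integer_, n_fun),
              rep_len(seq_len(spec$n_categories), n_con))

    unit <- function(v) v / sqrt(sum(v^2))
    centroids <- t(apply(matrix(stats::rnorm(spec$n_categories * d), ncol = d),
                         1, unit))
    s <- sqrt(spec$within_category_similarity)
    nscale <- if (is.null(noise)) sqrt(1 - s^2) else noise

    E <- matrix(0, V, d, dimnames = list(words, NULL))
    for (i in seq_len(V)) {
      if (is.na(cats[i])) {
        E[i, ] <- unit(stats::rnorm(d))
      } else {
        eps <- if (nscale > 0) nscale * unit(stats::rnorm(d)) else 0
        v <- s * centroids[cats[i], ] + eps
        E[i, ] <- unit(v)
      }
    }
    structure(E, categories = cats, function_words = words[is.na(cats)],
              class = c("embedding_table", "matrix", "array"))
  })
}

#' @exportS3Method base::print
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d words x %d dims (%d function words)\n",
              nrow(x), ncol(x), length(attr(x, "function_words"))))
  invisible(x)
}

#' Generate a synthetic training corpus
#'
#' Sentences are sampled from a category-biased first-order Markov chain over
#' content words: the transition score from word w to w' is their embedding
#' cosine, turned into probabilities by a softmax with the given temperature.
#' Low temperature concentrates mass on few transitions so that some 5-grams
#' recur many times (low surprisal) while others never occur (high surprisal).
#' Function words are interspersed as independent draws.
#'
#' @param embeddings An `embedding_table`.
#' @param n_sentences Number of sentences; 0 is an error.
#' @param transition_temperature Softmax temperature; 0 means deterministic
#'   argmax transitions.
#' @param sentence_length Words per sentence (fixed; keeps the temperature-0
#'   limit fully deterministic).
#' @param function_word_prob Probability that any token position is a function
#'   word.
#' @param start_words Optional character vector of allowed sentence-initial
#'   words; default is all content words.
#' @param seed Integer seed.
#' @return A `corpus`: list of character vectors (one per sentence), with the
#'   sampler parameters kept as attributes so transcripts can reuse them.
#' @export
generate_corpus <- function(embeddings, n_sentences, transition_temperature = 0.15,
                            sentence_length = 8L, function_word_prob = 0.15,
                            start_words = NULL, seed = 1L) {
  if (n_sentences < 1L) stopf("empty corpus requested: n_sentences must be >= 1")
  if (nrow(embeddings) == 0L) stopf("empty vocabulary")
  fun_words <- attr(embeddings, "function_words") %||% character(0)
  content <- setdiff(rownames(embeddings), fun_words)
  if (length(content) == 0L) stopf("no content words in vocabulary")
  if (is.null(start_words)) start_words <- content
  Ec <- embeddings[content, , drop = FALSE]
  sim <- Ec %*% t(Ec)          # cosine similarities (rows are unit vectors)
  diag(sim) <- -Inf            # no self-transitions

  sents <- with_seed(seed, {
    lapply(seq_len(n_sentences), function(si) {
      out <- character(sentence_length)
      prev <- NULL
      for (k in seq_len(sentence_length)) {
        is_fun <- length(fun_words) > 0 && stats::runif(1) < function_word_prob
        if (is_fun) {
          out[k] <- sample(fun_words, 1L)
          next                  # function words do not advance the chain
        }
        if (is.null(prev)) {
          out[k] <- if (length(start_words) == 1L) start_words else sample(start_words, 1L)
        } else {
          sc <- sim[prev, ]
          sc[content %in% out[seq_len(k - 1L)]] <- -Inf  # no repeats in a sentence
          if (transition_temperature <= 0) {
            out[k] <- content[which.max(sc)]
          } else {
            p <- exp((sc - max(sc[is.finite(sc)])) / transition_temperature)
            p[!is.finite(p)] <- 0
            out[k] <- sample(content, 1L, prob = p)
          }
        }
        prev <- out[k]
      }
      out
    })
  })
  structure(sents, class = "corpus", embeddings = embeddings,
            transition_temperature = transition_temperature,
            sentence_length = as.integer(sentence_length),
            function_word_prob = function_word_prob,
            start_words = start_words)
}

#' @exportS3Method base::print
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d sentences, %d tokens\n", length(x),
              sum(lengths(x))))
  invisible(x)
}

#' Draw fresh sentences from the sampler that produced a corpus
#'
#' @param corpus A [generate_corpus()] result.
#' @param n_sentences Number of sentences to draw.
#' @param seed Integer seed (independent of the corpus seed).
#' @return A `corpus` object.
#' @export
sample_sentences <- function(corpus, n_sentences, seed) {
  generate_corpus(attr(corpus, "embeddings"), n_sentences,
                  transition_temperature = attr(corpus, "transition_temperature"),
                  sentence_length = attr(corpus, "sentence_length"),
                  function_word_prob = attr(corpus, "function_word_prob"),
                  start_words = attr(corpus, "start_words"),
                  seed = seed)
}
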