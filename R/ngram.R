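# Interpolated modified Kneser-Ney n-gram language model.
#
# The highest order uses raw counts; every lower order uses continuation
# counts (number of distinct left contexts). Each order carries three
# absolute discounts D1, D2, D3+ estimated from count-of-count statistics,
# and lower orders are always interpolated in (never backoff-only), so the
# model assigns positive probability to every in-vocabulary word after any
# history and sums to one exactly.

SEP <- "\x1f"
BOS <- "<s>"
EOS <- "</s>"
UNK <- "<unk>"
ROOT <- "\x1d"   # environment key for the empty (unigram) history

ng_key <- function(words) paste(words, collapse = SEP)

#' Train an interpolated modified Kneser-Ney model
#'
#' @param corpus A `corpus` (list of character-vector sentences) or a
#'   `word_tokens` data.frame (sentences recovered from `sentence_id`).
#' @param order Model order (5 = probability of a word given the 4 preceding
#'   words).
#' @return An `ngram_model`.
#' @details Discounts per order follow the count-of-counts estimator
#'   `Y = n1/(n1 + 2 n2)`, `D1 = 1 - 2Y n2/n1`, `D2 = 2 - 3Y n3/n2`,
#'   `D3+ = 3 - 4Y n4/n3`. When a corpus is too small to populate the needed
#'   count-of-counts (or yields out-of-range estimates) the affected order
#'   falls back to a fixed discount of 0.75 with a warning.
#' @export
train_kneser_ney <- function(corpus, order = 5L) {
  sents <- corpus_sentences(corpus)
  if (length(sents) == 0L || sum(lengths(sents)) == 0L) stopf("empty corpus")
  order <- as.integer(order)
  sents <- lapply(sents, function(s) {
    s <- normalize_word(s)
    s[nzchar(s)]
  })
  sents <- sents[lengths(sents) > 0]
  vocab <- sort(unique(unlist(sents)))
  pred_vocab <- c(vocab, EOS, UNK)     # words the model can predict

  # raw n-gram counts at the top order over BOS-padded sentences
  top <- new.env(parent = emptyenv(), hash = TRUE)
  for (s in sents) {
    padded <- c(rep(BOS, order - 1L), s, EOS)
    for (i in seq_len(length(padded) - order + 1L)) {
      k <- ng_key(padded[i:(i + order - 1L)])
      top[[k]] <- (top[[k]] %||% 0) + 1
    }
  }

  # continuation counts for each lower order: distinct left contexts
  tables <- vector("list", order)
  tables[[order]] <- top
  src <- top
  for (k in seq(order - 1L, 1L)) {
    seen <- new.env(parent = emptyenv(), hash = TRUE)   # left-type sets
    tab <- new.env(parent = emptyenv(), hash = TRUE)
    for (key in ls(src, sorted = FALSE)) {
      w <- strsplit(key, SEP, fixed = TRUE)[[1]]
      suffix <- ng_key(w[-1])
      left <- w[1]
      skey <- paste(suffix, left, sep = "\x1e")
      if (is.null(seen[[skey]])) {
        seen[[skey]] <- TRUE
        tab[[suffix]] <- (tab[[suffix]] %||% 0) + 1
      }
    }
    tables[[k]] <- tab
    src <- tab
  }

  # per-history totals and N1/N2/N3+ type counts, per order
  hists <- vector("list", order)
  for (k in seq_len(order)) {
    h <- new.env(parent = emptyenv(), hash = TRUE)
    for (key in ls(tables[[k]], sorted = FALSE)) {
      cnt <- tables[[k]][[key]]
      w <- strsplit(key, SEP, fixed = TRUE)[[1]]
      hk <- if (k > 1L) ng_key(w[-k]) else ROOT
      cur <- h[[hk]] %||% c(0, 0, 0, 0)
      bucket <- if (cnt == 1) 2L else if (cnt == 2) 3L else 4L
      cur[1] <- cur[1] + cnt
      cur[bucket] <- cur[bucket] + 1
      h[[hk]] <- cur
    }
    hists[[k]] <- h
  }

  discounts <- matrix(NA_real_, order, 3,
                      dimnames = list(NULL, c("D1", "D2", "D3")))
  fell_back <- integer(0)
  for (k in seq_len(order)) {
    cc <- table(factor(unlist(lapply(ls(tables[[k]], sorted = FALSE),
                                     function(x) tables[[k]][[x]])),
                       levels = 1:4))
    n1 <- cc[["1"]]; n2 <- cc[["2"]]; n3 <- cc[["3"]]; n4 <- cc[["4"]]
    ok <- n1 > 0 && n2 > 0 && n3 > 0 && n4 > 0
    if (ok) {
      Y <- n1 / (n1 + 2 * n2)
      D <- c(1 - 2 * Y * n2 / n1, 2 - 3 * Y * n3 / n2, 3 - 4 * Y * n4 / n3)
      ok <- all(is.finite(D)) && all(D > 0) && all(D <= 1:3)
    }
    if (ok) discounts[k, ] <- D else {
      discounts[k, ] <- rep(0.75, 3)
      fell_back <- c(fell_back, k)
    }
  }
  if (length(fell_back)) {
    warnf("count-of-counts too sparse at order(s) %s; using fixed discount 0.75",
          paste(fell_back, collapse = ", "))
  }

  structure(list(order = order, tables = tables, hists = hists,
                 discounts = discounts, vocab = vocab,
                 pred_vocab = pred_vocab),
            class = "ngram_model")
}

corpus_sentences <- function(corpus) {
  if (inherits(corpus, "corpus") || (is.list(corpus) && !is.data.frame(corpus))) {
    return(corpus)
  }
  if (is.data.frame(corpus)) {
    return(split(corpus$word, corpus$sentence_id))
  }
  stopf("corpus must be a list of sentences or a word_tokens data.frame")
}

#' @exportS3Method base::print
print.ngram_model <- function(x, ...) {
  cat(sprintf("<ngram_model> order %d, |V| = %d, %d distinct %d-grams\n",
              x$order, length(x$pred_vocab), length(ls(x$tables[[x$order]])),
              x$order))
  invisible(x)
}

map_unk <- function(model, words) {
  special <- words %in% c(BOS, EOS, UNK)
  words[!special] <- normalize_word(words[!special])
  ifelse(special | words %in% model$vocab, words, UNK)
}

#' Conditional n-gram probability
#'
#' `P(word | history)` under the interpolated modified Kneser-Ney recursion.
#' Out-of-vocabulary words map to the unknown symbol; histories longer than
#' `order - 1` are truncated from the left.
#'
#' @param model An `ngram_model`.
#' @param word Single word.
#' @param history Character vector of preceding words (oldest first).
#' @export
ngram_prob <- function(model, word, history = character(0)) {
  w <- map_unk(model, word)
  h <- map_unk(model, history)
  n <- length(h)
  if (n > model$order - 1L) h <- h[(n - model$order + 2L):n]
  kn_prob(model, w, h, length(h) + 1L)
}

kn_prob <- function(model, w, h, k) {
  if (k == 1L) {
    tab <- model$tables[[1]]
    st <- model$hists[[1]][[ROOT]] %||% c(0, 0, 0, 0)
    V <- length(model$pred_vocab)
    if (st[1] == 0) return(1 / V)
    D <- unname(model$discounts[1, ])
    cnt <- tab[[w]] %||% 0
    gamma <- (D[1] * st[2] + D[2] * st[3] + D[3] * st[4]) / st[1]
    return(max(cnt - disc_for(cnt, D), 0) / st[1] + gamma / V)
  }
  hk <- ng_key(h)
  st <- model$hists[[k]][[hk]]
  if (is.null(st) || st[1] == 0) return(kn_prob(model, w, h[-1], k - 1L))
  D <- unname(model$discounts[k, ])
  cnt <- model$tables[[k]][[ng_key(c(h, w))]] %||% 0
  gamma <- (D[1] * st[2] + D[2] * st[3] + D[3] * st[4]) / st[1]
  max(cnt - disc_for(cnt, D), 0) / st[1] + gamma * kn_prob(model, w, h[-1], k - 1L)
}

disc_for <- function(cnt, D) {
  if (cnt == 0) 0 else if (cnt == 1) D[1] else if (cnt == 2) D[2] else D[3]
}

#' Per-word lexical surprisal
#'
#' `-log P(word | up to order-1 preceding words)` (natural log) for every
#' token, with histories built from all words (content and function) and
#' truncated at sentence starts.
#'
#' @param model An `ngram_model`.
#' @param tokens `word_tokens` (or character vector of one sentence).
#' @return Numeric vector of surprisals (>= 0), one per token.
#' @export
surprisal <- function(model, tokens) {
  if (is.character(tokens)) {
    tokens <- data.frame(word = tokens, sentence_id = 1L,
                         stringsAsFactors = FALSE)
  }
  n <- nrow(tokens)
  out <- numeric(n)
  ctx <- model$order - 1L
  for (i in seq_len(n)) {
    same <- tokens$sentence_id == tokens$sentence_id[i]
    prev_idx <- which(same & seq_len(n) < i)
    prev <- utils::tail(tokens$word[prev_idx], ctx)
    hist <- c(rep(BOS, ctx - length(prev)), prev)  # pad to full order
    out[i] <- -log(ngram_prob(model, tokens$word[i], hist))
  }
  out
}
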