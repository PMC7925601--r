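# Independent oracles: deliberately naive re-derivations used to check the
# package's optimized paths. None of these call package internals.

# O(n*m) direct convolution
naive_conv <- function(x, k) {
  n <- length(x); m <- length(k)
  out <- numeric(n + m - 1)
  for (i in seq_len(n)) {
    if (x[i] != 0) {
      out[i:(i + m - 1)] <- out[i:(i + m - 1)] + x[i] * k
    }
  }
  out
}

# dense ridge solve with unpenalized intercept, via base solve()
dense_ridge <- function(X, y, lambda, intercept = TRUE) {
  X <- as.matrix(X)
  if (intercept) X <- cbind(X, 1)
  pen <- c(rep(1, ncol(X) - intercept), if (intercept) 0)
  solve(crossprod(X) + lambda * diag(pen), crossprod(X, y))
}

# Benjamini-Hochberg step-up straight from the definition: find the largest
# k with p_(k) <= k * alpha / m; reject all p <= p_(k)
bh_reject_bruteforce <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  ks <- which(ps <= seq_len(m) * alpha / m)
  if (length(ks) == 0L) return(rep(FALSE, m))
  p <- p
  p <= ps[max(ks)]
}

# --- naive interpolated modified Kneser-Ney with fixed discount ------------
# Builds the count tables with plain named lists and walks the recursion
# directly; only valid for corpora small enough that the package falls back
# to the fixed 0.75 discount at every order.
naive_kn_tables <- function(sents, order) {
  cnt <- function() list()
  tabs <- vector("list", order)
  top <- list()
  for (s in sents) {
    pad <- c(rep("<s>", order - 1), s, "</s>")
    for (i in seq_len(length(pad) - order + 1)) {
      key <- paste(pad[i:(i + order - 1)], collapse = " ")
      top[[key]] <- (if (is.null(top[[key]])) 0 else top[[key]]) + 1
    }
  }
  tabs[[order]] <- top
  src <- top
  for (k in seq(order - 1, 1)) {
    tab <- list()
    seen <- character(0)
    for (key in names(src)) {
      w <- strsplit(key, " ", fixed = TRUE)[[1]]
      sfx <- paste(w[-1], collapse = " ")
      sig <- paste(sfx, "|", w[1])
      if (!(sig %in% seen)) {
        seen <- c(seen, sig)
        tab[[sfx]] <- (if (is.null(tab[[sfx]])) 0 else tab[[sfx]]) + 1
      }
    }
    tabs[[k]] <- tab
    src <- tab
  }
  tabs
}

naive_kn_prob <- function(sents, word, hist, order = 5, D = 0.75, pad = TRUE) {
  tabs <- naive_kn_tables(sents, order)
  vocab <- sort(unique(unlist(sents)))
  V <- length(vocab) + 2                      # + </s> + <unk>
  if (pad) {
    hist <- c(rep("<s>", max(0, order - 1 - length(hist))), hist)
    if (length(hist) > order - 1) {
      hist <- hist[(length(hist) - order + 2):length(hist)]
    }
  }

  rec <- function(w, h, k) {
    tab <- tabs[[k]]
    if (k == 1) {
      tot <- sum(unlist(tab))
      if (tot == 0) return(1 / V)
      cw <- if (is.null(tab[[w]])) 0 else tab[[w]]
      gamma <- D * length(tab) / tot
      return(max(cw - if (cw > 0) D else 0, 0) / tot + gamma / V)
    }
    hkey <- paste(h, collapse = " ")
    keys <- names(tab)
    mine <- keys[startsWith(keys, paste0(hkey, " ")) &
                   lengths(strsplit(keys, " ", fixed = TRUE)) == k]
    tot <- sum(unlist(tab[mine]))
    if (tot == 0) return(rec(w, h[-1], k - 1))
    full <- paste(c(h, w), collapse = " ")
    cw <- if (is.null(tab[[full]])) 0 else tab[[full]]
    ntypes <- length(mine)
    gamma <- D * ntypes / tot
    max(cw - if (cw > 0) D else 0, 0) / tot + gamma * rec(w, h[-1], k - 1)
  }
  rec(word, hist, length(hist) + 1)
}

# closed-form partial correlation from the three pairwise correlations
partial_cor_closed <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}
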