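# Internal helpers shared across modules.

#' Evaluate an expression with a locally fixed RNG seed
#'
#' Saves and restores `.Random.seed` so that generators are deterministic
#' given their `seed` argument without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic integer mixing for sub-seeds (subject / fold / perm streams).
# Keeps results below 2^31 so set.seed() accepts them.
mix_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 17
  for (p in parts) {
    # multiplier kept small so h * 69069 stays exact in double precision
    h <- (h * 69069 + (as.numeric(p) %% 2147483647) + 12345) %% 2147483647
  }
  as.integer(h)
}

#' Moore-Penrose pseudoinverse via SVD
#' @noRd
pinv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Pearson correlation that tolerates zero-variance inputs (returns NA).
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
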