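# Statistical battery with parametric/nonparametric gating. Parametric tests
# are only used when every sample passes an Anderson-Darling normality test
# (alpha = 0.05) and contains no point outside the 1.5 IQR fences; otherwise
# the rank-based counterpart runs. Outliers trigger routing only, never
# removal.

#' Anderson-Darling test for composite normality
#'
#' Case with estimated mean and variance; the small-sample correction and
#' p-value approximation follow D'Agostino & Stephens (1986).
#'
#' @param x Numeric sample (n >= 4, NAs dropped).
#' @return List with statistic `A2` (corrected) and `p_value`.
#' @export
anderson_darling <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 4L) stopf("Anderson-Darling test needs n >= 4")
  z <- stats::pnorm((x - mean(x)) / stats::sd(x))
  z <- pmin(pmax(z, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(z) + log(1 - rev(z))))
  A2s <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (A2s >= 0.6) {
    exp(1.2937 - 5.709 * A2s + 0.0186 * A2s^2)
  } else if (A2s >= 0.34) {
    exp(0.9177 - 4.279 * A2s - 1.38 * A2s^2)
  } else if (A2s >= 0.2) {
    1 - exp(-8.318 + 42.796 * A2s - 59.938 * A2s^2)
  } else {
    1 - exp(-13.436 + 101.14 * A2s - 223.73 * A2s^2)
  }
  list(A2 = A2s, p_value = min(max(p, 0), 1))
}

has_iqr_outlier <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  any(x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr, na.rm = TRUE)
}

#' Choose the parametric or nonparametric branch
#'
#' Parametric iff every sample passes Anderson-Darling normality at
#' `alpha` AND has no point outside the 1.5 IQR fences. Samples smaller than
#' 4 route nonparametric with a warning.
#'
#' @param ... Numeric samples (or a single list of them).
#' @param alpha Gate level for the normality test.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
gate_test_choice <- function(..., alpha = 0.05) {
  samples <- list(...)
  if (length(samples) == 1L && is.list(samples[[1]]) && !is.numeric(samples[[1]])) {
    samples <- samples[[1]]
  }
  for (x in samples) {
    x <- x[!is.na(x)]
    if (length(x) < 4L) {
      warnf("sample of n = %d too small for the normality gate; routing nonparametric",
            length(x))
      return("nonparametric")
    }
    if (stats::sd(x) == 0) return("nonparametric")
    if (anderson_darling(x)$p_value < alpha) return("nonparametric")
    if (has_iqr_outlier(x)) return("nonparametric")
  }
  "parametric"
}

#' Cohen's d (pooled standard deviation)
#' @param a,b Numeric samples.
#' @param paired Use the sd of the differences for paired data.
#' @export
cohens_d <- function(a, b, paired = FALSE) {
  if (paired) {
    d <- a - b
    return(mean(d) / stats::sd(d))
  }
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  (mean(a) - mean(b)) / sp
}

#' Gated two-sample / paired / k-sample comparison
#'
#' Two samples route to a t-test (two-sample or paired) when the gate passes
#' and to Mann-Whitney U / Wilcoxon signed-rank otherwise; three or more
#' samples run a Kruskal-Wallis test. Rank tests use the exact null for
#' n <= 25 without ties and the normal approximation with continuity
#' correction otherwise. All tests are two-sided. Cohen's d accompanies
#' t-tests.
#'
#' @param a,b Numeric samples; `b` may be NULL if `a` is a list of >= 3
#'   samples.
#' @param paired Paired comparison?
#' @return A `test_result`: test_name, statistic, p_value, effect_size, n,
#'   gating_path.
#' @export
compare_samples <- function(a, b = NULL, paired = FALSE) {
  if (is.list(a) && is.null(b)) {
    if (length(a) < 3L) stopf("k-sample comparison needs >= 3 samples")
    if (stats::sd(unlist(a)) == 0) {   # degenerate: identical everywhere
      return(test_result("kruskal-wallis", 0, 1, NA_real_,
                         sum(lengths(a)), "nonparametric"))
    }
    kw <- stats::kruskal.test(a)
    return(test_result("kruskal-wallis", unname(kw$statistic), kw$p.value,
                       NA_real_, sum(lengths(a)), "nonparametric"))
  }
  if (paired && length(a) != length(b)) stopf("paired samples differ in length")
  path <- if (paired) {
    suppressWarnings(gate_test_choice(list(a - b)))
  } else {
    suppressWarnings(gate_test_choice(list(a, b)))
  }
  if (path == "parametric") {
    tt <- stats::t.test(a, b, paired = paired, var.equal = TRUE)
    return(test_result(if (paired) "paired t" else "2-sample t",
                       unname(tt$statistic), tt$p.value,
                       cohens_d(a, b, paired), length(a) + length(b), path))
  }
  if (paired) {
    d <- a - b
    if (all(d == 0)) {
      return(test_result("wilcoxon signed-rank", 0, 1, NA_real_,
                         length(a), path))
    }
    exact <- sum(d != 0) <= 25 && !any(duplicated(abs(d[d != 0]))) && !any(d == 0)
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = exact,
                                              correct = TRUE))
    return(test_result("wilcoxon signed-rank", unname(wt$statistic), wt$p.value,
                       NA_real_, length(a), path))
  }
  exact <- max(length(a), length(b)) <= 25 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  test_result("mann-whitney U", unname(wt$statistic), wt$p.value, NA_real_,
              length(a) + length(b), path)
}

test_result <- function(name, statistic, p, effect, n, path) {
  structure(list(test_name = name, statistic = statistic,
                 p_value = p, effect_size = effect, n = n,
                 gating_path = path),
            class = "test_result")
}

#' @exportS3Method base::print
print.test_result <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4g, p = %.4g%s, n = %d\n",
              x$test_name, x$gating_path, x$statistic, x$p_value,
              if (!is.na(x$effect_size)) sprintf(", d = %.3g", x$effect_size) else "",
              x$n))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Own implementation of the step-up rule (kept separate from
#' `stats::p.adjust` so tests can check it against the definition).
#' @param p Vector of p-values.
#' @return Adjusted p-values (monotone step-up).
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Running paired t-test across lags with FDR correction
#'
#' Paired t-test at every lag (columns), Benjamini-Hochberg across lags,
#' returning the mask of lags surviving at `alpha`.
#'
#' @param weightsA,weightsB Matrices subject x lag, aligned.
#' @param alpha FDR level.
#' @return Logical mask per lag; attributes `p_raw` and `p_adj`.
#' @export
running_paired_ttest_fdr <- function(weightsA, weightsB, alpha = 0.05) {
  stopifnot(all(dim(weightsA) == dim(weightsB)))
  if (nrow(weightsA) < 2L) stopf("need at least 2 subjects")
  p <- vapply(seq_len(ncol(weightsA)), function(l) {
    d <- weightsA[, l] - weightsB[, l]
    if (stats::sd(d) <= 1e-12 * (abs(mean(d)) + 1)) {
      # constant difference: identically zero -> null; nonzero -> certain
      return(if (abs(mean(d)) <= 1e-12) 1 else 0)
    }
    stats::t.test(d)$p.value
  }, 0)
  padj <- bh_adjust(p)
  structure(padj <= alpha, p_raw = p, p_adj = padj)
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' removal of `covariate`; p-value from the t distribution on n - 3 degrees
#' of freedom.
#'
#' @param x,y Numeric vectors.
#' @param covariate Numeric vector (constant covariate reduces to the plain
#'   correlation, with a warning).
#' @return List with `r`, `p_value`, `n`.
#' @export
partial_correlation <- function(x, y, covariate) {
  n <- length(x)
  stopifnot(length(y) == n, length(covariate) == n)
  if (n < 5L) stopf("partial correlation needs n >= 5")
  if (stats::sd(covariate) == 0) {
    warnf("constant covariate: partial correlation reduces to plain Pearson")
    r <- stats::cor(x, y)
  } else {
    rx <- stats::residuals(stats::lm(x ~ covariate))
    ry <- stats::residuals(stats::lm(y ~ covariate))
    # a variable collinear with the covariate leaves numerical-noise
    # residuals; its partial correlation is 0 by definition
    if (stats::sd(rx) <= 1e-10 * (stats::sd(x) + 1) ||
        stats::sd(ry) <= 1e-10 * (stats::sd(y) + 1)) {
      r <- 0
    } else {
      r <- stats::cor(rx, ry)
    }
  }
  tval <- r * sqrt((n - 3) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 3)
  list(r = r, p_value = p, n = n)
}

#' Group trough-latency contrast
#'
#' Group delay = mean(older latencies) - mean(younger latencies); the
#' significance test routes through the parametric/nonparametric gate.
#'
#' @param metrics Data frame with columns `group` ("younger"/"older") and
#'   `peak_latency_ms`, one row per subject.
#' @return List with `delay_ms` and the `test_result`.
#' @export
latency_contrast <- function(metrics) {
  old <- metrics$peak_latency_ms[metrics$group == "older"]
  yng <- metrics$peak_latency_ms[metrics$group == "younger"]
  if (length(old) == 0L || length(yng) == 0L) stopf("both groups must be populated")
  list(delay_ms = mean(old) - mean(yng),
       test = compare_samples(old, yng))
}
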