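# Multiway canonical correlation analysis for group denoising, in the
# summed-covariance formulation: each subject's data is reduced to n_pc
# whitened principal components, the whitened blocks are concatenated, and
# the eigenvectors of the concatenated covariance define canonical
# components ordered by the variance they share across subjects. Denoising
# projects a subject into canonical space, truncates to the leading n_cc
# components, and projects back to channel space.

#' Fit an MCCA model across subjects
#'
#' @param recordings List, one element per subject: either an
#'   [eeg_recording()] or a list of them (trials are concatenated in time;
#'   all subjects must be time-aligned with equal total length).
#' @param n_pc Principal components kept per subject before the canonical
#'   stage (reduced with a warning if a subject is rank-deficient).
#' @param n_cc Canonical components retained when denoising (clipped to
#'   `n_subjects * n_pc` with a warning).
#' @return An `mcca_model`.
#' @export
mcca_fit <- function(recordings, n_pc = 40L, n_cc = 110L) {
  mats <- lapply(recordings, subject_matrix)    # each: time x channels
  Tn <- unique(vapply(mats, nrow, 0L))
  if (length(Tn) != 1L) stopf("subjects are not time-aligned (lengths %s)",
                              paste(Tn, collapse = ", "))
  S <- length(mats)
  n_pc <- as.integer(n_pc)

  subj <- vector("list", S)
  blocks <- vector("list", S)
  # No internal centering: the transform stays strictly linear (zero in,
  # zero out); callers are expected to feed high-passed / demeaned data.
  for (s in seq_len(S)) {
    X <- mats[[s]]
    sv <- svd(X)
    tol <- max(sv$d) * 1e-10
    r <- sum(sv$d > tol)
    npc_s <- min(n_pc, r, ncol(X))
    if (npc_s < n_pc) {
      warnf("subject %d: rank %d < n_pc = %d; keeping %d components",
            s, r, n_pc, npc_s)
    }
    U <- sv$u[, seq_len(npc_s), drop = FALSE]       # whitened time courses
    # channel -> whitened map and its inverse
    W <- sv$v[, seq_len(npc_s), drop = FALSE] %*%
      diag(1 / sv$d[seq_len(npc_s)], npc_s)
    Winv <- diag(sv$d[seq_len(npc_s)], npc_s) %*%
      t(sv$v[, seq_len(npc_s), drop = FALSE])
    subj[[s]] <- list(W = W, Winv = Winv, n_pc = npc_s)
    blocks[[s]] <- U
  }
  Z <- do.call(cbind, blocks)
  ev <- eigen(crossprod(Z), symmetric = TRUE)
  total <- ncol(Z)
  if (n_cc > total) {
    warnf("n_cc = %d exceeds n_subjects * n_pc = %d; clipping", n_cc, total)
    n_cc <- total
  }
  offs <- c(0L, cumsum(vapply(subj, `[[`, 0L, "n_pc")))
  for (s in seq_len(S)) {
    subj[[s]]$V <- ev$vectors[(offs[s] + 1L):offs[s + 1L], , drop = FALSE]
  }
  structure(list(subjects = subj, eigenvalues = ev$values,
                 n_pc = n_pc, n_cc = as.integer(n_cc), n_subjects = S,
                 n_samples = Tn),
            class = "mcca_model")
}

subject_matrix <- function(x) {
  if (inherits(x, "eeg_recording")) return(t(x$data))
  if (is.list(x)) return(do.call(rbind, lapply(x, function(r) t(r$data))))
  if (is.matrix(x)) return(t(x))   # channels x samples convention
  stopf("cannot interpret subject data of class %s", class(x)[1])
}

#' @exportS3Method base::print
print.mcca_model <- function(x, ...) {
  cat(sprintf("<mcca_model> %d subjects, n_pc = %d, n_cc = %d (of %d)\n",
              x$n_subjects, x$n_pc, x$n_cc,
              length(x$eigenvalues)))
  invisible(x)
}

#' Canonical-component time courses
#'
#' @param model An `mcca_model`.
#' @param recordings The cohort the model was fitted on.
#' @param k Which components (default all retained).
#' @return Matrix time x components: summed whitened subject projections.
#' @export
mcca_components <- function(model, recordings, k = seq_len(model$n_cc)) {
  acc <- 0
  for (s in seq_len(model$n_subjects)) {
    su <- model$subjects[[s]]
    X <- subject_matrix(recordings[[s]])
    acc <- acc + (X %*% su$W) %*% su$V[, k, drop = FALSE]
  }
  acc
}

#' Denoise one subject by truncated canonical back-projection
#'
#' @param rec The subject's [eeg_recording()] (or trial list / matrix).
#' @param model An `mcca_model` fitted on a cohort containing this subject.
#' @param subject Index of the subject within the fitted cohort.
#' @param n_cc Number of canonical components retained (default from model).
#' @return Object of the same shape as `rec` with denoised data.
#' @export
mcca_denoise <- function(rec, model, subject, n_cc = model$n_cc) {
  if (subject < 1L || subject > model$n_subjects) {
    stopf("subject %d not in the fitted cohort (n = %d)", subject,
          model$n_subjects)
  }
  su <- model$subjects[[subject]]
  X <- subject_matrix(rec)
  Vt <- su$V[, seq_len(n_cc), drop = FALSE]
  Z <- X %*% su$W                  # whitened
  Zhat <- (Z %*% Vt) %*% pinv(Vt)  # truncated canonical round trip
  Xhat <- Zhat %*% su$Winv

  if (inherits(rec, "eeg_recording")) {
    out <- rec
    out$data <- t(Xhat)
    rownames(out$data) <- rec$channel_labels
    return(out)
  }
  if (is.list(rec)) {
    lens <- vapply(rec, function(r) ncol(r$data), 0L)
    splits <- rep(seq_along(rec), lens)
    return(lapply(seq_along(rec), function(i) {
      out <- rec[[i]]
      out$data <- t(Xhat[splits == i, , drop = FALSE])
      rownames(out$data) <- out$channel_labels
      out
    }))
  }
  t(Xhat)
}
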