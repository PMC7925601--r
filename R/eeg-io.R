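# EEG container and plain-text serialization. Recordings travel as a
# channels x samples matrix plus sampling rate and channel metadata; on disk
# each trial is a TSV matrix with a JSON sidecar (fs, labels, roles).

#' Construct an EEG recording
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one per channel.
#' @param channel_roles "scalp" or "mastoid", one per channel.
#' @param bad_mask Logical per-channel flag (defaults to all clean).
#' @param subject_id,trial_id Optional identifiers.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL, channel_roles = NULL,
                          bad_mask = NULL, subject_id = NA_character_,
                          trial_id = NA_integer_) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stopf("EEG data must be finite")
  if (fs <= 0) stopf("sampling rate must be positive")
  n_ch <- nrow(data)
  if (is.null(channel_labels)) channel_labels <- sprintf("E%03d", seq_len(n_ch))
  if (is.null(channel_roles)) channel_roles <- rep("scalp", n_ch)
  if (is.null(bad_mask)) bad_mask <- rep(FALSE, n_ch)
  stopifnot(length(channel_labels) == n_ch, length(channel_roles) == n_ch,
            length(bad_mask) == n_ch)
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 channel_roles = channel_roles, bad_mask = bad_mask,
                 subject_id = subject_id, trial_id = trial_id),
            class = "eeg_recording")
}

#' @exportS3Method base::print
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%d mastoid, %d bad)\n",
              nrow(x$data), ncol(x$data), x$fs,
              sum(x$channel_roles == "mastoid"), sum(x$bad_mask)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Write / read recordings as a plain-text directory container
#'
#' One `trial_<k>.tsv` per recording (channels x samples, no headers) plus a
#' `meta.json` holding fs, channel labels/roles and identifiers.
#'
#' @param recordings A list of [eeg_recording()] (one subject's trials).
#' @param dir Directory (created if needed).
#' @export
write_eeg_dir <- function(recordings, dir) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r1 <- recordings[[1]]
  meta <- list(fs = r1$fs, channel_labels = r1$channel_labels,
               channel_roles = r1$channel_roles,
               subject_id = r1$subject_id,
               trial_ids = vapply(recordings, function(r) as.integer(r$trial_id), 0L),
               n_trials = length(recordings))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  for (k in seq_along(recordings)) {
    utils::write.table(recordings[[k]]$data,
                       file.path(dir, sprintf("trial_%02d.tsv", k)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_eeg_dir
#' @export
read_eeg_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  lapply(seq_len(meta$n_trials), function(k) {
    m <- as.matrix(utils::read.table(
      file.path(dir, sprintf("trial_%02d.tsv", k)), sep = "\t"))
    dimnames(m) <- NULL
    eeg_recording(m, fs = meta$fs, channel_labels = meta$channel_labels,
                  channel_roles = meta$channel_roles,
                  subject_id = meta$subject_id %||% NA_character_,
                  trial_id = meta$trial_ids[k])
  })
}
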