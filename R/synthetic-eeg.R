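# Forward model: known word-level response kernels convolved with feature
# impulse trains, mixed over a synthetic sensor layout, plus structured noise.
# The generating kernels are retained so estimation can be scored against
# ground truth.

#' Synthetic sensor layout on the unit sphere
#'
#' Scalp sensors are placed on an upper-hemisphere Fibonacci spiral; two
#' mastoid sensors sit low and lateral. Coordinates are unit-normalized, as
#' required by spherical-spline interpolation.
#'
#' @param n_scalp Number of scalp channels.
#' @param mastoids Include two mastoid channels (roles "mastoid").
#' @return A `channel_layout` data.frame: label, role, x, y, z.
#' @export
channel_layout <- function(n_scalp = 32L, mastoids = TRUE) {
  n_scalp <- as.integer(n_scalp)
  i <- seq_len(n_scalp)
  golden <- pi * (3 - sqrt(5))
  z <- (i - 0.5) / n_scalp        # upper hemisphere
  r <- sqrt(1 - z^2)
  th <- golden * i
  pos <- cbind(x = r * cos(th), y = r * sin(th), z = z)
  lab <- sprintf("E%03d", i)
  role <- rep("scalp", n_scalp)
  if (mastoids) {
    m <- rbind(c(0.83, -0.37, -0.42), c(-0.83, -0.37, -0.42))
    m <- m / sqrt(rowSums(m^2))
    pos <- rbind(pos, m)
    lab <- c(lab, "M1", "M2")
    role <- c(role, "mastoid", "mastoid")
  }
  structure(data.frame(label = lab, role = role, pos, stringsAsFactors = FALSE),
            class = c("channel_layout", "data.frame"))
}

#' Smooth centro-parietal topography over a layout
#'
#' Gaussian gain profile centred over a posterior-midline site, mimicking the
#' scalp distribution of late semantic responses; mastoids get zero gain.
#' @param layout A [channel_layout()].
#' @param centre Unit 3-vector of the gain peak.
#' @param width Angular width of the profile.
#' @return Per-channel gain vector in [0, 1].
#' @export
parietal_topography <- function(layout, centre = c(0, -0.45, 0.893), width = 0.8) {
  centre <- centre / sqrt(sum(centre^2))
  d2 <- (layout$x - centre[1])^2 + (layout$y - centre[2])^2 + (layout$z - centre[3])^2
  g <- exp(-d2 / (2 * width^2))
  g[layout$role != "scalp"] <- 0
  g / max(g)
}

#' Specify a word-response kernel
#'
#' A Gaussian trough (negative amplitude for N400-like responses) at a given
#' post-onset latency, distributed over channels by a topography vector.
#'
#' @param feature_name Which feature impulse train this kernel answers to.
#' @param trough_latency_ms Latency of the extremum after word onset.
#' @param trough_width_ms Full width at half maximum of the Gaussian.
#' @param amplitude Peak amplitude (negative for a trough).
#' @param topography Per-channel gain vector.
#' @param support_ms Kernel support `[0, support_ms]`.
#' @export
kernel_spec <- function(feature_name, trough_latency_ms = 400,
                        trough_width_ms = 120, amplitude = -1,
                        topography, support_ms = 800) {
  if (trough_latency_ms < 0 || trough_latency_ms > support_ms) {
    stopf("kernel trough latency %.0f ms outside support [0, %.0f]",
          trough_latency_ms, support_ms)
  }
  structure(list(feature_name = feature_name,
                 trough_latency_ms = trough_latency_ms,
                 trough_width_ms = trough_width_ms,
                 amplitude = amplitude, topography = topography,
                 support_ms = support_ms),
            class = "kernel_spec")
}

#' Sample a kernel's temporal shape on a given rate grid
#'
#' @param kernel A [kernel_spec()].
#' @param fs Sampling rate (Hz).
#' @return Numeric vector over lags `0 .. support_ms` at `fs`.
#' @export
eval_kernel <- function(kernel, fs) {
  t_ms <- seq(0, kernel$support_ms, by = 1000 / fs)
  sig <- kernel$trough_width_ms / (2 * sqrt(2 * log(2)))
  kernel$amplitude * exp(-(t_ms - kernel$trough_latency_ms)^2 / (2 * sig^2))
}

# 1/f amplitude-shaped noise, unit sd per column, via spectral shaping of
# white noise (all channels in one multivariate FFT)
pink_noise_mat <- function(n, ncols, fs) {
  if (n < 4) return(matrix(stats::rnorm(n * ncols), n, ncols))
  W <- stats::mvfft(matrix(stats::rnorm(n * ncols), n, ncols))
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  fold <- f > fs / 2
  f[fold] <- fs - f[fold]
  a <- 1 / sqrt(pmax(f, fs / n))
  a[1] <- 0                              # no DC
  x <- Re(stats::mvfft(W * a, inverse = TRUE)) / n
  sweep(x, 2, apply(x, 2, stats::sd), `/`)
}

pink_noise <- function(n, fs) pink_noise_mat(n, 1L, fs)[, 1]

conv_full <- function(x, k) {
  # linear convolution via FFT, length n + m - 1
  n <- length(x); m <- length(k)
  N <- stats::nextn(n + m - 1L, 2)
  out <- Re(stats::fft(stats::fft(c(x, numeric(N - n))) *
                       stats::fft(c(k, numeric(N - m))), inverse = TRUE)) / N
  out[seq_len(n + m - 1L)]
}

#' Forward-simulate one subject's EEG for a trial
#'
#' The clean response is the sum over features of the feature's onset impulse
#' train convolved with its kernel, spread over channels by the kernel
#' topography. Noise adds spectrally pink and white sensor components, plus an
#' optional rank-1 artifact shared across subjects (supplied, or generated
#' here and returned, so a cohort can inject the identical component into
#' every subject).
#'
#' @param tokens `word_tokens` for the trial.
#' @param feature_values Named list: per feature, numeric values aligned to the
#'   scored content tokens (names give token indices via `attr(.,"token_index")`
#'   or positional alignment to content tokens).
#' @param kernels List of [kernel_spec()], one per feature (names must match).
#' @param noise List: white_sd, pink_sd, shared_artifact_sd.
#' @param fs Sampling rate (Hz).
#' @param n_channels Number of scalp channels (kernel topographies must match
#'   total channel count including mastoids if a layout is given).
#' @param layout Optional [channel_layout()]; defaults to
#'   `channel_layout(n_channels)`.
#' @param duration_s Trial length; defaults to last offset plus kernel support.
#' @param shared_artifact Optional numeric vector (samples) to use as the
#'   shared temporal component; generated when NULL and sd > 0.
#' @param seed Integer seed.
#' @return An [eeg_recording()] with attribute `clean` (noiseless channels x
#'   samples matrix) and `shared_artifact` (the temporal component used).
#' @export
simulate_subject_eeg <- function(tokens, feature_values, kernels,
                                 noise = list(white_sd = 0, pink_sd = 0,
                                              shared_artifact_sd = 0),
                                 fs = 128, n_channels = 32L, layout = NULL,
                                 duration_s = NULL, shared_artifact = NULL,
                                 seed = 1L) {
  if (is.null(layout)) layout <- channel_layout(n_channels, mastoids = TRUE)
  n_ch <- nrow(layout)
  if (is.null(duration_s)) {
    duration_s <- max(tokens$offset_s) + max(vapply(kernels, `[[`, 0, "support_ms")) / 1000
  }
  n_samp <- as.integer(round(duration_s * fs))

  clean <- matrix(0, n_ch, n_samp)
  for (f in names(kernels)) {
    k <- kernels[[f]]
    if (length(k$topography) != n_ch) {
      stopf("kernel '%s' topography has %d gains for %d channels",
            f, length(k$topography), n_ch)
    }
    vals <- feature_values[[f]]
    if (is.null(vals)) stopf("no feature values supplied for kernel '%s'", f)
    imp <- build_impulse_series(attr(vals, "tokens") %||% tokens[tokens$is_content, ],
                                as.numeric(vals), fs, n_samp, name = f)
    resp <- conv_full(imp$values, eval_kernel(k, fs))[seq_len(n_samp)]
    clean <- clean + outer(k$topography, resp)
  }

  with_seed(seed, {
    noisy <- clean
    if ((noise$shared_artifact_sd %||% 0) > 0) {
      if (is.null(shared_artifact)) {
        shared_artifact <- pink_noise(n_samp, fs)
      }
      mix <- stats::rnorm(n_ch)           # subject-specific artifact topography
      mix <- mix / sqrt(mean(mix^2))
      noisy <- noisy + noise$shared_artifact_sd * outer(mix, shared_artifact)
    }
    if ((noise$pink_sd %||% 0) > 0) {
      noisy <- noisy + noise$pink_sd * t(pink_noise_mat(n_samp, n_ch, fs))
    }
    if ((noise$white_sd %||% 0) > 0) {
      noisy <- noisy + noise$white_sd * stats::rnorm(length(noisy))
    }
    rec <- eeg_recording(noisy, fs = fs, channel_labels = layout$label,
                         channel_roles = layout$role)
    attr(rec, "clean") <- clean
    attr(rec, "shared_artifact") <- shared_artifact
    rec
  })
}

#' Specify a simulated two-group cohort
#'
#' Group-level manipulations follow the study design this simulator emulates:
#' an older group whose response kernels are delayed and whose semantic
#' dissimilarity response is attenuated relative to a younger group, with a
#' verbal-fluency covariate linked to each older subject's dissimilarity gain.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param group_params Named list (`younger`, `older`) of lists with
#'   latency_shift_ms, dissimilarity_gain, surprisal_gain, age_range.
#' @param gain_sd Between-subject sd of the per-subject feature gains.
#' @param latency_jitter_ms Between-subject sd of kernel latency (ms).
#' @param fluency_link List: intercept, slope, noise_sd mapping a subject's
#'   dissimilarity gain to a semantic-fluency score.
#' @param noise List: white_sd, pink_sd, shared_artifact_sd (per-channel sds
#'   relative to the unit-variance reference response).
#' @param n_trials Trials per subject.
#' @param trial_duration_s Seconds per trial.
#' @param fs Sampling rate.
#' @param n_channels Scalp channel count.
#' @param seed Master seed.
#' @export
cohort_spec <- function(n_per_group = 8L,
                        group_params = list(
                          younger = list(latency_shift_ms = 0,
                                         dissimilarity_gain = 1,
                                         surprisal_gain = 1,
                                         age_range = c(19, 38)),
                          older = list(latency_shift_ms = 74,
                                       dissimilarity_gain = 1,
                                       surprisal_gain = 1,
                                       age_range = c(55, 77))),
                        gain_sd = 0.3, latency_jitter_ms = 20,
                        fluency_link = list(intercept = 20, slope = 10,
                                            noise_sd = 3.5),
                        noise = list(white_sd = 1, pink_sd = 1,
                                     shared_artifact_sd = 0.5),
                        n_trials = 4L, trial_duration_s = 60, fs = 128,
                        n_channels = 32L, seed = 1L) {
  if (n_per_group < 2L) stopf("invalid cohort spec: n_per_group must be >= 2")
  if (fs <= 0) stopf("invalid cohort spec: fs must be positive")
  if (any(unlist(noise) < 0)) stopf("invalid cohort spec: noise sds must be >= 0")
  structure(list(n_per_group = as.integer(n_per_group),
                 group_params = group_params, gain_sd = gain_sd,
                 latency_jitter_ms = latency_jitter_ms,
                 fluency_link = fluency_link, noise = noise,
                 n_trials = as.integer(n_trials),
                 trial_duration_s = trial_duration_s,
                 fs = fs, n_channels = as.integer(n_channels),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Forward-simulate a two-group cohort
#'
#' Older-group kernels are the younger-group base kernels shifted by
#' `latency_shift_ms` and scaled by the group gains; each subject additionally
#' gets seeded gain and latency jitter. Per-subject semantic fluency is
#' `intercept + slope * dissimilarity_gain + noise`. Noise sds are interpreted
#' relative to the variance of the reference (gain-1) clean response, so a
#' spec can be calibrated to a target SNR with [noise_for_snr()].
#'
#' @param spec A [cohort_spec()].
#' @param trial_tokens List (length n_trials) of `word_tokens`.
#' @param trial_features List (length n_trials) of named lists of per-word
#'   feature values (as passed to [simulate_subject_eeg()]); must contain
#'   `dissimilarity` and `surprisal`.
#' @param base_kernels Optional named list of [kernel_spec()] for the younger
#'   group; defaults place the surprisal trough at 380 ms and the
#'   dissimilarity trough at 400 ms over a centro-parietal topography.
#' @return List with `subjects` (per-subject list: id, group, age, fluency
#'   scores, recordings) and `ground_truth` (`simulation_ground_truth`).
#' @export
generate_cohort <- function(spec, trial_tokens, trial_features,
                            base_kernels = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  layout <- channel_layout(spec$n_channels, mastoids = TRUE)
  topo <- parietal_topography(layout)
  if (is.null(base_kernels)) {
    # an acoustic onset response (equal across groups, untouched by the
    # manipulations) plus the two N400-like semantic kernels; the analysis
    # side carries an onset nuisance regressor for exactly this component
    onset_topo <- parietal_topography(layout, centre = c(0, 0.2, 0.98),
                                      width = 0.9)
    base_kernels <- list(
      onset = kernel_spec("onset", trough_latency_ms = 110,
                          trough_width_ms = 90, amplitude = -1.5,
                          topography = onset_topo),
      surprisal = kernel_spec("surprisal", trough_latency_ms = 380,
                              trough_width_ms = 120, amplitude = -1,
                              topography = topo),
      dissimilarity = kernel_spec("dissimilarity", trough_latency_ms = 400,
                                  trough_width_ms = 120, amplitude = -1,
                                  topography = topo))
  }
  gains_for <- function(kname, gp) {
    switch(kname, dissimilarity = gp$dissimilarity_gain,
           surprisal = gp$surprisal_gain, 1)
  }
  shift_for <- function(kname, gp) {
    # acoustic onset processing is not delayed by the group manipulation
    if (kname == "onset") 0 else gp$latency_shift_ms
  }
  for (g in names(spec$group_params)) {
    gp <- spec$group_params[[g]]
    for (k in base_kernels) {
      lat <- k$trough_latency_ms + shift_for(k$feature_name, gp)
      if (lat < 0 || lat > k$support_ms) {
        stopf("latency shift %.0f ms pushes '%s' trough to %.0f ms, outside [0, %.0f]",
              gp$latency_shift_ms, k$feature_name, lat, k$support_ms)
      }
    }
  }
  # synthesize the constant-height onset feature the analysis regressor
  # mirrors (mean of the pooled semantic values per trial)
  trial_features <- lapply(trial_features, function(fv) {
    if (!("onset" %in% names(fv)) && "onset" %in% names(base_kernels)) {
      d <- as.numeric(fv$dissimilarity); s <- as.numeric(fv$surprisal)
      ok <- !is.na(d) & !is.na(s)
      h <- mean(c(d[ok], s[ok]))
      v <- ifelse(ok, h, NA_real_)
      attr(v, "tokens") <- attr(fv$dissimilarity, "tokens")
      fv$onset <- v
    }
    fv
  })

  # calibrate: variance of the gain-1 clean response at scalp channels
  ref_var <- reference_signal_variance(trial_tokens, trial_features,
                                       base_kernels, spec$fs, layout)

  subjects <- list()
  gt_rows <- list()
  shared <- vector("list", spec$n_trials)
  sid <- 0L
  for (g in names(spec$group_params)) {
    gp <- spec$group_params[[g]]
    for (i in seq_len(spec$n_per_group)) {
      sid <- sid + 1L
      sseed <- mix_seed(spec$seed, sid, 101L)
      draws <- with_seed(sseed, {
        list(age = stats::runif(1, gp$age_range[1], gp$age_range[2]),
             gain = stats::rnorm(length(base_kernels), 1, spec$gain_sd),
             lat = stats::rnorm(1, 0, spec$latency_jitter_ms),
             flu_noise = stats::rnorm(1, 0, spec$fluency_link$noise_sd),
             letter_flu = stats::rnorm(1, 15, 3))
      })
      kernels <- base_kernels
      subj_gain <- numeric(0)
      for (ki in seq_along(kernels)) {
        k <- kernels[[ki]]
        gk <- max(0, gains_for(k$feature_name, gp) * draws$gain[ki])
        subj_gain[k$feature_name] <- gk
        k$amplitude <- k$amplitude * gk
        jit <- if (k$feature_name == "onset") 0 else draws$lat
        k$trough_latency_ms <- min(k$support_ms, max(
          0, k$trough_latency_ms + shift_for(k$feature_name, gp) + jit))
        kernels[[ki]] <- k
      }
      diss_gain <- if ("dissimilarity" %in% names(subj_gain)) {
        subj_gain[["dissimilarity"]]
      } else 1
      fluency <- spec$fluency_link$intercept +
        spec$fluency_link$slope * diss_gain + draws$flu_noise

      recs <- vector("list", spec$n_trials)
      for (tr in seq_len(spec$n_trials)) {
        sim <- simulate_subject_eeg(
          trial_tokens[[tr]], trial_features[[tr]], kernels,
          noise = lapply(spec$noise, function(s) s * sqrt(ref_var)),
          fs = spec$fs, layout = layout,
          duration_s = spec$trial_duration_s,
          shared_artifact = shared[[tr]],
          seed = mix_seed(sseed, tr))
        if (is.null(shared[[tr]]) && !is.null(attr(sim, "shared_artifact"))) {
          shared[[tr]] <- attr(sim, "shared_artifact")
        }
        sim$subject_id <- sprintf("S%02d", sid)
        sim$trial_id <- tr
        recs[[tr]] <- sim
      }
      subjects[[sid]] <- list(id = sprintf("S%02d", sid), group = g,
                              age = draws$age,
                              fluency_semantic = fluency,
                              fluency_letter = draws$letter_flu,
                              kernels = kernels, recordings = recs)
      gt_rows[[sid]] <- data.frame(
        subject_id = sprintf("S%02d", sid), group = g, age = draws$age,
        dissimilarity_gain = diss_gain,
        surprisal_gain = if ("surprisal" %in% names(subj_gain))
          subj_gain[["surprisal"]] else 1,
        latency_ms = (kernels[["surprisal"]] %||% kernels[[1]])$trough_latency_ms,
        fluency_semantic = fluency, seed = sseed,
        stringsAsFactors = FALSE)
    }
  }
  ground_truth <- structure(
    list(table = do.call(rbind, gt_rows), base_kernels = base_kernels,
         layout = layout, topography = topo, ref_var = ref_var, spec = spec),
    class = "simulation_ground_truth")
  list(subjects = subjects, ground_truth = ground_truth)
}

# variance of the clean gain-1 response over scalp channels, averaged over trials
reference_signal_variance <- function(trial_tokens, trial_features, kernels,
                                      fs, layout) {
  v <- 0
  scalp <- layout$role == "scalp"
  for (tr in seq_along(trial_tokens)) {
    n_samp <- NULL
    acc <- NULL
    for (f in names(kernels)) {
      k <- kernels[[f]]
      vals <- trial_features[[tr]][[f]]
      dur <- max(trial_tokens[[tr]]$offset_s) + k$support_ms / 1000
      if (is.null(n_samp)) {
        n_samp <- as.integer(round(dur * fs))
        acc <- matrix(0, sum(scalp), n_samp)
      }
      imp <- build_impulse_series(attr(vals, "tokens") %||%
                                    trial_tokens[[tr]][trial_tokens[[tr]]$is_content, ],
                                  as.numeric(vals), fs, n_samp, name = f)
      resp <- conv_full(imp$values, eval_kernel(k, fs))[seq_len(n_samp)]
      acc <- acc + outer(k$topography[scalp], resp)
    }
    v <- v + stats::var(as.numeric(acc))
  }
  v / length(trial_tokens)
}

#' Noise spec for a target signal-to-noise ratio
#'
#' Returns per-component sds (relative to unit signal variance, the convention
#' [generate_cohort()] uses) whose total variance is `1 / snr`, split by
#' `mix` proportions.
#' @param snr Signal variance / total noise variance.
#' @param mix Proportions for (pink, white, shared) components.
#' @export
noise_for_snr <- function(snr, mix = c(pink = 0.45, white = 0.45, shared = 0.10)) {
  tot <- 1 / snr
  list(pink_sd = sqrt(tot * mix[["pink"]]),
       white_sd = sqrt(tot * mix[["white"]]),
       shared_artifact_sd = sqrt(tot * mix[["shared"]]))
}
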