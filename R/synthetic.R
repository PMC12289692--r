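# Synthetic motor-imagery EEG: cue-locked mu-band (8-12 Hz) oscillations with
# class-lateralized event-related desynchronization (ERD) on top of 1/f
# background noise, plus occasional sub-4-Hz blink transients.

#' Configuration for the synthetic motor-imagery EEG generator
#'
#' The generator emulates cue-locked binary motor imagery: during each trial a
#' mu-band oscillation (subject-specific peak in 9-11 Hz) is added to every
#' channel, and its power on the channel group contralateral to the imagined
#' hand is attenuated by `erd_factor` relative to the ipsilateral group. By
#' convention the first half of the channel list is the "left hemisphere"
#' group (contralateral to right-hand imagery, label +1) and the second half
#' the "right hemisphere" group (contralateral to left-hand imagery, label
#' -1). The background is 1/f^`noise_exponent` noise; blinks are half-cosine
#' bumps of 0.4 s at 10x the background SD, arriving at Poisson times.
#'
#' @param n_subjects number of subjects.
#' @param n_trials_per_subject trials per subject (labels balanced to within
#'   one trial).
#' @param n_channels number of EEG channels (even counts split cleanly into
#'   the two lateral groups).
#' @param fs sampling rate in Hz; must be at least twice the upper mu band
#'   edge (>= 24 Hz).
#' @param trial_len trial length in seconds following the imagery cue.
#' @param erd_factor multiplicative mu-power attenuation on the contralateral
#'   group, in (0, 1]; 1 means no class information.
#' @param noise_exponent slope of the 1/f background spectrum.
#' @param blink_rate blink events per minute.
#' @param mu_rms RMS amplitude (microvolts) of the mu oscillation on the
#'   unattenuated side.
#' @param noise_sd standard deviation (microvolts) of the background noise.
#' @param iti inter-trial interval in seconds between the end of one trial
#'   window and the next cue.
#' @param seed integer master seed; all randomness derives from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 8L, n_trials_per_subject = 200L,
                         n_channels = 8L, fs = 90, trial_len = 4,
                         erd_factor = 0.5, noise_exponent = 1,
                         blink_rate = 2, mu_rms = 4, noise_sd = 2,
                         iti = 2, seed = 1L) {
  if (n_subjects < 1L || n_trials_per_subject < 1L || n_channels < 2L)
    stop("counts must be positive (and n_channels >= 2)")
  if (fs < 24) stop("fs must be at least 24 Hz (twice the upper mu band edge)")
  if (trial_len <= 0) stop("trial_len must be positive")
  if (erd_factor <= 0 || erd_factor > 1) stop("erd_factor must be in (0, 1]")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_subject = as.integer(n_trials_per_subject),
                 n_channels = as.integer(n_channels), fs = fs,
                 trial_len = trial_len, erd_factor = erd_factor,
                 noise_exponent = noise_exponent, blink_rate = blink_rate,
                 mu_rms = mu_rms, noise_sd = noise_sd, iti = iti,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Channel groups used for lateralized mu modulation
#'
#' First half of the channels = left hemisphere, second half = right.
#' @param n_channels channel count.
#' @return list with integer index vectors `left` and `right`.
#' @export
lateral_groups <- function(n_channels) {
  h <- n_channels %/% 2L
  list(left = seq_len(h), right = seq.int(h + 1L, n_channels))
}

# 1/f^a noise of length n via spectral shaping of white Gaussian noise,
# normalized to unit SD. Uses the current RNG stream.
pink_noise <- function(n, exponent) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w)
  W <- stats::fft(w)
  f <- seq_len(n) - 1L
  f <- pmin(f, n - f)                 # two-sided frequency index
  shape <- c(0, (f[-1L] / f[2L])^(-exponent / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

run_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

subject_seed <- function(cfg, subject_id) {
  # deterministic per (master seed, subject); kept < 2^31
  (as.double(cfg$seed) * 1000003 + as.double(subject_id) * 7919) %% 2147483629 + 1
}

#' Generate one subject's continuous recording
#'
#' Produces a continuous multichannel signal with cue events. Deterministic
#' given `cfg$seed` and `subject_id` (bit-identical on repeated calls); the
#' caller's RNG state is left untouched.
#'
#' @param cfg a [synth_config()].
#' @param subject_id subject index (1-based).
#' @return A `raw_recording`: list with `data` (channels x samples matrix,
#'   microvolts), `fs`, `channel_names`, `events` (data.frame with
#'   `onset` sample index, 1-based, and `label` in \{-1, +1\}) and
#'   `subject_id`.
#' @export
generate_recording <- function(cfg, subject_id) {
  stopifnot(inherits(cfg, "synth_config"))
  if (subject_id < 1L) stop("subject_id must be a positive index")
  run_seeded(subject_seed(cfg, subject_id), {
    fs <- cfg$fs
    n_tr <- cfg$n_trials_per_subject
    len_tr <- round(cfg$trial_len * fs)
    len_iti <- round(cfg$iti * fs)
    pad <- round(2 * fs)
    n_samp <- pad + n_tr * (len_tr + len_iti) + pad
    nc <- cfg$n_channels

    # between-subject variability: overall gain, mu peak frequency/amplitude
    gain <- exp(stats::rnorm(1, 0, 0.15))
    mu_f <- stats::runif(1, 9, 11)
    mu_amp <- sqrt(2) * cfg$mu_rms * exp(stats::rnorm(1, 0, 0.1))
    ch_gain <- exp(stats::rnorm(nc, 0, 0.05))

    data <- matrix(0, nc, n_samp)
    for (ch in seq_len(nc))
      data[ch, ] <- cfg$noise_sd * pink_noise(n_samp, cfg$noise_exponent)

    # balanced, shuffled labels
    labels <- rep(c(-1, 1), length.out = n_tr)[sample.int(n_tr)]
    onsets <- pad + (seq_len(n_tr) - 1L) * (len_tr + len_iti) + 1L

    grp <- lateral_groups(nc)
    tt <- (seq_len(len_tr) - 1) / fs
    ramp <- 0.25
    env <- pmin(1, pmin(tt, rev(tt)) / ramp)    # raised edges, 0.25 s ramps
    for (i in seq_len(n_tr)) {
      contra <- if (labels[i] > 0) grp$left else grp$right
      amp <- rep(mu_amp, nc)
      amp[contra] <- amp[contra] * sqrt(cfg$erd_factor)
      idx <- onsets[i]:(onsets[i] + len_tr - 1L)
      for (ch in seq_len(nc)) {
        phase <- stats::runif(1, 0, 2 * pi)
        data[ch, idx] <- data[ch, idx] + amp[ch] * env * sin(2 * pi * mu_f * tt + phase)
      }
    }

    # blink transients: half-cosine bump, 0.4 s, 10x background SD, < 4 Hz
    if (cfg$blink_rate > 0) {
      n_blinks <- stats::rpois(1, cfg$blink_rate * n_samp / fs / 60)
      if (n_blinks > 0) {
        blen <- round(0.4 * fs)
        bump <- 10 * cfg$noise_sd * sin(pi * (seq_len(blen) - 0.5) / blen)
        at <- sort(sample.int(n_samp - blen, n_blinks))
        for (b in at) {
          idx <- b:(b + blen - 1L)
          data[, idx] <- data[, idx] + matrix(bump, nc, blen, byrow = TRUE)
        }
      }
    }

    data <- data * gain * ch_gain
    structure(list(data = data, fs = fs,
                   channel_names = sprintf("CH%02d", seq_len(nc)),
                   events = data.frame(onset = onsets, label = labels),
                   subject_id = as.integer(subject_id)),
              class = "raw_recording")
  })
}

#' Generate a multi-subject dataset
#'
#' One recording per subject with subject-specific gains and mu parameters so
#' that leave-one-subject-out generalization is non-trivial; labels are
#' balanced within each subject.
#'
#' @param cfg a [synth_config()].
#' @return list of `raw_recording`, length `cfg$n_subjects`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  lapply(seq_len(cfg$n_subjects), function(s) generate_recording(cfg, s))
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %d: %d channels x %d samples @ %g Hz, %d events\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}

#' Band power per channel group during trials
#'
#' Diagnostic used to verify the planted ERD effect: band-pass the recording
#' in `band` and average the within-trial variance over channels of each
#' lateral group, separately per class.
#'
#' @param rec a `raw_recording`.
#' @param band numeric length-2, passband in Hz (default mu band 8-12).
#' @param trial_len trial window in seconds.
#' @return data.frame with one row per class: `label`, `contra`, `ipsi`,
#'   `ratio` (contralateral / ipsilateral mean band power).
#' @export
mu_power_ratio <- function(rec, band = c(8, 12), trial_len = 4) {
  bf <- signal::butter(4, band / (rec$fs / 2), type = "pass")
  filt <- t(apply(rec$data, 1L, function(ch) signal::filtfilt(bf, ch)))
  len <- round(trial_len * rec$fs)
  grp <- lateral_groups(nrow(rec$data))
  out <- lapply(c(-1, 1), function(lb) {
    ev <- rec$events[rec$events$label == lb, , drop = FALSE]
    pw <- sapply(seq_len(nrow(ev)), function(i) {
      idx <- ev$onset[i]:(ev$onset[i] + len - 1L)
      c(left = mean(apply(filt[grp$left, idx, drop = FALSE], 1L, stats::var)),
        right = mean(apply(filt[grp$right, idx, drop = FALSE], 1L, stats::var)))
    })
    m <- rowMeans(pw)
    contra <- if (lb > 0) m[["left"]] else m[["right"]]
    ipsi <- if (lb > 0) m[["right"]] else m[["left"]]
    data.frame(label = lb, contra = contra, ipsi = ipsi, ratio = contra / ipsi)
  })
  do.call(rbind, out)
}
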