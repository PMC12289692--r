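# Preprocessing: 4-Hz high-pass Butterworth filtering, 4-s cue-locked
# epoching, and statistical trial/channel rejection by the
# mean-absolute-value (MAV) rule: drop units whose MAV exceeds
# mean + 3*sd across units. No low-pass filtering is applied.

#' High-pass filter specification
#'
#' Fourth-order Butterworth high-pass at 4 Hz by default, the minimal
#' preprocessing used throughout the pipeline to suppress ocular artifacts
#' (dominant below 4 Hz) while leaving the rest of the spectrum intact.
#'
#' @param order filter order (>= 1).
#' @param cutoff cutoff frequency in Hz.
#' @param zero_phase if `TRUE` (default) apply forward-backward filtering
#'   (zero phase, magnitude response squared); if `FALSE` a single causal
#'   pass, whose gain matches the closed-form Butterworth magnitude
#'   `|H(f)| = (f/fc)^n / sqrt(1 + (f/fc)^(2n))`.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(order = 4L, cutoff = 4, zero_phase = TRUE) {
  if (order < 1L) stop("order must be >= 1")
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(order = as.integer(order), cutoff = cutoff,
                 kind = "highpass", design = "butterworth",
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Apply the high-pass filter to a recording
#'
#' Per-channel Butterworth IIR filtering; zero-phase (filtfilt) by default.
#' The DC component is in the stopband and is removed up to the filter's
#' edge transient.
#'
#' @param rec a `raw_recording`.
#' @param spec a [filter_spec()].
#' @return the filtered `raw_recording` (same shape, events untouched).
#' @export
highpass_filter <- function(rec, spec = filter_spec()) {
  if (spec$cutoff >= rec$fs / 2)
    stop("cutoff must be below the Nyquist frequency")
  if (anyNA(rec$data) || any(!is.finite(rec$data)))
    stop("recording contains NaN/Inf samples")
  bf <- signal::butter(spec$order, spec$cutoff / (rec$fs / 2), type = "high")
  app <- if (spec$zero_phase) {
    function(ch) signal::filtfilt(bf, ch)
  } else {
    function(ch) as.numeric(signal::filter(bf, ch))
  }
  out <- rec
  out$data <- t(apply(rec$data, 1L, app))
  out
}

new_epoch_set <- function(data, labels, fs, subject_id = NA_integer_,
                          kept_trial_idx = seq_len(dim(data)[1L]),
                          channel_names = NULL) {
  stopifnot(length(labels) == dim(data)[1L])
  structure(list(data = data, labels = as.numeric(labels), fs = fs,
                 subject_id = subject_id,
                 kept_trial_idx = as.integer(kept_trial_idx),
                 channel_names = channel_names),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz (subject %s)\n",
              d[1L], d[2L], d[3L], x$fs, x$subject_id))
  invisible(x)
}

#' Segment a recording into cue-locked epochs
#'
#' One epoch per event, starting at the event onset, spanning
#' `round(trial_len * fs)` samples (half-open window, 0-based offsets).
#' Events whose window would run past the end of the recording are dropped
#' and counted in the `n_dropped` attribute.
#'
#' @param rec a `raw_recording`.
#' @param trial_len epoch length in seconds (default 4).
#' @return an `epoch_set` with `data` trials x channels x samples, `labels`
#'   in \{-1, +1\}, and attribute `n_dropped`.
#' @export
segment_epochs <- function(rec, trial_len = 4) {
  len <- round(trial_len * rec$fs)
  ev <- rec$events
  keep <- ev$onset + len - 1L <= ncol(rec$data)
  n_dropped <- sum(!keep)
  ev <- ev[keep, , drop = FALSE]
  nt <- nrow(ev)
  nc <- nrow(rec$data)
  data <- array(0, c(nt, nc, len))
  for (i in seq_len(nt))
    data[i, , ] <- rec$data[, ev$onset[i]:(ev$onset[i] + len - 1L)]
  out <- new_epoch_set(data, ev$label, rec$fs,
                       subject_id = rec$subject_id %||% NA_integer_,
                       kept_trial_idx = which(keep),
                       channel_names = rec$channel_names)
  attr(out, "n_dropped") <- n_dropped
  out
}

mav_threshold <- function(mav) mean(mav) + 3 * stats::sd(mav)

#' Reject artifact trials by the MAV + 3 SD rule
#'
#' The mean absolute value of each trial (over all channels and samples) is
#' compared against `mean(MAV) + 3*sd(MAV)`; trials strictly above the
#' threshold are removed.
#'
#' @param epochs an `epoch_set` with at least 2 trials.
#' @return list with `epochs` (cleaned) and `report` (a `rejection_report`:
#'   `trial_mav`, `threshold`, `rejected_trials` as indices into the input).
#' @export
reject_trials <- function(epochs) {
  nt <- dim(epochs$data)[1L]
  if (nt < 2L) stop("trial rejection requires at least 2 trials")
  mav <- apply(abs(epochs$data), 1L, mean)
  thr <- mav_threshold(mav)
  bad <- which(mav > thr)
  if (length(bad) == nt) stop("all trials rejected; pipeline cannot proceed")
  keep <- setdiff(seq_len(nt), bad)
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$labels <- epochs$labels[keep]
  out$kept_trial_idx <- epochs$kept_trial_idx[keep]
  report <- structure(list(trial_mav = mav, threshold = thr,
                           rejected_trials = bad,
                           rejected_channels = integer(0)),
                      class = "rejection_report")
  list(epochs = out, report = report)
}

#' Reject noisy channels by the MAV + 3 SD rule
#'
#' Same statistic as [reject_trials()], computed per channel across all
#' trials and samples; channels strictly above `mean + 3*sd` are removed.
#'
#' @param epochs an `epoch_set` with at least 2 channels.
#' @return list with `epochs` and `report` (`rejected_channels`,
#'   `channel_mav` stored in `trial_mav` slot name `channel_mav`).
#' @export
reject_channels <- function(epochs) {
  nc <- dim(epochs$data)[2L]
  if (nc < 2L) stop("channel rejection requires at least 2 channels")
  mav <- apply(abs(epochs$data), 2L, mean)
  thr <- mav_threshold(mav)
  bad <- which(mav > thr)
  if (length(bad) == nc) stop("all channels rejected; pipeline cannot proceed")
  keep <- setdiff(seq_len(nc), bad)
  out <- epochs
  out$data <- epochs$data[, keep, , drop = FALSE]
  if (!is.null(out$channel_names)) out$channel_names <- out$channel_names[keep]
  report <- structure(list(channel_mav = mav, threshold = thr,
                           rejected_trials = integer(0),
                           rejected_channels = bad),
                      class = "rejection_report")
  list(epochs = out, report = report)
}

#' Full preprocessing pipeline for one recording
#'
#' Filter -> segment -> reject, in that order. Channel rejection runs before
#' trial rejection (the rejection statistics are computed once, not
#' iteratively).
#'
#' @param rec a `raw_recording`.
#' @param spec a [filter_spec()].
#' @param trial_len epoch length in seconds.
#' @return list with `epochs`, `channel_report`, `trial_report`.
#' @export
preprocess_recording <- function(rec, spec = filter_spec(), trial_len = 4) {
  filtered <- highpass_filter(rec, spec)
  epochs <- segment_epochs(filtered, trial_len)
  ch <- reject_channels(epochs)
  tr <- reject_trials(ch$epochs)
  list(epochs = tr$epochs, channel_report = ch$report, trial_report = tr$report)
}

#' Map epochs onto the model input window
#'
#' The networks operate on a fixed-length window (180 samples by default,
#' the length whose six-fold ceiling-halving gives the 90/45/23/12/6/3 time
#' progression). Epochs are reduced to that length either by integer-factor
#' decimation (block averaging of adjacent samples; used when the epoch
#' length is an integer multiple of `input_time`) or by cropping the first
#' `input_time` samples.
#'
#' @param epochs an `epoch_set`.
#' @param input_time target window length in samples.
#' @param method `"auto"` (decimate when the lengths divide evenly, crop
#'   otherwise), `"decimate"`, or `"crop"`.
#' @return an `epoch_set` whose last dimension is `input_time`.
#' @export
prepare_input <- function(epochs, input_time = 180L, method = c("auto", "decimate", "crop")) {
  method <- match.arg(method)
  s <- dim(epochs$data)[3L]
  if (s < input_time) stop("epochs shorter than the requested input window")
  if (s == input_time) return(epochs)
  fac <- s / input_time
  if (method == "auto") method <- if (fac == round(fac)) "decimate" else "crop"
  out <- epochs
  if (method == "decimate") {
    if (fac != round(fac)) stop("decimation requires an integer factor")
    d <- dim(epochs$data)
    x <- array(epochs$data, c(d[1L], d[2L], fac, input_time))
    out$data <- colMeans(aperm(x, c(3L, 1L, 2L, 4L)))
    out$fs <- epochs$fs / fac
  } else {
    out$data <- epochs$data[, , seq_len(input_time), drop = FALSE]
  }
  out
}
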