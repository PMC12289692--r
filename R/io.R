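# File interchange: a minimal EDF (European Data Format) writer/reader for
# continuous recordings, and the internal epoch container (flat binary array
# + JSON metadata sidecar). EDF stores int16 samples with per-signal
# physical/digital scaling; cue events go to a companion tab-separated file
# because plain EDF has no annotation channel.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Writes a plain EDF (one data record per second, int16 samples scaled to
#' the physical range of each channel). Event markers are written to
#' `<path>.events.tsv` with columns `onset` (sample) and `label`.
#'
#' @param rec a `raw_recording`.
#' @param path output file path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  data <- rec$data
  fs <- rec$fs
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  nc <- nrow(data)
  spr <- as.integer(fs)                       # samples per record (1-s records)
  n_rec <- ceiling(ncol(data) / spr)
  if (ncol(data) < n_rec * spr)               # zero-pad the final record
    data <- cbind(data, matrix(0, nc, n_rec * spr - ncol(data)))
  pmin_ <- apply(data, 1L, min)
  pmax_ <- apply(data, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1              # avoid zero physical range
  # the header stores the physical range rounded to 2 decimals; use exactly
  # the stored values for scaling so the round trip is step-accurate
  pmin_ <- floor(pmin_ * 100) / 100
  pmax_ <- ceiling(pmax_ * 100) / 100
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L),
    edf_pad("synthetic motor imagery EEG", 80L),
    edf_pad(sprintf("subject %d", rec$subject_id %||% 0L), 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * (1L + nc), 8L),
    edf_pad("", 44L),
    edf_pad(n_rec, 8L),
    edf_pad("1", 8L),
    edf_pad(nc, 4L))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    edf_pad(rec$channel_names, 16L),
    edf_pad(rep("synthetic EEG", nc), 80L),
    edf_pad(rep("uV", nc), 8L),
    edf_pad(formatC(pmin_, format = "f", digits = 2), 8L),
    edf_pad(formatC(pmax_, format = "f", digits = 2), 8L),
    edf_pad(rep(dmin, nc), 8L),
    edf_pad(rep(dmax, nc), 8L),
    edf_pad(rep("", nc), 80L),
    edf_pad(rep(spr, nc), 8L),
    edf_pad(rep("", nc), 32L))
  for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- (r - 1L) * spr + seq_len(spr)
    for (ch in seq_len(nc)) {
      dig <- round((data[ch, idx] - pmin_[ch]) * scale[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  if (!is.null(rec$events) && nrow(rec$events) > 0)
    utils::write.table(rec$events, paste0(path, ".events.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Restores the channels x samples matrix (to int16 quantization precision),
#' sampling rate, channel names, and events from the companion
#' `.events.tsv` if present.
#'
#' @param path EDF file path.
#' @return a `raw_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8L); rd(80L)
  patient <- trimws(rd(80L))                   # "subject <id>" when written here
  subject_id <- if (grepl("^subject [0-9]+$", patient))
    as.integer(sub("^subject ", "", patient)) else NA_integer_
  rd(8L); rd(8L)
  rd(8L)                                       # header bytes
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  nc <- as.integer(rd(4L))
  labels <- trimws(vapply(seq_len(nc), function(i) rd(16L), ""))
  for (i in seq_len(nc)) rd(80L)
  for (i in seq_len(nc)) rd(8L)
  pmin_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8L), ""))
  pmax_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8L), ""))
  dmin <- as.numeric(vapply(seq_len(nc), function(i) rd(8L), ""))
  dmax <- as.numeric(vapply(seq_len(nc), function(i) rd(8L), ""))
  for (i in seq_len(nc)) rd(80L)
  spr <- as.integer(vapply(seq_len(nc), function(i) rd(8L), ""))
  for (i in seq_len(nc)) rd(32L)

  data <- matrix(0, nc, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nc)) {
      dig <- readBin(con, "integer", spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) /
        (dmax[ch] - dmin[ch]) + pmin_[ch]
      data[ch, (r - 1L) * spr[ch] + seq_len(spr[ch])] <- phys
    }
  }
  evp <- paste0(path, ".events.tsv")
  events <- if (file.exists(evp)) {
    utils::read.table(evp, header = TRUE, sep = "\t")
  } else data.frame(onset = integer(0), label = numeric(0))
  structure(list(data = data, fs = spr[1L] / rec_dur, channel_names = labels,
                 events = events, subject_id = subject_id),
            class = "raw_recording")
}

#' Write an epoch set to the internal container
#'
#' A directory holding `data.bin` (float64, little-endian, in
#' trials x channels x samples order) and `meta.json` with dimensions,
#' labels, sampling rate, subject id and kept trial indices.
#'
#' @param epochs an `epoch_set` (see [segment_epochs()]).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "data.bin"), "wb")
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  close(con)
  meta <- list(dim = dim(epochs$data), labels = epochs$labels, fs = epochs$fs,
               subject_id = epochs$subject_id,
               kept_trial_idx = epochs$kept_trial_idx,
               channel_names = epochs$channel_names)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read an epoch set from the internal container
#' @param dir directory written by [write_epochs()].
#' @return an `epoch_set`.
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(file.path(dir, "data.bin"), "rb")
  x <- readBin(con, "numeric", n, size = 8L, endian = "little")
  close(con)
  new_epoch_set(array(x, meta$dim), meta$labels, meta$fs,
                meta$subject_id %||% NA_integer_,
                meta$kept_trial_idx, meta$channel_names)
}
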