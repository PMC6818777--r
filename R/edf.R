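#' Write a recording to an EDF file
#'
#' Minimal European Data Format writer: one data record per second, all
#' channels sampled at the recording rate, signals scaled linearly into the
#' 16-bit digital range from per-channel physical extrema. Channel labels
#' are the recording's montage. Values survive a round trip through
#' [read_edf()] up to 16-bit quantization of the per-channel range.
#'
#' @param recording a `psg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  sig <- recording$signal
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(sig)
  n_rec <- ncol(sig) %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  sig <- sig[, seq_len(n_rec * fs), drop = FALSE]

  pmin_ <- apply(sig, 1L, min)
  pmax_ <- apply(sig, 1L, max)
  same <- pmax_ - pmin_ < 1e-12
  pmax_[same] <- pmin_[same] + 1

  pad <- function(x, w) {
    x <- substr(as.character(x), 1L, w)
    formatC(x, width = w, flag = "-")
  }
  num <- function(x, w) pad(formatC(x, format = "g", digits = 8), w)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  # fixed 256-byte header
  wr(pad("0", 8))
  wr(pad(paste("X X X", recording$subject), 80))
  wr(pad(paste("Startdate X X X", recording$session), 80))
  wr(pad("01.01.00", 8)); wr(pad("00.00.00", 8))
  wr(pad(as.character(256L + ns * 256L), 8))
  wr(pad("", 44))
  wr(pad(as.character(n_rec), 8))
  wr(pad("1", 8))
  wr(pad(as.character(ns), 4))
  # per-channel header fields, each field for all channels in sequence
  wr(paste0(vapply(recording$channels, pad, character(1), w = 16L), collapse = ""))
  wr(strrep(" ", 80L * ns))                       # transducer
  wr(paste0(rep(pad("uV", 8), ns), collapse = "")) # physical dimension
  wr(paste0(vapply(pmin_, num, character(1), w = 8L), collapse = ""))
  wr(paste0(vapply(pmax_, num, character(1), w = 8L), collapse = ""))
  wr(paste0(rep(pad("-32768", 8), ns), collapse = ""))
  wr(paste0(rep(pad("32767", 8), ns), collapse = ""))
  wr(strrep(" ", 80L * ns))                       # prefiltering
  wr(paste0(rep(pad(as.character(fs), 8), ns), collapse = ""))
  wr(strrep(" ", 32L * ns))                       # reserved

  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    idx <- (r - 1L) * fs + seq_len(fs)
    for (c_i in seq_len(ns)) {
      dig <- round((sig[c_i, idx] - pmin_[c_i]) / scale[c_i]) - 32768L
      writeBin(as.integer(pmin(32767, pmax(-32768, dig))), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Parses the EDF header and 16-bit data records and rescales to physical
#' units. Subject and session identifiers are recovered from the patient and
#' recording-id header fields when present.
#'
#' @param path EDF file path.
#' @param hypnogram optional stage-label vector (e.g. from
#'   [read_hypnogram()]) to attach.
#' @return a `psg_recording` (hypnogram empty unless supplied).
#' @export
read_edf <- function(path, hypnogram = character(0)) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  patient <- rd(80)
  recid <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  rd(80 * ns)
  rd(8 * ns)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(32 * ns)

  fs <- spr[1] / rec_dur
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1],
                dimnames = list(labels, NULL))
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_rec)) {
    for (c_i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[c_i], size = 2L, signed = TRUE,
                     endian = "little")
      sig[c_i, (r - 1L) * spr[c_i] + seq_len(spr[c_i])] <-
        (dig - dmin_[c_i]) * scale[c_i] + pmin_[c_i]
    }
  }
  subject <- sub("^X X X ", "", patient)
  session <- sub("^Startdate X X X ", "", recid)
  structure(list(subject = subject, session = session, channels = labels,
                 fs = fs, epoch_s = 30, signal = sig, hypnogram = hypnogram),
            class = "psg_recording")
}

#' Write a hypnogram as CSV
#'
#' Two columns: `epoch_index` (0-based) and `stage`.
#' @param hypnogram character vector of stage labels.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hypnogram, path) {
  write.csv(data.frame(epoch_index = seq_along(hypnogram) - 1L,
                       stage = hypnogram),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a hypnogram CSV
#' @param path CSV with `epoch_index,stage` columns.
#' @return character vector of stage labels ordered by epoch index.
#' @export
read_hypnogram <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$stage[order(df$epoch_index)]
}
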