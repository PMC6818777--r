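#' @importFrom stats nextn
NULL

# zero-phase FIR filtering: |B(f)|^2 applied in the frequency domain.
# Equivalent to forward-backward application of the FIR b; edge transients
# are circular over the zero padding and negligible for taps << length(x).
.fir_zerophase <- function(x, b) {
  n <- length(x)
  nfft <- nextn(n + 2L * length(b), 2)
  H <- fft(c(b, numeric(nfft - length(b))))
  X <- fft(c(x, numeric(nfft - n)))
  Re(fft(X * (Mod(H)^2), inverse = TRUE))[seq_len(n)] / nfft
}

.apply_rows <- function(sig, fun) {
  out <- t(apply(sig, 1L, fun))
  dimnames(out) <- dimnames(sig)
  out
}

#' Down-sample a recording
#'
#' Anti-alias FIR low-pass (Hamming-window design, cutoff at 80% of the new
#' Nyquist frequency, applied zero-phase) followed by decimation. The target
#' rate must divide the original rate.
#'
#' @param recording a `psg_recording`.
#' @param target_fs new sampling rate in Hz (e.g. 125 from a 500 Hz
#'   acquisition).
#' @return the recording resampled at `target_fs`.
#' @export
downsample <- function(recording, target_fs = 125) {
  fs <- recording$fs
  if (target_fs >= fs) stop("target_fs must be below the original rate")
  q <- fs / target_fs
  if (abs(q - round(q)) > 1e-9) stop("target_fs must divide the original rate")
  q <- as.integer(round(q))
  b <- signal::fir1(64, 0.8 / q)
  sel <- seq(1L, ncol(recording$signal), by = q)
  recording$signal <- .apply_rows(recording$signal,
                                  function(x) .fir_zerophase(x, b)[sel])
  recording$fs <- target_fs
  recording$provenance <- c(recording$provenance,
                            sprintf("downsample: %g -> %g Hz", fs, target_fs))
  recording
}

#' Band-pass filter a recording
#'
#' Zero-phase FIR band-pass (Hamming-window design) applied per channel; the
#' default 0.5-35 Hz band is the standard conditioning for neonatal sleep
#' EEG. Filter length scales with the low edge so the transition band stays
#' below one octave of it (about `3.3 * fs / low` taps), giving < 1 dB
#' pass-band ripple and > 40 dB stop-band attenuation after the two-pass
#' (magnitude-squared) application.
#'
#' @param recording a `psg_recording`.
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @return the filtered recording.
#' @export
bandpass <- function(recording, low = 0.5, high = 35) {
  fs <- recording$fs
  if (low <= 0 || high <= low || high >= fs / 2) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  ntaps <- 2L * ceiling(1.65 * fs / low) + 1L
  ntaps <- min(ntaps, 2L * (ncol(recording$signal) %/% 4L) + 1L)
  b <- signal::fir1(ntaps - 1L, c(low, high) / (fs / 2), type = "pass")
  recording$signal <- .apply_rows(recording$signal,
                                  function(x) .fir_zerophase(x, b))
  recording$provenance <- c(recording$provenance,
                            sprintf("bandpass: %g-%g Hz FIR, zero-phase", low, high))
  recording
}

#' Reduce a recording to the standard sleep montage
#'
#' Selects (and reorders) the requested channels. A requested bipolar channel
#' `"A-B"` absent from the input is formed by subtracting unipolar `B` from
#' `A` when both are present, so high-density input can be reduced to the
#' habitual 11-channel sleep montage. Requesting the montage the recording
#' already has is the identity.
#'
#' @param recording a `psg_recording`.
#' @param montage character vector of channel names, default [psg_montage()].
#' @return the recording restricted to `montage`, in that order.
#' @export
reduce_montage <- function(recording, montage = psg_montage()) {
  have <- recording$channels
  rows <- matrix(NA_real_, nrow = length(montage), ncol = ncol(recording$signal),
                 dimnames = list(montage, NULL))
  for (i in seq_along(montage)) {
    ch <- montage[i]
    if (ch %in% have) {
      rows[i, ] <- recording$signal[ch, ]
    } else if (grepl("-", ch, fixed = TRUE)) {
      parts <- strsplit(ch, "-", fixed = TRUE)[[1]]
      if (length(parts) == 2 && all(parts %in% have)) {
        rows[i, ] <- recording$signal[parts[1], ] - recording$signal[parts[2], ]
      } else {
        stop("missing channel: ", ch)
      }
    } else {
      stop("missing channel: ", ch)
    }
  }
  recording$signal <- rows
  recording$channels <- montage
  recording$provenance <- c(recording$provenance,
                            sprintf("montage: %d channels", length(montage)))
  recording
}

#' Cut a recording into fixed-length labeled epochs
#'
#' Epoch `i` (0-based) covers samples `[i*epoch_s*fs, (i+1)*epoch_s*fs)`;
#' a trailing partial segment is dropped. Stage labels are attached from the
#' recording's hypnogram by index. A hypnogram shorter or longer than the
#' signal by more than one epoch is an error.
#'
#' @param recording a `psg_recording`.
#' @param epoch_s epoch length in seconds (default 30).
#' @return an `epoch_set`: list with `epochs` (each `subject`, `session`,
#'   `index`, `stage`, `signal`, `fs`), `montage`, `fs`, `provenance`.
#' @export
epoch_recording <- function(recording, epoch_s = 30) {
  if (epoch_s <= 0) stop("epoch_s must be positive")
  spe <- as.integer(round(epoch_s * recording$fs))
  n_ep <- ncol(recording$signal) %/% spe
  n_hyp <- length(recording$hypnogram)
  if (abs(n_hyp - n_ep) > 1L) {
    stop(sprintf("hypnogram length (%d) differs from signal epochs (%d) by more than one",
                 n_hyp, n_ep))
  }
  n_ep <- min(n_ep, n_hyp)
  epochs <- vector("list", n_ep)
  for (i in seq_len(n_ep)) {
    idx <- (i - 1L) * spe + seq_len(spe)
    epochs[[i]] <- list(subject = recording$subject,
                        session = recording$session,
                        index = i - 1L,
                        stage = recording$hypnogram[i],
                        signal = recording$signal[, idx, drop = FALSE],
                        fs = recording$fs)
  }
  structure(list(epochs = epochs, montage = recording$channels,
                 fs = recording$fs,
                 provenance = c(recording$provenance,
                                sprintf("epoch: %g s, %d epochs", epoch_s, n_ep))),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  st <- vapply(x$epochs, function(e) e$stage, character(1))
  cat(sprintf("Epoch set: %d epochs, %d channels @ %g Hz\n",
              length(x$epochs), length(x$montage), x$fs))
  if (length(st)) print(table(st))
  invisible(x)
}

# mean band power over EEG channels, the artifact score (Welch estimate)
.artifact_score <- function(epoch, band) {
  eeg <- intersect(.eeg_channels(), rownames(epoch$signal))
  if (!length(eeg)) eeg <- rownames(epoch$signal)
  mean(vapply(eeg, function(ch) {
    ps <- .welch_density(epoch$signal[ch, ], epoch$fs,
                         nseg = min(round(2 * epoch$fs), ncol(epoch$signal)),
                         overlap = 0.5)
    sel <- ps$freq >= band[1] & ps$freq <= band[2]
    mean(ps$psd[sel])
  }, numeric(1)))
}

#' Exclude artifact epochs
#'
#' Two stages, mirroring the study design: (1) every epoch labeled MOVEMENT
#' or TRANSITIONAL is removed unconditionally; (2) each remaining epoch gets
#' an artifact score — its mean Welch power in `band` (default 19-21 Hz, the
#' signature of electrode-impedance artifacts) averaged over the EEG
#' channels — and the epochs whose score lies above the recording-wise
#' `percentile` quantile (the top `floor(n * (1 - percentile))` scores) are
#' removed. Score ties are broken by keeping the earlier epoch. The removal
#' fractions are appended to the provenance log.
#'
#' The operation is idempotent: the provenance log records the exclusion
#' parameters, and an epoch set that already went through the same
#' band/percentile thresholding is not thresholded again (the quantile is
#' defined on the raw recording's score distribution, so re-applying it to
#' already-clean epochs would discard clean data).
#'
#' @param epoch_set an `epoch_set`.
#' @param band numeric `c(lo, hi)` Hz for the artifact score (default 19-21).
#' @param percentile quantile threshold in (0, 1), default 0.95.
#' @return the reduced `epoch_set`; only NREM/REM/WAKE epochs remain.
#' @export
exclude_artifacts <- function(epoch_set, band = c(19, 21), percentile = 0.95) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  if (percentile <= 0 || percentile >= 1) stop("percentile must be in (0, 1)")
  if (!length(epoch_set$epochs)) stop("empty epoch set")
  stages <- vapply(epoch_set$epochs, function(e) e$stage, character(1))
  keep_lbl <- stages %in% .stages()
  n_lbl_removed <- sum(!keep_lbl)
  eps <- epoch_set$epochs[keep_lbl]

  tag <- sprintf("exclude[band=%g-%g,p=%g]", band[1], band[2], percentile)
  already <- any(startsWith(epoch_set$provenance %||% character(0), tag))

  n <- length(eps)
  k <- if (already) 0L else floor(n * (1 - percentile))
  removed_idx <- integer(0)
  if (n > 0 && k > 0) {
    scores <- vapply(eps, .artifact_score, numeric(1), band = band)
    # top-k by score; ties keep the earlier epoch (later index removed first)
    ord <- order(scores, seq_len(n), decreasing = TRUE)
    removed_idx <- sort(ord[seq_len(k)])
  }
  if (length(removed_idx)) eps <- eps[-removed_idx]

  epoch_set$epochs <- eps
  epoch_set$provenance <- c(
    epoch_set$provenance,
    sprintf("%s: %d movement/transitional (%.1f%%), %d artifact (%.1f%%)",
            tag, n_lbl_removed, 100 * n_lbl_removed / max(1L, n_lbl_removed + n),
            length(removed_idx), 100 * length(removed_idx) / max(1L, n))
  )
  epoch_set
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full preprocessing chain on a recording
#'
#' Fixed, logged order: down-sample, reduce montage, band-pass, epoch,
#' exclude artifacts.
#'
#' @param recording a `psg_recording`.
#' @param target_fs,low,high,epoch_s,band,percentile stage parameters; see
#'   the individual operations.
#' @param montage target montage, default [psg_montage()].
#' @return a clean `epoch_set`.
#' @export
preprocess_recording <- function(recording, target_fs = 125,
                                 montage = psg_montage(),
                                 low = 0.5, high = 35, epoch_s = 30,
                                 band = c(19, 21), percentile = 0.95) {
  rec <- downsample(recording, target_fs)
  rec <- reduce_montage(rec, montage)
  rec <- bandpass(rec, low, high)
  es <- epoch_recording(rec, epoch_s)
  exclude_artifacts(es, band = band, percentile = percentile)
}
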