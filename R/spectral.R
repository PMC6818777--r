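#' Welch power spectral density of a multi-channel epoch
#'
#' Welch's method: the signal is cut into overlapping Hamming-windowed
#' segments, each segment's one-sided periodogram is computed with density
#' normalization (`|FFT|^2 / (fs * sum(w^2))`, doubled off DC/Nyquist), and
#' the periodograms are averaged. The native-resolution spectrum is then
#' aggregated into 1-Hz-wide bins centered on integer frequencies (`f` covers
#' `[f - 0.5, f + 0.5)`), the representation used for the 330-dimensional
#' (11 channels x 30 bins) spectral feature vectors.
#'
#' Density normalization satisfies Parseval: the PSD of unit-variance white
#' noise integrates to about 1 over `[0, fs/2]`.
#'
#' @param epoch a channels-x-samples matrix with channel rownames, or an
#'   `epoch` object.
#' @param fs sampling rate in Hz (taken from the epoch object if present).
#' @param window_s segment length in seconds (default 4).
#' @param overlap fractional segment overlap in `[0, 1)` (default 0.5).
#' @param fmin,fmax first and last 1-Hz bin center (defaults 1 and 30 Hz).
#' @param step bin spacing in Hz (default 1).
#' @return a `psd_vector`: named numeric vector `<channel>_f<hz>` in
#'   microvolt^2/Hz, channel-major, with attributes `channels` and `freqs`.
#' @examples
#' x <- matrix(rnorm(3750), 1, dimnames = list("C3", NULL))
#' welch_psd(x, fs = 125)
#' @export
welch_psd <- function(epoch, fs = NULL, window_s = 4, overlap = 0.5,
                      fmin = 1, fmax = 30, step = 1) {
  sig <- if (is.list(epoch) && !is.null(epoch$signal)) epoch$signal else epoch
  if (is.list(epoch) && is.null(fs)) fs <- epoch$fs
  if (is.null(fs)) stop("fs must be supplied for a bare signal matrix")
  if (!is.matrix(sig)) sig <- matrix(sig, nrow = 1)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  nseg <- round(window_s * fs)
  if (nseg > ncol(sig)) stop("window longer than the epoch")
  if (fmax >= fs / 2) stop("fmax must be below the Nyquist frequency")

  channels <- rownames(sig)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(sig)))
  freqs <- seq(fmin, fmax, by = step)

  vals <- numeric(0)
  for (c_i in seq_len(nrow(sig))) {
    ps <- .welch_density(sig[c_i, ], fs, nseg, overlap)
    vals <- c(vals, .aggregate_bins(ps$psd, ps$freq, freqs, step))
  }
  names(vals) <- as.vector(t(outer(channels, freqs,
                                   function(ch, f) sprintf("%s_f%g", ch, f))))
  structure(vals, channels = channels, freqs = freqs,
            class = c("psd_vector", "numeric"))
}

# one-sided Welch density at native FFT resolution
.welch_density <- function(x, fs, nseg, overlap) {
  hop <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1)) # Hamming
  u <- sum(w^2)
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)] * w
    p <- abs(fft(seg))^2 / (fs * u)
    p <- p[seq_len(nfreq)]
    # one-sided: double everything except DC and (for even nseg) Nyquist
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nseg %% 2L == 0L) dbl[nfreq] <- 1
    acc <- acc + p * dbl
  }
  list(psd = acc / length(starts), freq = (seq_len(nfreq) - 1L) * fs / nseg)
}

# mean density within [f - step/2, f + step/2) per requested bin center
.aggregate_bins <- function(psd, freq, centers, step) {
  vapply(centers, function(f) {
    sel <- freq >= f - step / 2 & freq < f + step / 2
    if (!any(sel)) return(NA_real_)
    mean(psd[sel])
  }, numeric(1))
}

#' Per-epoch Welch PSD feature table for an epoch set
#'
#' Applies [welch_psd()] to every epoch; one row per epoch with metadata
#' columns followed by `<channel>_f<hz>` columns (channel-major). With the
#' 11-channel montage and 1-30 Hz bins this is the 330-column table fed to
#' the PSD-based classifier.
#'
#' @inheritParams welch_psd
#' @param epoch_set an epoch set.
#' @return data frame with a `feature_info` attribute (channel and frequency
#'   per column).
#' @export
psd_features <- function(epoch_set, window_s = 4, overlap = 0.5,
                         fmin = 1, fmax = 30, step = 1) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  feats <- lapply(epoch_set$epochs, function(ep) {
    as.numeric(welch_psd(ep$signal, fs = ep$fs, window_s = window_s,
                         overlap = overlap, fmin = fmin, fmax = fmax,
                         step = step))
  })
  channels <- epoch_set$montage
  freqs <- seq(fmin, fmax, by = step)
  cols <- as.vector(t(outer(channels, freqs,
                            function(ch, f) sprintf("%s_f%g", ch, f))))
  .feature_table(epoch_set, feats, cols,
                 data.frame(feature = cols,
                            channel = rep(channels, each = length(freqs)),
                            freq = rep(freqs, length(channels)),
                            stringsAsFactors = FALSE))
}
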