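#' @importFrom stats fft rnorm runif rbinom rgeom quantile median sd setNames
#' @importFrom utils read.csv write.csv
NULL

#' Canonical 11-channel neonatal sleep montage
#'
#' Six EEG channels (F3, F4, C3, C4, O1, O2) and five peripheral channels
#' (bipolar ECG, bipolar EMG, bipolar VEOG, left and right HEOG), the reduced
#' habitual sleep montage used throughout the pipeline.
#' @export
psg_montage <- function() {
  c("F3", "F4", "C3", "C4", "O1", "O2",
    "ECG", "EMG", "VEOG", "HEOG_L", "HEOG_R")
}

.eeg_channels <- function() c("F3", "F4", "C3", "C4", "O1", "O2")
.stages <- function() c("NREM", "REM", "WAKE")

#' Specification of one vigilance state's signal structure
#'
#' Describes how the generator synthesises EEG for one state: relative power
#' per frequency band, an optional coherent slow oscillation, the broadband
#' (white) noise fraction controlling fast-scale irregularity, overall RMS
#' amplitude, and event models for tracé-alternant-like bursting, slow eye
#' movements and muscle tone.
#'
#' @param name one of `"NREM"`, `"REM"`, `"WAKE"`.
#' @param band_powers named numeric vector of relative powers for the bands
#'   `delta` (0.5-4 Hz), `theta` (4-8), `alpha` (8-12), `beta` (12-30);
#'   non-negative, normalized internally.
#' @param amplitude target RMS of the EEG channels in microvolts.
#' @param broadband fraction of EEG variance that is white noise, in `[0, 1)`.
#'   This is the generator's complexity dial: higher values raise fast-scale
#'   permutation entropy.
#' @param slow_osc `NULL` or `c(freq = Hz, power = fraction)`: a coherent
#'   high-amplitude slow oscillation (the dominant feature of neonatal wake
#'   EEG) that survives coarse-graining and lowers slow-scale entropy.
#' @param burst `NULL` or a list with `rate_per_min`, `duration_s`, `band`
#'   (`c(lo, hi)` Hz) and `gain`: amplitude bursts with superimposed fast
#'   activity, a tracé-alternant-like NREM pattern. The quantitative defaults
#'   are placeholders (no quantitative burst model is available for this
#'   population); only their presence/absence is meaningful.
#' @param ocular_rate slow-eye-movement events per minute on the EOG channels.
#' @param emg_tone relative broadband EMG power (1 = full wake tone).
#' @return a `state_spec` list.
#' @export
state_spec <- function(name,
                       band_powers = c(delta = 0.5, theta = 0.25,
                                       alpha = 0.15, beta = 0.10),
                       amplitude = 40, broadband = 0.3, slow_osc = NULL,
                       burst = NULL, ocular_rate = 0, emg_tone = 0.3) {
  if (!name %in% .stages()) {
    stop("unknown state '", name, "': must be one of NREM, REM, WAKE")
  }
  if (any(band_powers < 0)) stop("band powers must be non-negative")
  if (amplitude <= 0) stop("amplitude must be positive")
  if (broadband < 0 || broadband >= 1) stop("broadband fraction must be in [0, 1)")
  structure(list(name = name, band_powers = band_powers, amplitude = amplitude,
                 broadband = broadband, slow_osc = slow_osc, burst = burst,
                 ocular_rate = ocular_rate, emg_tone = emg_tone),
            class = "state_spec")
}

#' Default state specifications
#'
#' Encode the qualitative neonatal EEG structure the analysis relies on:
#' \itemize{
#'   \item NREM ("quiet sleep"): high-voltage slow activity dominated by
#'     delta, low broadband fraction, tracé-alternant-like bursts, muscle
#'     tone reduced, few eye movements.
#'   \item REM ("active sleep"): low-voltage irregular EEG with a flatter
#'     spectrum, frequent slow eye movements, muscular atonia.
#'   \item WAKE: mixed EEG with a very-high-amplitude coherent slow
#'     oscillation, the highest broadband fraction, full EMG tone and eye
#'     movements.
#' }
#' The broadband fractions (NREM 0.08 < REM 0.28 < WAKE 0.50) order
#' fast-scale permutation entropy WAKE > REM > NREM by construction; the
#' coherent wake oscillation makes WAKE the most regular state after
#' coarse-graining, giving REM > WAKE at the slow scale.
#' @return named list of [state_spec()] objects.
#' @export
default_state_specs <- function() {
  list(
    NREM = state_spec("NREM",
      band_powers = c(delta = 0.78, theta = 0.12, alpha = 0.06, beta = 0.04),
      amplitude = 60, broadband = 0.08,
      burst = list(rate_per_min = 3, duration_s = 3, band = c(12, 25),
                   gain = 0.6),
      ocular_rate = 0.2, emg_tone = 0.4),
    REM = state_spec("REM",
      band_powers = c(delta = 0.35, theta = 0.30, alpha = 0.20, beta = 0.15),
      amplitude = 30, broadband = 0.28,
      ocular_rate = 4, emg_tone = 0.08),
    WAKE = state_spec("WAKE",
      band_powers = c(delta = 0.30, theta = 0.10, alpha = 0.05, beta = 0.05),
      amplitude = 40, broadband = 0.50,
      slow_osc = c(freq = 2.5, power = 0.5),
      ocular_rate = 3, emg_tone = 1.0)
  )
}

#' Specification of a recording session
#'
#' @param session_id `"week2"` or `"week5"`.
#' @param prevalence probability vector over (NREM, REM, WAKE); must sum to 1.
#' @param dwell mean bout length per state in epochs (named, all >= 1). Bouts
#'   are geometric, and states are entered with probability proportional to
#'   `prevalence / dwell` so that time fractions track `prevalence`.
#' @param complexity_offset scalar added to every state's broadband-noise
#'   fraction; encodes the developmental complexity difference (week-2 EEG is
#'   more irregular than week-5).
#' @return a `session_spec` list.
#' @export
session_spec <- function(session_id,
                         prevalence = c(NREM = 0.115, REM = 0.606, WAKE = 0.279),
                         dwell = c(NREM = 3, REM = 6, WAKE = 4),
                         complexity_offset = 0) {
  if (!session_id %in% c("week2", "week5")) {
    stop("session_id must be 'week2' or 'week5'")
  }
  if (abs(sum(prevalence) - 1) > 1e-8) stop("prevalence must sum to 1")
  if (any(dwell < 1)) stop("dwell means must be at least 1 epoch")
  structure(list(session_id = session_id, prevalence = prevalence,
                 dwell = dwell, complexity_offset = complexity_offset),
            class = "session_spec")
}

#' Default week-2 and week-5 session specifications
#'
#' State prevalences follow the reported time-in-state fractions (week-2:
#' NREM 11.5%, REM 60.6%, WAKE 27.9%; week-5: 19%, 57.2%, 23.8%). The week-2
#' session carries a +0.12 broadband complexity offset so week-2 signals have
#' strictly higher fast-scale entropy than week-5, the developmental effect
#' the downstream statistics and cross-session classification probe.
#' @return named list of [session_spec()] objects.
#' @export
default_session_specs <- function() {
  list(
    week2 = session_spec("week2",
      prevalence = c(NREM = 0.115, REM = 0.606, WAKE = 0.279),
      dwell = c(NREM = 3, REM = 6, WAKE = 4),
      complexity_offset = 0.12),
    week5 = session_spec("week5",
      prevalence = c(NREM = 0.19, REM = 0.572, WAKE = 0.238),
      dwell = c(NREM = 3, REM = 6, WAKE = 4),
      complexity_offset = 0)
  )
}

# unit-variance band-limited Gaussian noise, synthesised by masking the
# spectrum of white noise (exact band edges, no inter-band leakage)
.band_noise <- function(n, fs, lo, hi) {
  hi <- min(hi, fs / 2)
  X <- fft(rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f) # two-sided frequency axis
  X[f < lo | f >= hi] <- 0
  x <- Re(fft(X, inverse = TRUE)) / n
  s <- sd(x)
  if (s < .Machine$double.eps) return(numeric(n))
  x / s
}

# raised-cosine event envelope train; events at `rate` per minute
.event_train <- function(n, fs, rate_per_min, duration_s) {
  env <- numeric(n)
  n_ev <- rbinom(1, size = max(1, round(n / fs / 60 * rate_per_min * 3)),
                 prob = min(1, 1 / 3))
  if (n_ev == 0) return(env)
  len <- max(2L, round(duration_s * fs))
  bump <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = len)))
  starts <- sort(sample.int(max(1L, n - len), n_ev, replace = TRUE))
  for (s0 in starts) {
    idx <- s0:(s0 + len - 1L)
    env[idx] <- pmax(env[idx], bump)
  }
  env
}

# synthesise all channels for one contiguous run of a single state
.state_run_signal <- function(spec, n, fs, complexity_offset,
                              amp_scale = 1, emg_scale = 1,
                              frontal_bb_scale = 0.85) {
  ch <- psg_montage()
  out <- matrix(0, nrow = length(ch), ncol = n, dimnames = list(ch, NULL))
  bands <- list(delta = c(0.5, 4), theta = c(4, 8),
                alpha = c(8, 12), beta = c(12, 30))
  bp <- spec$band_powers / sum(spec$band_powers)
  w <- min(0.95, max(0, spec$broadband + complexity_offset))
  osc_p <- if (is.null(spec$slow_osc)) 0 else unname(spec$slow_osc["power"])

  burst_env <- NULL
  if (!is.null(spec$burst)) {
    burst_env <- .event_train(n, fs, spec$burst$rate_per_min,
                              spec$burst$duration_s)
  }

  for (c_i in seq_along(.eeg_channels())) {
    cn <- .eeg_channels()[c_i]
    banded <- numeric(n)
    for (b in names(bands)) {
      if (bp[[b]] > 0) {
        banded <- banded + sqrt(bp[[b]]) * .band_noise(n, fs, bands[[b]][1],
                                                       bands[[b]][2])
      }
    }
    banded <- banded / max(sd(banded), .Machine$double.eps)
    if (!is.null(burst_env)) {
      fast <- .band_noise(n, fs, spec$burst$band[1], spec$burst$band[2])
      banded <- banded * (1 + spec$burst$gain * burst_env) +
        spec$burst$gain * burst_env * fast
      banded <- banded / max(sd(banded), .Machine$double.eps)
    }
    osc <- numeric(n)
    if (osc_p > 0) {
      f0 <- unname(spec$slow_osc["freq"])
      drift <- cumsum(rnorm(n, 0, 0.02 / sqrt(fs)))
      osc <- sqrt(2) * sin(2 * pi * f0 * (seq_len(n) / fs) + drift)
    }
    w_ch <- if (cn %in% c("F3", "F4")) w * frontal_bb_scale else w
    mix <- sqrt(max(0, 1 - w_ch - osc_p * (1 - w_ch))) * banded +
      sqrt(osc_p * (1 - w_ch)) * osc +
      sqrt(w_ch) * rnorm(n)
    out[cn, ] <- amp_scale * spec$amplitude * mix /
      max(sd(mix), .Machine$double.eps)
  }

  # ECG: quasi-periodic R-wave train (neonatal heart rate ~130 bpm)
  hr <- 130 / 60
  beat_t <- cumsum(1 / hr * (1 + 0.05 * rnorm(ceiling(n / fs * hr * 1.5) + 5)))
  ecg <- numeric(n)
  width <- max(2L, round(0.03 * fs))
  kernel <- exp(-0.5 * ((seq(-2 * width, 2 * width)) / width)^2)
  for (bt in beat_t[beat_t * fs < n - 2 * width - 1 & beat_t > 0]) {
    i0 <- round(bt * fs)
    idx <- (i0 - 2 * width):(i0 + 2 * width)
    ok <- idx >= 1 & idx <= n
    ecg[idx[ok]] <- ecg[idx[ok]] + kernel[ok]
  }
  out["ECG", ] <- 120 * ecg + 5 * rnorm(n)

  # EMG: high-frequency broadband scaled by muscle tone
  out["EMG", ] <- 25 * sqrt(emg_scale * spec$emg_tone) *
    .band_noise(n, fs, 20, fs / 2 * 0.9) + 3 * rnorm(n)

  # EOGs: base noise + slow-eye-movement excursions (HEOGs mirrored)
  sem <- .event_train(n, fs, spec$ocular_rate, duration_s = 1.2)
  sgn <- sign(rnorm(1) + 0.01)
  out["VEOG", ] <- 15 * .band_noise(n, fs, 0.5, 8) + 60 * sem * sgn + 4 * rnorm(n)
  h <- 80 * sem * sgn
  out["HEOG_L", ] <- 12 * .band_noise(n, fs, 0.5, 8) + h + 4 * rnorm(n)
  out["HEOG_R", ] <- 12 * .band_noise(n, fs, 0.5, 8) - h + 4 * rnorm(n)
  out
}

# semi-Markov hypnogram: geometric bouts with mean dwell, bout states drawn
# with probability proportional to prevalence / dwell so that expected time
# shares equal the prevalences (adjacent equal bouts simply merge)
.sample_hypnogram <- function(n_epochs, prevalence, dwell) {
  stages <- .stages()
  entry_w <- prevalence / dwell
  hyp <- character(0)
  while (length(hyp) < n_epochs) {
    cur <- sample(stages, 1, prob = entry_w)
    len <- 1L + rgeom(1, prob = 1 / dwell[[cur]])
    hyp <- c(hyp, rep(cur, len))
  }
  hyp[seq_len(n_epochs)]
}

#' Generate one synthetic neonatal PSG recording
#'
#' Produces a labeled multi-channel recording for one subject-session: a
#' semi-Markov hypnogram of 30-s epochs honoring the session's state
#' prevalences and mean bout lengths, and a per-state signal built from
#' band-limited Gaussian noise mixtures, a broadband (white) complexity
#' component, and state-specific burst / ocular / cardiac / muscular event
#' processes. Identical arguments (including `seed`) give bit-identical
#' output.
#'
#' A configurable fraction of epochs is relabeled MOVEMENT or TRANSITIONAL
#' and overwritten with high-amplitude broadband artifact, so that the
#' exclusion logic downstream is exercised.
#'
#' @param subject_id character subject identifier.
#' @param session_spec a [session_spec()].
#' @param state_specs named list of [state_spec()] objects (NREM, REM, WAKE).
#' @param duration_min recording length in minutes (>= 1).
#' @param seed integer RNG seed.
#' @param fs native sampling rate in Hz (default 500, the acquisition rate).
#' @param epoch_s epoch length in seconds (default 30).
#' @param movement_rate fraction of epochs relabeled MOVEMENT/TRANSITIONAL
#'   (default 0.08, near the reported 7.7% exclusion rate).
#' @param subject_sd named vector of visit-level variability: standard
#'   deviations of the recording's broadband-fraction shift (additive) and
#'   of the log amplitude and log EMG-tone factors. Small relative to the
#'   between-state differences, so state orderings are preserved while
#'   recordings remain individually distinct.
#' @return a `psg_recording`: list with `subject`, `session`, `channels`,
#'   `fs`, `epoch_s`, `signal` (11 x samples matrix, microvolts) and
#'   `hypnogram` (one label per epoch).
#' @export
generate_recording <- function(subject_id, session_spec,
                               state_specs = default_state_specs(),
                               duration_min = 30, seed = 1L, fs = 500,
                               epoch_s = 30, movement_rate = 0.08,
                               subject_sd = c(broadband = 0.04,
                                              amplitude = 0.10,
                                              emg = 0.20)) {
  stopifnot(inherits(session_spec, "session_spec"))
  if (duration_min < 1) stop("duration must be at least one minute")
  bad <- setdiff(names(state_specs), .stages())
  if (length(bad)) stop("unknown state in specs: ", paste(bad, collapse = ", "))
  if (!all(.stages() %in% names(state_specs))) {
    stop("state_specs must cover NREM, REM and WAKE")
  }
  n_epochs <- floor(duration_min * 60 / epoch_s)
  if (n_epochs < 1) stop("duration shorter than one epoch")
  set.seed(as.integer(seed))

  hyp <- .sample_hypnogram(n_epochs, session_spec$prevalence,
                           session_spec$dwell)
  # visit-level variability: each recording carries its own small shift in
  # broadband fraction, overall amplitude and muscle tone, so classifiers
  # must generalize across subjects rather than memorize fixed mixtures
  jitter_bb <- rnorm(1, 0, subject_sd["broadband"])
  amp_scale <- exp(rnorm(1, 0, subject_sd["amplitude"]))
  emg_scale <- exp(rnorm(1, 0, subject_sd["emg"]))
  spe <- epoch_s * fs
  sig <- matrix(0, nrow = length(psg_montage()), ncol = n_epochs * spe,
                dimnames = list(psg_montage(), NULL))

  runs <- rle(hyp)
  pos <- 0L
  for (r in seq_along(runs$lengths)) {
    n_run <- runs$lengths[r] * spe
    sig[, pos + seq_len(n_run)] <-
      .state_run_signal(state_specs[[runs$values[r]]], n_run, fs,
                        session_spec$complexity_offset + jitter_bb,
                        amp_scale = amp_scale, emg_scale = emg_scale)
    pos <- pos + n_run
  }

  if (movement_rate > 0) {
    mv <- which(runif(n_epochs) < movement_rate)
    for (e in mv) {
      hyp[e] <- if (runif(1) < 0.75) "MOVEMENT" else "TRANSITIONAL"
      idx <- (e - 1L) * spe + seq_len(spe)
      sig[, idx] <- 150 * matrix(rnorm(length(psg_montage()) * spe),
                                 nrow = length(psg_montage()))
    }
  }

  structure(list(subject = subject_id, session = session_spec$session_id,
                 channels = psg_montage(), fs = fs, epoch_s = epoch_s,
                 signal = sig, hypnogram = hyp),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf(
    "PSG recording %s/%s: %d channels @ %g Hz, %d epochs of %g s\n",
    x$subject, x$session, length(x$channels), x$fs, length(x$hypnogram),
    x$epoch_s
  ))
  print(table(x$hypnogram))
  invisible(x)
}

#' Generate a two-session synthetic cohort
#'
#' Two recordings per subject (week2 then week5) with a shared subject id.
#' Week-2 recordings have a strictly higher broadband-noise fraction than
#' week-5 (the sessions' `complexity_offset`), so fast-scale entropy is
#' higher at week-2 by construction.
#'
#' @param n_subjects number of subjects (0 gives an empty list).
#' @param seed integer; per-recording seeds are derived as
#'   `seed + subject_index * 1000 + session_index` unless `seeds` is given.
#' @param seeds optional integer matrix/vector of one seed per
#'   subject-session (subjects x sessions).
#' @param session_specs named list of two [session_spec()] objects.
#' @param subject_ids optional character vector (must be unique).
#' @param ... passed to [generate_recording()].
#' @return list of `psg_recording` objects, length `2 * n_subjects`.
#' @export
generate_cohort <- function(n_subjects, seed = 1L, seeds = NULL,
                            session_specs = default_session_specs(),
                            subject_ids = NULL, ...) {
  if (n_subjects == 0) return(list())
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("S%02d", seq_len(n_subjects))
  }
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  if (is.null(seeds)) {
    seeds <- outer(seq_len(n_subjects) * 1000L, seq_along(session_specs), `+`) +
      as.integer(seed)
  }
  seeds <- matrix(as.integer(seeds), nrow = n_subjects)
  out <- vector("list", 2L * n_subjects)
  k <- 1L
  for (i in seq_len(n_subjects)) {
    for (j in seq_along(session_specs)) {
      out[[k]] <- generate_recording(subject_ids[i], session_specs[[j]],
                                     seed = seeds[i, j], ...)
      k <- k + 1L
    }
  }
  out
}
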