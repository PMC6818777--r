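# small recording builder: deterministic signals, direct control of content
make_recording <- function(signal, fs, hypnogram, channels = rownames(signal),
                           subject = "S01", session = "week5") {
  structure(list(subject = subject, session = session, channels = channels,
                 fs = fs, epoch_s = 30, signal = signal,
                 hypnogram = hypnogram),
            class = "psg_recording")
}

sine_recording <- function(freq, fs = 500, minutes = 2, amp = 10) {
  n <- minutes * 60 * fs
  t <- seq_len(n) / fs
  sig <- matrix(rep(amp * sin(2 * pi * freq * t), 2), nrow = 2, byrow = TRUE,
                dimnames = list(c("C3", "C4"), NULL))
  make_recording(sig, fs, rep("REM", minutes * 2))
}

test_that("downsampling preserves sample count and in-band amplitude", {
  rec <- sine_recording(10, fs = 500, minutes = 2)
  out <- downsample(rec, 125)
  expect_equal(out$fs, 125)
  expect_equal(ncol(out$signal), 2 * 60 * 125)

  # compare against the analytic sinusoid at the kept sample times
  # (decimation keeps original samples 1, 5, 9, ...)
  t <- (1 + (seq_len(ncol(out$signal)) - 1) * 4) / 500
  ref <- 10 * sin(2 * pi * 10 * t)
  core <- 200:(length(ref) - 200)
  rms <- function(v) sqrt(mean(v^2))
  expect_equal(rms(out$signal[1, core]), rms(ref[core]), tolerance = 0.01)
  expect_lt(max(abs(out$signal[1, core] - ref[core])), 0.12)

  expect_error(downsample(rec, 500), "below")
  expect_error(downsample(rec, 300), "divide")
})

test_that("band-pass keeps in-band and rejects out-of-band components", {
  rms <- function(v) sqrt(mean(v^2))
  # 0.1 Hz: below the 0.5 Hz edge, must be strongly attenuated
  slow <- sine_recording(0.1, fs = 125, minutes = 4)
  out <- bandpass(slow, 0.5, 35)
  expect_lt(rms(out$signal[1, ]), 0.10 * rms(slow$signal[1, ]))

  # 10 Hz: mid-band, amplitude preserved within 5%
  mid <- sine_recording(10, fs = 125, minutes = 4)
  out2 <- bandpass(mid, 0.5, 35)
  core <- 500:(ncol(out2$signal) - 500)
  expect_equal(rms(out2$signal[1, core]), rms(mid$signal[1, core]),
               tolerance = 0.05)

  # 50 Hz: above the 35 Hz edge at fs 125
  fast <- sine_recording(50, fs = 125, minutes = 4)
  out3 <- bandpass(fast, 0.5, 35)
  expect_lt(rms(out3$signal[1, ]), 0.10 * rms(fast$signal[1, ]))

  expect_error(bandpass(mid, 40, 35), "band edges")
})

test_that("montage reduction selects, reorders and derives bipolar channels", {
  set.seed(9)
  n <- 1000
  chans <- c("F3", "F4", "M1", "M2", "E1", "E2")
  sig <- matrix(rnorm(length(chans) * n), nrow = length(chans),
                dimnames = list(chans, NULL))
  rec <- make_recording(sig, 125, rep("REM", 1))

  out <- reduce_montage(rec, c("F4", "F3"))
  expect_equal(out$channels, c("F4", "F3"))
  expect_identical(out$signal["F3", ], sig["F3", ])

  # bipolar derivation by subtraction of unipolar constituents
  out2 <- reduce_montage(rec, c("F3", "E1-E2"))
  expect_equal(out2$signal["E1-E2", ], sig["E1", ] - sig["E2", ],
               ignore_attr = TRUE)

  # identity on an already-reduced recording
  out3 <- reduce_montage(out, c("F4", "F3"))
  expect_identical(out3$signal, out$signal)

  expect_error(reduce_montage(rec, c("F3", "Cz9")), "missing channel")
})

test_that("epoching is partition-exact and drops trailing partials", {
  fs <- 125
  set.seed(10)
  n_ep <- 4
  sig <- matrix(rnorm(2 * (n_ep * 30 * fs + 17)), nrow = 2,
                dimnames = list(c("C3", "C4"), NULL))
  rec <- make_recording(sig, fs, rep(c("NREM", "REM"), 2))
  es <- epoch_recording(rec, 30)
  expect_length(es$epochs, 4L)
  expect_equal(vapply(es$epochs, function(e) e$stage, character(1)),
               c("NREM", "REM", "NREM", "REM"))
  # concatenating the epochs reproduces the trimmed recording bit-exactly
  cat_sig <- do.call(cbind, lapply(es$epochs, function(e) e$signal))
  expect_identical(cat_sig, sig[, seq_len(n_ep * 30 * fs)])

  # 27 minutes -> 54 epochs of 30 s
  rec27 <- make_recording(
    matrix(0, 1, 27 * 60 * fs, dimnames = list("C3", NULL)),
    fs, rep("REM", 54))
  expect_length(epoch_recording(rec27, 30)$epochs, 54L)

  # hypnogram mismatch beyond one epoch is an error
  bad <- make_recording(sig, fs, rep("REM", 10))
  expect_error(epoch_recording(bad, 30), "differs")
})

test_that("artifact exclusion removes movement labels then the top band-power fraction", {
  fs <- 125
  # 104 epochs: 8 movement/transitional + 96 clean with a known 20 Hz ramp
  n <- 104
  stages <- rep("REM", n)
  stages[c(3, 17, 30, 44, 58, 71, 85, 99)] <- c("MOVEMENT", "TRANSITIONAL",
                                                "MOVEMENT", "MOVEMENT",
                                                "TRANSITIONAL", "MOVEMENT",
                                                "MOVEMENT", "MOVEMENT")
  amp20 <- numeric(n) # per-epoch 20 Hz amplitude, increasing with index
  clean_idx <- which(stages == "REM")
  amp20[clean_idx] <- seq(0.1, 3, length.out = length(clean_idx))
  set.seed(12)
  es <- make_epoch_set(n, fs = fs, channels = c("F3", "C3", "O1"),
                       gen = function(i, ch) {
                         t <- seq_len(30 * fs) / fs
                         rnorm(30 * fs, sd = 0.5) +
                           amp20[i] * sin(2 * pi * 20 * t)
                       })
  for (i in seq_len(n)) es$epochs[[i]]$stage <- stages[i]

  out <- exclude_artifacts(es, band = c(19, 21), percentile = 0.95)
  kept <- vapply(out$epochs, function(e) e$index, integer(1))

  # all 8 movement/transitional epochs removed first
  expect_false(any((c(3, 17, 30, 44, 58, 71, 85, 99) - 1L) %in% kept))
  # then floor(96 * 0.05) = 4 removed by threshold
  expect_length(kept, 96L - 4L)

  # brute-force oracle: the removed clean epochs are exactly the top-4 by
  # 20 Hz amplitude (amplitude ordering implies band-power ordering)
  top4 <- clean_idx[order(amp20[clean_idx], decreasing = TRUE)[1:4]] - 1L
  expect_setequal(setdiff(clean_idx - 1L, kept), top4)

  # idempotence on its own output
  out2 <- exclude_artifacts(out, band = c(19, 21), percentile = 0.95)
  expect_equal(length(out2$epochs), length(out$epochs))

  expect_error(exclude_artifacts(structure(list(epochs = list(),
                                                montage = "C3", fs = fs,
                                                provenance = character(0)),
                                           class = "epoch_set")),
               "empty")
})

test_that("exact top-fraction count: 100 clean epochs at 0.95 lose exactly 5", {
  fs <- 125
  set.seed(13)
  es <- make_epoch_set(100, fs = fs, channels = c("F3", "C3"),
                       gen = function(i, ch) rnorm(30 * fs))
  out <- exclude_artifacts(es, percentile = 0.95)
  expect_length(out$epochs, 95L)
})

test_that("the full preprocessing chain logs its fixed stage order", {
  rec <- generate_recording("S01", default_session_specs()$week5,
                            duration_min = 2, seed = 77, movement_rate = 0)
  es <- preprocess_recording(rec)
  expect_s3_class(es, "epoch_set")
  prov <- paste(es$provenance, collapse = " -> ")
  expect_match(prov, "downsample.*montage.*bandpass.*epoch.*exclude")
  expect_true(all(vapply(es$epochs, function(e)
    e$stage %in% c("NREM", "REM", "WAKE"), logical(1))))
})
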