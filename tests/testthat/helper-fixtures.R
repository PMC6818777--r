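# Shared fixtures, built lazily once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# cohort MSPE feature table used by several unit tests: 3 subjects,
# two sessions, 10 min each (20 epochs/recording before exclusions)
small_cohort_features <- function() {
  cached_fixture("small_features", {
    feats <- list()
    sspecs <- default_session_specs()
    for (subj in 1:3) {
      for (sess in names(sspecs)) {
        rec <- generate_recording(sprintf("S%02d", subj), sspecs[[sess]],
                                  duration_min = 10,
                                  seed = 500L + 100L * subj +
                                    match(sess, names(sspecs)))
        es <- preprocess_recording(rec)
        feats[[length(feats) + 1L]] <- mspe_features(es)
      }
    }
    info <- attr(feats[[1]], "feature_info")
    out <- do.call(rbind, feats)
    attr(out, "feature_info") <- info
    out
  })
}

# the default study-scale cohort (6 subjects, 30 min/session) used by the
# structure-recovery and chance-level acceptance checks
demo_cohort_features <- function(seed = 20L) {
  cached_fixture(paste0("demo_features_", seed), {
    feats <- list()
    sspecs <- default_session_specs()
    for (subj in 1:6) {
      for (sess in names(sspecs)) {
        rec <- generate_recording(sprintf("S%02d", subj), sspecs[[sess]],
                                  duration_min = 30,
                                  seed = seed + 1000L * subj +
                                    match(sess, names(sspecs)))
        es <- preprocess_recording(rec)
        feats[[length(feats) + 1L]] <- mspe_features(es)
      }
    }
    info <- attr(feats[[1]], "feature_info")
    out <- do.call(rbind, feats)
    attr(out, "feature_info") <- info
    out
  })
}

# independent naive oracle: enumerate ordinal patterns by an explicit
# double loop with the same tie rule (earlier sample ranks lower)
naive_pattern_counts <- function(x, m, tau) {
  perms <- neosleep:::.rank_permutations(m)
  keys <- apply(perms, 1L, paste0, collapse = "")
  counts <- setNames(integer(length(keys)), keys)
  n <- length(x) - (m - 1L) * tau
  for (t in seq_len(n)) {
    w <- x[t + (0:(m - 1L)) * tau]
    r <- integer(m)
    for (j in seq_len(m)) {
      for (i in seq_len(m)) {
        if (i == j) next
        if (w[i] < w[j] || (w[i] == w[j] && i < j)) r[j] <- r[j] + 1L
      }
    }
    key <- paste0(r, collapse = "")
    counts[key] <- counts[key] + 1L
  }
  counts
}

# well-separated 3-class feature table for staging unit tests:
# class means differ along a few columns, subjects tagged round-robin
toy_features <- function(n_per_class = 60, n_subjects = 6, p = 8,
                         sep = 3, seed = 7, session = "week5") {
  set.seed(seed)
  stages <- rep(c("NREM", "REM", "WAKE"), each = n_per_class)
  mu <- matrix(0, nrow = 3, ncol = p)
  mu[1, 1:2] <- sep
  mu[2, 3:4] <- sep
  mu[3, 5:6] <- sep
  x <- t(vapply(seq_along(stages), function(i) {
    mu[match(stages[i], c("NREM", "REM", "WAKE")), ] + rnorm(p)
  }, numeric(p)))
  colnames(x) <- paste0("f", seq_len(p))
  df <- data.frame(
    subject = sprintf("S%02d", rep_len(seq_len(n_subjects), length(stages))),
    session = session,
    epoch = seq_along(stages) - 1L,
    stage = stages,
    stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(x))
}

# quick epoch_set builder around a signal-generating function
make_epoch_set <- function(n_epochs, fs = 125, epoch_s = 30,
                           channels = psg_montage(),
                           stage = "REM",
                           gen = function(i, ch) rnorm(fs * epoch_s)) {
  stages <- rep_len(stage, n_epochs)
  epochs <- lapply(seq_len(n_epochs), function(i) {
    sig <- t(vapply(channels, function(ch) gen(i, ch), numeric(fs * epoch_s)))
    rownames(sig) <- channels
    list(subject = "S01", session = "week5", index = i - 1L,
         stage = stages[i], signal = sig, fs = fs)
  })
  structure(list(epochs = epochs, montage = channels, fs = fs,
                 provenance = character(0)),
            class = "epoch_set")
}
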