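#' Ordinal pattern distribution of a signal
#'
#' Slides a window of `m` samples (spaced `tau` apart) along `x` and, for each
#' window, identifies the rank-order (ordinal) pattern of its values. With
#' embedding order `m = 3` there are `3! = 6` possible patterns. Ties between
#' equal sample values are broken by temporal order: the earlier sample is
#' assigned the lower rank. This matters for quantized EEG where exact value
#' ties occur.
#'
#' Patterns are indexed `0 ... m!-1` in lexicographic order of their rank
#' sequence: for `m = 3` pattern 0 is ranks `(0,1,2)` (ascending), pattern 5 is
#' `(2,1,0)` (descending).
#'
#' @param x numeric vector, the signal.
#' @param m integer embedding order (window length), `m >= 2`.
#' @param tau integer lag between window samples, in samples.
#' @return An object of class `ordinal_pattern_distribution`: a list with
#'   `counts` (named integer vector of length `m!`, names are rank sequences
#'   such as `"012"`), `m`, `tau` and `n_patterns` (number of windows).
#' @examples
#' ordinal_patterns(c(1, 2, 3, 4), m = 3, tau = 1)
#' @export
ordinal_patterns <- function(x, m = 3L, tau = 1L) {
  m <- as.integer(m)
  tau <- as.integer(tau)
  if (m < 2L) stop("embedding order m must be at least 2")
  if (tau < 1L) stop("lag tau must be at least 1")
  n <- length(x) - (m - 1L) * tau
  if (n < 1L) stop("signal too short: need at least (m-1)*tau + 1 samples")

  # windows as columns of an n x m matrix (no copy loops over windows)
  idx <- outer(seq_len(n), (0:(m - 1L)) * tau, `+`)
  w <- matrix(x[idx], nrow = n, ncol = m)

  # stable rank of element j within each window: number of elements that are
  # strictly smaller, or equal but earlier in time
  ranks <- matrix(0L, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    r <- integer(n)
    for (i in seq_len(m)) {
      if (i == j) next
      if (i < j) r <- r + (w[, i] <= w[, j]) else r <- r + (w[, i] < w[, j])
    }
    ranks[, j] <- r
  }

  # base-m encoding of the rank sequence, mapped to lexicographic pattern ids
  code <- as.vector(ranks %*% m^((m - 1L):0))
  perms <- .rank_permutations(m)
  perm_codes <- as.vector(perms %*% m^((m - 1L):0))
  pattern_names <- apply(perms, 1L, paste0, collapse = "")
  counts <- tabulate(match(code, perm_codes), nbins = nrow(perms))
  names(counts) <- pattern_names

  structure(
    list(counts = counts, m = m, tau = tau, n_patterns = n),
    class = "ordinal_pattern_distribution"
  )
}

# all permutations of 0..m-1 in lexicographic order, one per row
.rank_permutations <- function(m) {
  if (m == 1L) return(matrix(0L, 1L, 1L))
  sub <- .rank_permutations(m - 1L)
  out <- matrix(0L, nrow = factorial(m), ncol = m)
  row <- 1L
  for (first in 0:(m - 1L)) {
    rest <- setdiff(0:(m - 1L), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ] + 1L])
      row <- row + 1L
    }
  }
  out
}

#' @export
print.ordinal_pattern_distribution <- function(x, ...) {
  cat(sprintf(
    "Ordinal pattern distribution: m = %d (%d patterns), tau = %d, %d windows\n",
    x$m, factorial(x$m), x$tau, x$n_patterns
  ))
  print(x$counts)
  invisible(x)
}

#' Permutation entropy of an ordinal pattern distribution
#'
#' Shannon entropy (in nats) of the relative pattern frequencies:
#' `H = -sum(p_i * log(p_i))` with `p_i = count_i / n_patterns`; zero-count
#' patterns contribute nothing. `H` lies in `[0, log(m!)]`: 0 for a signal
#' showing a single pattern (e.g. a monotone ramp), `log(m!)` when all
#' patterns are equally frequent.
#'
#' @param dist an [ordinal_patterns()] result, or a bare vector of counts.
#' @param normalized if `TRUE`, divide by `log(m!)` so the result is in
#'   `[0, 1]`. Default `FALSE` (raw nats).
#' @return entropy in nats (scalar).
#' @examples
#' permutation_entropy(ordinal_patterns(sin(1:100), m = 3))
#' @export
permutation_entropy <- function(dist, normalized = FALSE) {
  counts <- if (inherits(dist, "ordinal_pattern_distribution")) dist$counts else dist
  if (length(counts) == 0L || sum(counts) == 0) stop("empty pattern distribution")
  p <- counts[counts > 0] / sum(counts)
  h <- -sum(p * log(p))
  if (normalized) h <- h / log(length(counts))
  h
}

#' Coarse-grain a signal by non-overlapping window averaging
#'
#' Replaces the signal by the means of consecutive non-overlapping windows of
#' `s` samples. Like low-pass filtering, this removes fluctuations faster than
#' the window, so entropy computed on the coarse-grained signal reflects
#' slower time scales. Trailing samples that do not fill a window are dropped.
#'
#' @param x numeric vector.
#' @param s integer scale (window length in samples); `s = 1` returns `x`.
#' @return numeric vector of length `floor(length(x) / s)`.
#' @examples
#' coarse_grain(c(2, 4, 6, 8), 2) # c(3, 7)
#' @export
coarse_grain <- function(x, s) {
  s <- as.integer(s)
  if (s < 1L) stop("scale must be a positive integer")
  if (s == 1L) return(x)
  n <- (length(x) %/% s) * s
  if (n < s) stop("signal shorter than one coarse-graining window")
  colMeans(matrix(x[seq_len(n)], nrow = s))
}

#' Multi-scale permutation entropy of a multi-channel epoch
#'
#' Computes permutation entropy for every channel at every coarse-graining
#' scale `1 ... S`. With the 11-channel PSG montage and 5 scales this yields
#' the 55-dimensional per-epoch feature vector used for sleep staging. The
#' flattened order is channel-major: all scales of channel 1, then channel 2,
#' and so on; names are `<channel>_s<scale>`.
#'
#' Permutation entropy operates on the order of values, not their amplitude,
#' so the result is invariant under any strictly increasing transformation of
#' the signal (scaling, offset).
#'
#' @param epoch a numeric channels-x-samples matrix with channel rownames, or
#'   an `epoch` object from [epoch_recording()].
#' @param m,tau embedding order and lag, see [ordinal_patterns()].
#' @param scales integer vector of coarse-graining scales, default `1:5`.
#' @param normalized passed to [permutation_entropy()].
#' @return An `mspe_vector`: a named numeric vector (length
#'   `n_channels * length(scales)`) with attributes `channels` and `scales`.
#' @examples
#' x <- matrix(rnorm(2 * 500), 2, dimnames = list(c("F3", "F4"), NULL))
#' mspe(x, scales = 1:5)
#' @export
mspe <- function(epoch, m = 3L, tau = 1L, scales = 1:5, normalized = FALSE) {
  sig <- if (is.list(epoch) && !is.null(epoch$signal)) epoch$signal else epoch
  if (!is.matrix(sig)) stop("epoch must be a channels x samples matrix")
  channels <- rownames(sig)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(sig)))
  max_s <- max(scales)
  if (ncol(sig) %/% max_s < (m - 1L) * tau + 1L) {
    stop("epoch too short at the largest coarse-graining scale")
  }
  vals <- numeric(length(channels) * length(scales))
  nm <- character(length(vals))
  k <- 1L
  for (c_i in seq_along(channels)) {
    xc <- sig[c_i, ]
    for (s in scales) {
      vals[k] <- permutation_entropy(
        ordinal_patterns(coarse_grain(xc, s), m = m, tau = tau),
        normalized = normalized
      )
      nm[k] <- sprintf("%s_s%d", channels[c_i], s)
      k <- k + 1L
    }
  }
  names(vals) <- nm
  structure(vals,
    channels = channels, scales = as.integer(scales),
    class = c("mspe_vector", "numeric")
  )
}

#' Per-epoch MSPE feature table for an epoch set
#'
#' Applies [mspe()] to every epoch and assembles a data frame with one row per
#' epoch: metadata columns `subject`, `session`, `epoch`, `stage` followed by
#' the `<channel>_s<scale>` feature columns (channel-major order).
#'
#' @param epoch_set an [epoch_recording()] / [exclude_artifacts()] result.
#' @inheritParams mspe
#' @return data frame; attribute `feature_info` maps each feature column to
#'   its channel and scale (used by [channel_importance()]).
#' @export
mspe_features <- function(epoch_set, m = 3L, tau = 1L, scales = 1:5,
                          normalized = FALSE) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  feats <- lapply(epoch_set$epochs, function(ep) {
    as.numeric(mspe(ep$signal, m = m, tau = tau, scales = scales,
                    normalized = normalized))
  })
  channels <- epoch_set$montage
  cols <- as.vector(t(outer(channels, scales,
                            function(ch, s) sprintf("%s_s%d", ch, s))))
  .feature_table(epoch_set, feats, cols,
                 data.frame(feature = cols,
                            channel = rep(channels, each = length(scales)),
                            scale = rep(as.integer(scales), length(channels)),
                            stringsAsFactors = FALSE))
}

# shared assembly for mspe_features / psd_features
.feature_table <- function(epoch_set, feats, cols, info) {
  meta <- data.frame(
    subject = vapply(epoch_set$epochs, function(e) e$subject, character(1)),
    session = vapply(epoch_set$epochs, function(e) e$session, character(1)),
    epoch = vapply(epoch_set$epochs, function(e) e$index, integer(1)),
    stage = vapply(epoch_set$epochs, function(e) e$stage, character(1)),
    stringsAsFactors = FALSE
  )
  fm <- do.call(rbind, feats)
  if (is.null(fm)) fm <- matrix(numeric(0), 0L, length(cols))
  colnames(fm) <- cols
  out <- cbind(meta, as.data.frame(fm, optional = TRUE))
  attr(out, "feature_info") <- info
  out
}

#' Feature columns of a feature table
#'
#' Helper returning the names of the numeric feature columns (everything past
#' the `subject`/`session`/`epoch`/`stage` metadata).
#' @param features a data frame from [mspe_features()] or [psd_features()].
#' @return character vector of column names.
#' @export
feature_columns <- function(features) {
  setdiff(colnames(features), c("subject", "session", "epoch", "stage"))
}
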