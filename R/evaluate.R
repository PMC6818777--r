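#' Build a 3x3 confusion matrix
#'
#' Rows are the human (visual) labels, columns the classifier predictions,
#' in the fixed class order NREM, REM, WAKE.
#'
#' @param actual,predicted character/factor stage vectors of equal length.
#' @param classes class order (default NREM, REM, WAKE).
#' @return integer matrix with class dimnames.
#' @export
confusion_matrix <- function(actual, predicted, classes = .stages()) {
  tab <- table(factor(actual, levels = classes),
               factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(actual = classes, predicted = classes))
  m
}

#' Performance metrics from a confusion matrix
#'
#' Accuracy is the trace over the total count. Per class: precision (positive
#' predictive value) is the diagonal over the column sum, recall
#' (sensitivity) the diagonal over the row sum, and F1 their harmonic mean
#' `2PR/(P+R)`. A zero denominator yields a metric of 0 and the class is
#' listed in the `zero_division` flag, keeping the output machine-readable.
#'
#' The identity `sum_c recall_c * rowsum_c / total == accuracy` holds for
#' every confusion matrix.
#'
#' @param cm square count matrix (rows actual, columns predicted).
#' @return list with `accuracy`, `precision`, `recall`, `f1` (named per
#'   class) and `zero_division` (character vector of flagged classes).
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (any(cm < 0)) stop("confusion matrix counts must be non-negative")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(cm)))
  d <- diag(cm)
  col_s <- colSums(cm)
  row_s <- rowSums(cm)
  flagged <- character(0)
  safe_div <- function(num, den, what) {
    out <- numeric(length(num))
    for (i in seq_along(num)) {
      if (den[i] == 0) {
        out[i] <- 0
        flagged <<- union(flagged, paste0(what, ":", classes[i]))
      } else {
        out[i] <- num[i] / den[i]
      }
    }
    setNames(out, classes)
  }
  precision <- safe_div(d, col_s, "precision")
  recall <- safe_div(d, row_s, "recall")
  f1 <- setNames(numeric(length(classes)), classes)
  for (i in seq_along(classes)) {
    s <- precision[i] + recall[i]
    if (s == 0) {
      f1[i] <- 0
      flagged <- union(flagged, paste0("f1:", classes[i]))
    } else {
      f1[i] <- 2 * precision[i] * recall[i] / s
    }
  }
  list(accuracy = sum(d) / total, precision = precision, recall = recall,
       f1 = f1, zero_division = flagged)
}

.locations <- function() {
  list(frontal = c("F3", "F4"), central = c("C3", "C4"),
       occipital = c("O1", "O2"))
}

#' Bootstrap state-level entropy cell means
#'
#' For every (subject, session, stage, location, scale) cell the epoch-level
#' entropy values (the location's channel pair averaged per epoch) are
#' resampled with replacement `n_draws` times in samples of `draw_size`,
#' each sample is averaged, and the draw means are averaged again. This
#' yields one value per cell per subject regardless of how many epochs the
#' subject has in that state, equalizing observations across subjects and
#' stages. Cells with no epochs are flagged missing, not imputed.
#'
#' @param features an MSPE feature table ([mspe_features()]).
#' @param scales scales to summarize (default `c(1, 5)`, the fast and slow
#'   analysis scales).
#' @param draw_size bootstrap sample size (default 10).
#' @param n_draws number of bootstrap draws (default 1000).
#' @param seed integer.
#' @return a `bootstrap_summary`: list with `cells` (data frame `subject`,
#'   `session`, `stage`, `location`, `scale`, `value`, `n_epochs`),
#'   `missing` (cells without epochs), `draw_size`, `n_draws`, `seed`.
#' @export
bootstrap_cell_means <- function(features, scales = c(1, 5), draw_size = 10,
                                 n_draws = 1000, seed = 1L) {
  if (draw_size < 1) stop("draw_size must be at least 1")
  info <- attr(features, "feature_info")
  if (is.null(info) || !"scale" %in% colnames(info)) {
    stop("features must be an MSPE feature table with feature_info metadata")
  }
  locs <- .locations()
  set.seed(as.integer(seed))
  subjects <- unique(features$subject)
  sessions <- unique(features$session)
  rows <- list()
  missing <- list()
  for (subj in subjects) for (sess in sessions) for (stg in .stages()) {
    sel <- features$subject == subj & features$session == sess &
      features$stage == stg
    for (loc in names(locs)) for (sc in scales) {
      cols <- info$feature[info$channel %in% locs[[loc]] & info$scale == sc]
      if (!any(sel)) {
        missing[[length(missing) + 1L]] <-
          data.frame(subject = subj, session = sess, stage = stg,
                     location = loc, scale = sc)
        next
      }
      vals <- rowMeans(features[sel, cols, drop = FALSE])
      draws <- vapply(seq_len(n_draws), function(d) {
        mean(vals[sample.int(length(vals), draw_size, replace = TRUE)])
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(subject = subj, session = sess, stage = stg,
                   location = loc, scale = sc, value = mean(draws),
                   n_epochs = length(vals))
    }
  }
  structure(list(cells = do.call(rbind, rows),
                 missing = if (length(missing)) do.call(rbind, missing) else NULL,
                 draw_size = draw_size, n_draws = n_draws,
                 seed = as.integer(seed)),
            class = "bootstrap_summary")
}

#' Aggregate random-forest feature importances by channel
#'
#' Sums the forest's normalized per-feature importances over each channel's
#' features (its five entropy scales, or its thirty frequency bins), giving
#' a per-channel contribution that sums to 1.
#'
#' @param fit a [fit_stager()] result (or a bare `ranger` model).
#' @param feature_info data frame mapping `feature` to `channel` (the
#'   `feature_info` attribute of a feature table).
#' @return named numeric vector, one importance per channel, sorted
#'   decreasing.
#' @export
channel_importance <- function(fit, feature_info) {
  model <- if (inherits(fit, "ranger")) fit else fit$model
  imp <- ranger::importance(model)
  if (!setequal(names(imp), feature_info$feature)) {
    stop("feature metadata does not match the model's features")
  }
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  ch <- feature_info$channel[match(names(imp), feature_info$feature)]
  out <- vapply(split(imp, ch), sum, numeric(1))
  sort(out, decreasing = TRUE)
}

#' Export the bootstrap summary as a long-format statistics table
#'
#' One row per available (subject, session, stage, location, scale) cell,
#' the exact input a linear mixed model of state-level entropy consumes.
#' Missing cells are omitted (their count is reported as an attribute).
#' Written/read as plain CSV; the round trip is lossless.
#'
#' @param summary a [bootstrap_cell_means()] result.
#' @param file optional path; when given the table is also written as CSV.
#' @return data frame `subject, session, stage, location, scale, value`.
#' @export
export_stats_table <- function(summary, file = NULL) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  tab <- summary$cells[, c("subject", "session", "stage", "location",
                           "scale", "value")]
  rownames(tab) <- NULL
  attr(tab, "n_missing_cells") <- if (is.null(summary$missing)) 0L else
    nrow(summary$missing)
  if (!is.null(file)) {
    write.csv(tab, file, row.names = FALSE)
  }
  tab
}

#' Read back an exported statistics table
#' @param file CSV path written by [export_stats_table()].
#' @return data frame with the same columns and types.
#' @export
read_stats_table <- function(file) {
  read.csv(file, stringsAsFactors = FALSE)
}
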