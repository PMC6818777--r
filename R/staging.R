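#' Cross-validation scheme descriptor
#'
#' Subject-level repeated two-fold cross-validation, run either within one
#' recording session (train and test subjects of the same age) or across
#' sessions (train on one age group, test on the other). In both modes a
#' subject's data never appears in both the training and the testing set.
#'
#' @param mode `"within"` or `"cross"`.
#' @param train_session,test_session `"week2"` or `"week5"`; within-session
#'   schemes require them equal, cross-session schemes different.
#' @param n_repetitions number of repeated subject splits (default 20).
#' @param seed integer RNG seed for splits and under-sampling.
#' @return a `cv_scheme` list.
#' @export
cv_scheme <- function(mode = c("within", "cross"),
                      train_session = "week2",
                      test_session = train_session,
                      n_repetitions = 20, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "within" && train_session != test_session) {
    stop("within-session scheme requires train_session == test_session")
  }
  if (mode == "cross" && train_session == test_session) {
    stop("cross-session scheme requires different sessions")
  }
  structure(list(mode = mode, train_session = train_session,
                 test_session = test_session,
                 n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Split subjects into two disjoint halves
#'
#' Random halving for two-fold subject-level cross-validation; with an odd
#' number of subjects the training half gets the extra subject. The split is
#' deterministic under `seed`.
#'
#' @param subject_ids character vector of unique subject ids (>= 2).
#' @param seed integer.
#' @return list with `train` and `test` character vectors.
#' @export
split_subjects <- function(subject_ids, seed = 1L) {
  subject_ids <- unique(subject_ids)
  n <- length(subject_ids)
  if (n < 2) stop("need at least 2 subjects to split")
  set.seed(as.integer(seed))
  perm <- sample(subject_ids)
  n_test <- n %/% 2L
  list(train = sort(perm[seq_len(n - n_test)]),
       test = sort(perm[(n - n_test + 1L):n]))
}

#' Random under-sampling to balance sleep classes
#'
#' Downsamples every class, without replacement, to the minority-class count
#' so that all three stages are equally represented (applied to both training
#' and testing sets in the staging pipeline). Original row order is
#' preserved among kept epochs.
#'
#' @param features feature table (rows = epochs) with a `stage` column.
#' @param seed integer.
#' @param classes stages that must all be present (default NREM, REM, WAKE).
#' @return the row-subset feature table with equal class counts.
#' @export
undersample <- function(features, seed = 1L, classes = .stages()) {
  counts <- table(factor(features$stage, levels = classes))
  absent <- names(counts)[counts == 0]
  if (length(absent)) stop(paste(absent, collapse = ", "), " absent")
  m <- min(counts)
  set.seed(as.integer(seed))
  keep <- unlist(lapply(classes, function(cl) {
    idx <- which(features$stage == cl)
    if (length(idx) > m) sort(sample(idx, m)) else idx
  }))
  features[sort(keep), , drop = FALSE]
}

#' Fit the random-forest stager
#'
#' Trains a random-forest classifier on a balanced feature table. When the
#' hyper-parameter grid has more than one row, each candidate is scored by
#' k-fold cross-validated accuracy inside the training set and the best
#' (first on ties) is refit on the full training data. The fitted forest
#' exposes impurity-based per-feature importances.
#'
#' @param features numeric feature matrix or the feature table (metadata
#'   columns are dropped automatically).
#' @param labels factor/character stage labels aligned with rows.
#' @param hyper_grid data frame of candidate settings with columns
#'   `num_trees`, `max_depth` (0 = unlimited) and `mtry_frac` (`NA` = sqrt);
#'   see [default_hyper_grid()].
#' @param inner_folds folds for the inner CV (default 3).
#' @param seed integer.
#' @return list with `model` (a `ranger` fit), `hyper` (selected row),
#'   `inner_accuracy` (per-candidate inner CV accuracy, `NA` if skipped) and
#'   `feature_names`.
#' @export
fit_stager <- function(features, labels, hyper_grid = default_hyper_grid(),
                       inner_folds = 3, seed = 1L) {
  x <- .feature_matrix(features)
  y <- factor(labels)
  if (nrow(x) != length(y)) stop("features and labels are misaligned")
  const <- apply(x, 2L, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    message(sum(const), " constant feature column(s) retained: ",
            paste(colnames(x)[const][seq_len(min(3, sum(const)))], collapse = ", "))
  }
  inner_acc <- rep(NA_real_, nrow(hyper_grid))
  best <- 1L
  if (nrow(hyper_grid) > 1L) {
    set.seed(as.integer(seed))
    fold <- sample(rep_len(seq_len(inner_folds), nrow(x)))
    for (g in seq_len(nrow(hyper_grid))) {
      acc <- numeric(inner_folds)
      for (f in seq_len(inner_folds)) {
        fit <- .fit_ranger(x[fold != f, , drop = FALSE], y[fold != f],
                           hyper_grid[g, ], seed = seed + g)
        pred <- stats::predict(fit,
                               data = as.data.frame(x[fold == f, , drop = FALSE]))
        acc[f] <- mean(pred$predictions == y[fold == f])
      }
      inner_acc[g] <- mean(acc)
    }
    best <- which.max(inner_acc)
  }
  model <- .fit_ranger(x, y, hyper_grid[best, ], seed = seed)
  list(model = model, hyper = hyper_grid[best, , drop = FALSE],
       inner_accuracy = inner_acc, feature_names = colnames(x))
}

#' Default random-forest hyper-parameter grid
#'
#' Trees in {100, 300}, depth in {unlimited, 8}, features per split in
#' {sqrt(p), 0.3 p}: a small standard grid searched by inner cross-validated
#' accuracy.
#' @return data frame with one row per candidate.
#' @export
default_hyper_grid <- function() {
  expand.grid(num_trees = c(100L, 300L), max_depth = c(0L, 8L),
              mtry_frac = c(NA_real_, 0.3))
}

.fit_ranger <- function(x, y, hp, seed) {
  p <- ncol(x)
  mtry <- if (is.na(hp$mtry_frac)) max(1L, floor(sqrt(p))) else
    max(1L, floor(hp$mtry_frac * p))
  ranger::ranger(x = as.data.frame(x), y = y,
                 num.trees = hp$num_trees,
                 max.depth = if (hp$max_depth == 0L) NULL else hp$max_depth,
                 mtry = mtry, importance = "impurity",
                 seed = as.integer(seed) %% .Machine$integer.max,
                 num.threads = 1L)
}

.feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    as.matrix(features[, feature_columns(features), drop = FALSE])
  } else {
    as.matrix(features)
  }
}

#' Run repeated two-fold subject-level cross-validation
#'
#' For each repetition the subject set is split into two disjoint halves and
#' both halves serve once as the test fold. Training epochs come from the
#' scheme's train session, test epochs from its test session; in
#' cross-session mode the halves additionally guarantee that no subject
#' contributes to both sets in either session. Train and test sets are both
#' class-balanced by random under-sampling before fitting and scoring (a
#' flag restores unbalanced-test evaluation for real-world use).
#'
#' @param features feature table from [mspe_features()] or [psd_features()]
#'   covering all epochs of the cohort.
#' @param scheme a [cv_scheme()].
#' @param hyper_grid forest hyper-parameter candidates; a single row skips
#'   the inner search.
#' @param balance_test under-sample the test set too (default `TRUE`).
#' @param labels optional replacement stage labels (same length/order as
#'   `features` rows), used for shuffled-label chance runs.
#' @param classes class set (default NREM/REM/WAKE); all must be present in
#'   both halves of a fold for it to be evaluable.
#' @return a `cv_result`: list with `scheme`, `folds` (per-fold list of
#'   `accuracy`, `f1`, `confusion`, fold metadata), `median_accuracy`,
#'   `median_f1` (per class), `pooled_confusion` and `skipped` (folds where
#'   a random subject half lacked a class entirely and could not be
#'   balanced; they are excluded from the medians).
#' @export
run_cv <- function(features, scheme, hyper_grid = default_hyper_grid(),
                   balance_test = TRUE, labels = NULL, classes = .stages()) {
  stopifnot(inherits(scheme, "cv_scheme"))
  if (!is.null(labels)) features$stage <- as.character(labels)
  sessions <- unique(features$session)
  for (s in c(scheme$train_session, scheme$test_session)) {
    if (!s %in% sessions) stop("scheme session '", s, "' not present in data")
  }
  subjects <- sort(unique(features$subject))
  folds <- list()
  skipped <- character(0)
  for (rep_i in seq_len(scheme$n_repetitions)) {
    sp <- split_subjects(subjects, seed = scheme$seed + 7919L * rep_i)
    for (half in 1:2) {
      train_ids <- if (half == 1) sp$train else sp$test
      test_ids <- setdiff(subjects, train_ids)
      stopifnot(length(intersect(train_ids, test_ids)) == 0)
      tr <- features[features$subject %in% train_ids &
                       features$session == scheme$train_session, , drop = FALSE]
      te <- features[features$subject %in% test_ids &
                       features$session == scheme$test_session, , drop = FALSE]
      missing_cl <- union(
        setdiff(classes, unique(tr$stage)),
        setdiff(classes, unique(te$stage))
      )
      if (length(missing_cl)) {
        # a sparse class (typically NREM in young subjects) can be absent
        # from a random subject half; the fold cannot be balanced and is
        # skipped, recorded, and excluded from the medians
        skipped <- c(skipped, sprintf("rep %d fold %d: %s absent", rep_i,
                                      half, paste(missing_cl, collapse = "/")))
        next
      }
      us_seed <- scheme$seed + 104729L * rep_i + half
      tr <- undersample(tr, seed = us_seed, classes = classes)
      if (balance_test) te <- undersample(te, seed = us_seed + 1L,
                                          classes = classes)
      fit <- fit_stager(tr, tr$stage, hyper_grid = hyper_grid,
                        seed = us_seed + 2L)
      pred <- stats::predict(fit$model,
                             data = as.data.frame(.feature_matrix(te)))
      cm <- confusion_matrix(te$stage, as.character(pred$predictions),
                             classes = classes)
      met <- metrics_from_confusion(cm)
      folds[[length(folds) + 1L]] <- list(
        repetition = rep_i, fold = half,
        train_subjects = train_ids, test_subjects = test_ids,
        accuracy = met$accuracy, f1 = met$f1, confusion = cm
      )
    }
  }
  if (!length(folds)) stop("no evaluable folds: every split lacked a class")
  if (length(skipped)) {
    warning(length(skipped), " fold(s) skipped (class absent): ",
            paste(utils::head(skipped, 3), collapse = "; "))
  }
  acc <- vapply(folds, function(f) f$accuracy, numeric(1))
  f1m <- do.call(rbind, lapply(folds, function(f) f$f1))
  pooled <- Reduce(`+`, lapply(folds, function(f) f$confusion))
  structure(list(scheme = scheme, folds = folds,
                 accuracies = acc,
                 median_accuracy = median(acc),
                 median_f1 = apply(f1m, 2L, median),
                 pooled_confusion = pooled,
                 skipped = skipped),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "CV result (%s: train %s, test %s): %d folds, median accuracy %.3f\n",
    x$scheme$mode, x$scheme$train_session, x$scheme$test_session,
    length(x$folds), x$median_accuracy
  ))
  cat("median F1:", paste(sprintf("%s %.3f", names(x$median_f1), x$median_f1),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Empirical chance level by label shuffling
#'
#' Permutes the epoch stage labels globally (a new permutation per shuffle)
#' and reruns the full cross-validation pipeline, returning the null
#' distribution of fold accuracies. With three balanced classes its mean is
#' close to 1/3; an observed accuracy is compared against this distribution.
#'
#' @param features feature table.
#' @param scheme a [cv_scheme()]; for the null, `n_repetitions = 1` per
#'   shuffle is customary (the shuffles themselves provide replication).
#' @param n_shuffles number of label permutations (default 100).
#' @param hyper_grid forest settings for the null runs; defaults to a single
#'   fixed configuration (300 trees) since chance is insensitive to tuning.
#' @param ... passed to [run_cv()] (e.g. `classes`).
#' @return list with `accuracies` (one per shuffle, mean over that shuffle's
#'   folds), `fold_accuracies` (all folds), `mean` and `n_shuffles`.
#' @export
estimate_chance <- function(features, scheme, n_shuffles = 100,
                            hyper_grid = data.frame(num_trees = 300L,
                                                    max_depth = 0L,
                                                    mtry_frac = NA_real_),
                            ...) {
  if (n_shuffles < 1) stop("n_shuffles must be at least 1")
  acc <- numeric(n_shuffles)
  fold_acc <- list()
  for (s in seq_len(n_shuffles)) {
    set.seed(scheme$seed + 15485863L %% 1000000L + s)
    shuffled <- sample(features$stage)
    sc <- scheme
    sc$seed <- scheme$seed + 31L * s
    res <- run_cv(features, sc, hyper_grid = hyper_grid, labels = shuffled,
                  ...)
    acc[s] <- mean(res$accuracies)
    fold_acc[[s]] <- res$accuracies
  }
  list(accuracies = acc, fold_accuracies = unlist(fold_acc),
       mean = mean(acc), n_shuffles = n_shuffles)
}
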