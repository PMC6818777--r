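test_that("confusion-matrix metrics match hand-computed values", {
  # perfect diagonal
  cm <- diag(c(10L, 10L, 10L))
  dimnames(cm) <- list(actual = c("NREM", "REM", "WAKE"),
                       predicted = c("NREM", "REM", "WAKE"))
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 1)
  expect_equal(unname(m$f1), rep(1, 3))
  expect_length(m$zero_division, 0L)

  # hand computation from the precision/recall/F1 definitions
  cm2 <- matrix(c(8, 2, 0,
                  1, 9, 0,
                  0, 5, 5), nrow = 3, byrow = TRUE,
                dimnames = list(actual = c("NREM", "REM", "WAKE"),
                                predicted = c("NREM", "REM", "WAKE")))
  m2 <- metrics_from_confusion(cm2)
  expect_equal(m2$accuracy, 22 / 30, tolerance = 1e-12)
  # WAKE: precision 5/5 = 1, recall 5/10 = 0.5, F1 = 2*1*0.5/1.5
  expect_equal(unname(m2$f1["WAKE"]), 2 * 1 * 0.5 / 1.5, tolerance = 1e-9)
  expect_equal(unname(m2$precision["WAKE"]), 1)
  expect_equal(unname(m2$recall["WAKE"]), 0.5)

  expect_error(metrics_from_confusion(matrix(-1, 2, 2)), "non-negative")
  expect_error(metrics_from_confusion(matrix(0, 3, 3)), "empty")
})

test_that("zero-division metrics are reported as 0 with a flag", {
  # no epoch ever predicted WAKE: its precision denominator is 0
  cm <- matrix(c(10, 0, 0,
                 2, 8, 0,
                 3, 7, 0), nrow = 3, byrow = TRUE,
               dimnames = list(actual = c("NREM", "REM", "WAKE"),
                               predicted = c("NREM", "REM", "WAKE")))
  m <- metrics_from_confusion(cm)
  expect_equal(unname(m$precision["WAKE"]), 0)
  expect_equal(unname(m$f1["WAKE"]), 0)
  expect_true(any(grepl("WAKE", m$zero_division)))
})

test_that("recall weighted by row sums reproduces accuracy exactly", {
  set.seed(19)
  for (i in 1:20) {
    cm <- matrix(rpois(9, lambda = sample(3:30, 1)), nrow = 3,
                 dimnames = list(actual = c("NREM", "REM", "WAKE"),
                                 predicted = c("NREM", "REM", "WAKE")))
    if (sum(cm) == 0) next
    m <- metrics_from_confusion(cm)
    expect_equal(sum(m$recall * rowSums(cm)) / sum(cm), m$accuracy,
                 tolerance = 1e-12)
  }
})

test_that("confusion_matrix builds counts in the fixed class order", {
  cm <- confusion_matrix(c("NREM", "REM", "REM", "WAKE"),
                         c("NREM", "REM", "WAKE", "WAKE"))
  expect_equal(rownames(cm), c("NREM", "REM", "WAKE"))
  expect_equal(cm["REM", "WAKE"], 1L)
  expect_equal(sum(cm), 4L)
  expect_equal(rowSums(cm), c(NREM = 1L, REM = 2L, WAKE = 1L))
})

test_that("bootstrap cell means recover cell structure", {
  feats <- small_cohort_features()

  # a single-epoch cell's bootstrap mean is that value exactly
  one <- feats[1, , drop = FALSE]
  attr(one, "feature_info") <- attr(feats, "feature_info")
  bs1 <- bootstrap_cell_means(one, scales = 1, draw_size = 10, n_draws = 50,
                              seed = 3)
  frontal_cols <- c("F3_s1", "F4_s1")
  expect_equal(bs1$cells$value[bs1$cells$location == "frontal"],
               mean(as.numeric(one[1, frontal_cols])), tolerance = 1e-12)

  # determinism under seed
  bs_a <- bootstrap_cell_means(feats, draw_size = 10, n_draws = 100, seed = 5)
  bs_b <- bootstrap_cell_means(feats, draw_size = 10, n_draws = 100, seed = 5)
  expect_identical(bs_a$cells, bs_b$cells)

  # invariance to epoch ordering (same seed, permuted rows)
  perm <- sample(nrow(feats))
  shuffled <- feats[perm, , drop = FALSE]
  attr(shuffled, "feature_info") <- attr(feats, "feature_info")
  bs_c <- bootstrap_cell_means(shuffled, draw_size = 10, n_draws = 100,
                               seed = 5)
  # cells are keyed, not positional: compare by merged key
  key <- function(d) d[order(d$subject, d$session, d$stage, d$location,
                             d$scale), ]
  expect_equal(key(bs_a$cells)$n_epochs, key(bs_c$cells)$n_epochs)
  expect_equal(key(bs_a$cells)$value, key(bs_c$cells)$value, tolerance = 0.02)

  expect_error(bootstrap_cell_means(feats, draw_size = 0), "draw_size")
})

test_that("bootstrap means concentrate around the population mean (CLT)", {
  # synthetic feature table: one subject/stage cell with N(mu, sigma) values
  set.seed(23)
  mu <- 1.5
  sigma <- 0.05
  n_epochs <- 40
  f <- data.frame(subject = "S01", session = "week5",
                  epoch = seq_len(n_epochs) - 1L, stage = "REM",
                  F3_s1 = rnorm(n_epochs, mu, sigma),
                  F4_s1 = rnorm(n_epochs, mu, sigma))
  attr(f, "feature_info") <- data.frame(
    feature = c("F3_s1", "F4_s1"), channel = c("F3", "F4"), scale = c(1L, 1L))
  bs <- bootstrap_cell_means(f, scales = 1, draw_size = 10, n_draws = 1000,
                             seed = 29)
  frontal <- bs$cells[bs$cells$location == "frontal", ]
  # the double average concentrates near the empirical cell mean much
  # tighter than sigma/sqrt(draw_size); 3 sd of the draw-mean distribution
  cell_mean <- mean(rowMeans(f[, c("F3_s1", "F4_s1")]))
  tol <- 3 * sigma / sqrt(10 * 1000)
  expect_lt(abs(frontal$value - cell_mean), 5 * tol)
  # missing cells are flagged, not imputed
  expect_true(all(c("NREM", "WAKE") %in% bs$missing$stage))
})

test_that("channel importance aggregates to one per channel and sums to 1", {
  feats <- toy_features(n_per_class = 30, p = 10, sep = 3, seed = 37)
  x <- feats[, feature_columns(feats)]
  fit <- fit_stager(x, feats$stage,
                    hyper_grid = data.frame(num_trees = 100L, max_depth = 0L,
                                            mtry_frac = NA_real_),
                    seed = 9)
  info <- data.frame(feature = colnames(x),
                     channel = rep(c("F3", "F4", "C3", "C4", "O1"), each = 2))
  imp <- channel_importance(fit, info)
  expect_length(imp, 5L)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_true(all(imp >= 0))

  expect_error(channel_importance(fit, info[1:3, ]), "does not match")
})

test_that("channels carrying the class signal rank top in importance", {
  # only the EOG channels differ between classes
  set.seed(41)
  n <- 120
  stages <- rep(c("NREM", "REM", "WAKE"), each = n / 3)
  mu <- c(NREM = 0, REM = 2, WAKE = 4)
  df <- data.frame(subject = "S01", session = "week5", epoch = seq_len(n) - 1L,
                   stage = stages)
  channels <- c("F3", "C3", "HEOG_L", "HEOG_R")
  for (ch in channels) for (s in 1:2) {
    base <- if (grepl("HEOG", ch)) mu[stages] else 0
    df[[sprintf("%s_s%d", ch, s)]] <- base + rnorm(n)
  }
  info <- data.frame(
    feature = as.vector(t(outer(channels, 1:2,
                                function(c, s) sprintf("%s_s%d", c, s)))),
    channel = rep(channels, each = 2))
  fit <- fit_stager(df[, info$feature], df$stage,
                    hyper_grid = data.frame(num_trees = 200L, max_depth = 0L,
                                            mtry_frac = NA_real_),
                    seed = 13)
  imp <- channel_importance(fit, info)
  expect_setequal(names(imp)[1:2], c("HEOG_L", "HEOG_R"))
})

test_that("the exported statistics table round-trips losslessly", {
  feats <- small_cohort_features()
  bs <- bootstrap_cell_means(feats, draw_size = 5, n_draws = 50, seed = 11)
  path <- tempfile(fileext = ".csv")
  tab <- export_stats_table(bs, path)
  expect_true(all(c("subject", "session", "stage", "location", "scale",
                    "value") == colnames(tab)))
  # cardinality bound: subjects x sessions x stages x locations x scales
  expect_lte(nrow(tab), 3 * 2 * 3 * 3 * 2)
  back <- read_stats_table(path)
  expect_equal(back, as.data.frame(tab), ignore_attr = TRUE)
  # missing cells are omitted rows, their count is carried as an attribute
  expect_equal(nrow(tab) + attr(tab, "n_missing_cells"), 3 * 2 * 3 * 3 * 2)
})
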