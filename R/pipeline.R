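#' Build a pipeline run configuration
#'
#' A fully serializable description of one end-to-end run: cohort size and
#' seed, preprocessing parameters, feature kind, entropy parameters,
#' cross-validation settings and output directory. The same configuration
#' and package version reproduce a run's feature tables bit-for-bit.
#'
#' @param seed master integer seed; every random stage derives from it.
#' @param n_subjects cohort size (default 6, the demo size).
#' @param duration_min minutes per recording (default 30).
#' @param feature_kind `"mspe"` or `"psd"`.
#' @param m,tau,scales entropy parameters (see [mspe()]).
#' @param target_fs,low,high,artifact_percentile preprocessing parameters.
#' @param n_repetitions CV repetitions per scheme.
#' @param n_shuffles label shuffles for the empirical chance level.
#' @param hyper_grid forest hyper-parameter grid (data frame).
#' @param out_dir output directory.
#' @param write_edf also write each generated recording as EDF + hypnogram
#'   CSV (default `FALSE`).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, n_subjects = 6L, duration_min = 30,
                       feature_kind = c("mspe", "psd"),
                       m = 3L, tau = 1L, scales = 1:5,
                       target_fs = 125, low = 0.5, high = 35,
                       artifact_percentile = 0.95,
                       n_repetitions = 5L, n_shuffles = 0L,
                       hyper_grid = default_hyper_grid(),
                       out_dir = tempfile("neosleep_run_"),
                       write_edf = FALSE) {
  feature_kind <- match.arg(feature_kind)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 duration_min = duration_min, feature_kind = feature_kind,
                 m = m, tau = tau, scales = scales, target_fs = target_fs,
                 low = low, high = high,
                 artifact_percentile = artifact_percentile,
                 n_repetitions = as.integer(n_repetitions),
                 n_shuffles = as.integer(n_shuffles),
                 hyper_grid = hyper_grid, out_dir = out_dir,
                 write_edf = write_edf),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file whose keys are
#'   [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$hyper_grid)) cfg$hyper_grid <- as.data.frame(cfg$hyper_grid)
  do.call(run_config, cfg)
}

#' Hash of a run configuration
#'
#' FNV-1a hash of the configuration (excluding the output directory), as 8
#' hex digits. Every file a pipeline run writes carries this hash in its
#' name, so outputs can be traced back to the exact configuration.
#'
#' @param cfg a [run_config()].
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  bytes <- utf8ToInt(paste(deparse(cfg[order(names(cfg))]), collapse = ""))
  # 32-bit FNV-1a kept in a double; xor via 16-bit halves
  xor32 <- function(a, b) {
    bitwXor(a %% 65536, b %% 65536) +
      65536 * bitwXor(a %/% 65536, b %/% 65536)
  }
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- xor32(h, b)
    # (h * prime) mod 2^32 without exceeding double precision
    lo <- (h %% 65536) * prime
    hi <- ((h %/% 65536) * prime) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full pipeline end to end
#'
#' Generates the synthetic cohort one recording at a time (week-2 and week-5
#' per subject), preprocesses each, extracts the configured features, runs
#' the four cross-validation schemes (within week-2, within week-5, and both
#' cross-session directions), optionally estimates the shuffled-label chance
#' level, computes the bootstrap entropy summary, statistics table and
#' channel importances, and writes everything to the output directory. Every
#' output filename carries the 8-digit configuration hash.
#'
#' @param config a [run_config()].
#' @return the output directory path, invisibly; a `manifest_<hash>.json`
#'   inside lists all written files.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  out <- function(name) file.path(config$out_dir, sprintf(name, hash))
  log_lines <- c(sprintf("neosleep run %s", hash),
                 sprintf("config: %s", paste(deparse(unclass(
                   config[setdiff(names(config), "hyper_grid")])), collapse = " ")))
  written <- character(0)

  sspecs <- default_session_specs()
  feats <- list()
  for (i in seq_len(config$n_subjects)) {
    for (j in seq_along(sspecs)) {
      rec <- generate_recording(sprintf("S%02d", i), sspecs[[j]],
                                duration_min = config$duration_min,
                                seed = config$seed + 1000L * i + j)
      if (isTRUE(config$write_edf)) {
        ef <- out(sprintf("%s_%s_%%s.edf", rec$subject, rec$session))
        write_edf(rec, ef)
        write_hypnogram(rec$hypnogram, sub("\\.edf$", "_hypnogram.csv", ef))
        written <- c(written, ef, sub("\\.edf$", "_hypnogram.csv", ef))
      }
      es <- preprocess_recording(rec, target_fs = config$target_fs,
                                 low = config$low, high = config$high,
                                 percentile = config$artifact_percentile)
      log_lines <- c(log_lines, sprintf("%s/%s: %s", rec$subject, rec$session,
                                        paste(es$provenance, collapse = " | ")))
      feats[[length(feats) + 1L]] <- if (config$feature_kind == "mspe") {
        mspe_features(es, m = config$m, tau = config$tau,
                      scales = config$scales)
      } else {
        psd_features(es)
      }
    }
  }
  info <- attr(feats[[1]], "feature_info")
  features <- do.call(rbind, feats)
  attr(features, "feature_info") <- info

  ff <- out(sprintf("features_%s_%%s.csv", config$feature_kind))
  write.csv(features, ff, row.names = FALSE)
  written <- c(written, ff)

  schemes <- list(
    within_week2 = cv_scheme("within", "week2",
                             n_repetitions = config$n_repetitions,
                             seed = config$seed),
    within_week5 = cv_scheme("within", "week5",
                             n_repetitions = config$n_repetitions,
                             seed = config$seed + 1L),
    cross_w2_to_w5 = cv_scheme("cross", "week2", "week5",
                               n_repetitions = config$n_repetitions,
                               seed = config$seed + 2L),
    cross_w5_to_w2 = cv_scheme("cross", "week5", "week2",
                               n_repetitions = config$n_repetitions,
                               seed = config$seed + 3L)
  )
  cv_results <- list()
  for (nm in names(schemes)) {
    jf <- out(sprintf("cv_%s_%%s.json", nm))
    res <- tryCatch(
      run_cv(features, schemes[[nm]], hyper_grid = config$hyper_grid),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      # partial failure: record it and keep the run resumable
      jsonlite::write_json(list(scheme = unclass(schemes[[nm]]),
                                config_hash = hash, status = "failed",
                                error = conditionMessage(res)),
                           jf, auto_unbox = TRUE)
      log_lines <- c(log_lines, sprintf("%s: FAILED (%s)", nm,
                                        conditionMessage(res)))
    } else {
      cv_results[[nm]] <- res
      jsonlite::write_json(list(
        scheme = unclass(res$scheme), config_hash = hash, status = "ok",
        median_accuracy = res$median_accuracy,
        median_f1 = as.list(res$median_f1),
        accuracies = res$accuracies,
        pooled_confusion = res$pooled_confusion,
        skipped = res$skipped
      ), jf, auto_unbox = TRUE, digits = NA)
      log_lines <- c(log_lines, sprintf("%s: median accuracy %.3f", nm,
                                        res$median_accuracy))
    }
    written <- c(written, jf)
  }

  if (config$n_shuffles > 0) {
    ch_scheme <- cv_scheme("within", "week5", n_repetitions = 1L,
                           seed = config$seed + 9L)
    chance <- estimate_chance(features, ch_scheme,
                              n_shuffles = config$n_shuffles)
    cf <- out("chance_%s.json")
    jsonlite::write_json(list(config_hash = hash, mean = chance$mean,
                              accuracies = chance$accuracies),
                         cf, auto_unbox = TRUE, digits = NA)
    written <- c(written, cf)
    log_lines <- c(log_lines, sprintf("chance mean %.3f", chance$mean))
  }

  if (config$feature_kind == "mspe") {
    bs <- bootstrap_cell_means(features, seed = config$seed)
    sf <- out("stats_table_%s.csv")
    export_stats_table(bs, sf)
    written <- c(written, sf)

    # channel importance from a forest trained on the full balanced set
    bal <- undersample(features, seed = config$seed)
    fit <- fit_stager(bal, bal$stage,
                      hyper_grid = data.frame(num_trees = 300L, max_depth = 0L,
                                              mtry_frac = NA_real_),
                      seed = config$seed)
    imp <- channel_importance(fit, info)
    impf <- out("channel_importance_%s.csv")
    write.csv(data.frame(channel = names(imp), importance = as.numeric(imp)),
              impf, row.names = FALSE)
    written <- c(written, impf)
  }

  lf <- out("log_%s.txt")
  writeLines(log_lines, lf)
  mf <- out("manifest_%s.json")
  jsonlite::write_json(list(config_hash = hash, files = basename(c(written, lf))),
                       mf, auto_unbox = TRUE)
  invisible(config$out_dir)
}
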