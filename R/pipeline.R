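#' Available detector names
#' @export
hr_models <- function() c("arima", "lstm", "bilstm", "cae-lstm", "vae-bilstm")

# Fit one detector by name on a split, with benchmark-sized training
# settings (sizes documented in the methods vignette).
.fit_model <- function(model, split, seed, epochs = NULL) {
  val <- split$validation$series
  switch(model,
    "arima" = hr_arima(split$train, max_p = 2L, max_q = 2L),
    "lstm" = hr_lstm(split$train, val,
                     net_config(seed = seed, batch_size = 256L, train_stride = 2L,
                                learning_rate = 2e-3,
                                max_epochs = epochs %||% 15L, patience = 3L)),
    "bilstm" = hr_bilstm(split$train, val,
                         net_config(seed = seed, batch_size = 256L, train_stride = 2L,
                                    learning_rate = 2e-3,
                                    max_epochs = epochs %||% 15L, patience = 3L)),
    "cae-lstm" = hr_cae_lstm(split$train, val,
                             cae_config(seed = seed, batch_size = 256L,
                                        learning_rate = 2e-3,
                                        max_epochs = epochs %||% 25L, patience = 5L)),
    "vae-bilstm" = hr_vae_bilstm(split$train, val,
                                 vae_config(seed = seed, batch_size = 64L,
                                            max_epochs = epochs %||% 60L, patience = 10L)),
    stop("unknown model: ", model))
}

# Squared-error scores of a fitted detector over the training nights
# (threshold reference distribution).
.train_scores <- function(object, train_nights) {
  unlist(lapply(train_nights, function(s) hr_score(object, s)$scores))
}

#' Run the full study protocol once for one synthetic participant
#'
#' Simulates 7 nights, trims sleep edges, auto-labels each night with the
#' ensemble rule, builds the 5/1/1 split with cleaned training nights,
#' fits the requested detectors, tunes each detector's threshold
#' multiplier on the validation night (segment-adjusted F1 against the
#' injected ground truth), and evaluates raw and adjusted metrics on the
#' test night.
#'
#' @param seed Master seed for the run.
#' @param models Character vector of detector names (see [hr_models()]).
#' @param interval_seconds Sampling interval (30 or 60).
#' @param profile,spec Generator settings; defaults are the study
#'   conditions.
#' @param labeler A [labeler_config()].
#' @param k_grid Threshold-multiplier grid.
#' @param epochs Optional cap on training epochs for the neural models.
#' @param model_seed Seed for the stochastic parts of model training
#'   (defaults to `seed`); repeated runs on the same data vary this only.
#' @return List with per-model `detection_result`s (`results`), tuned `k`s,
#'   the `split`, truth masks and fitted `models`.
#' @export
run_protocol <- function(seed = 1L, models = "vae-bilstm", interval_seconds = 60L,
                         profile = NULL, spec = NULL,
                         labeler = NULL, k_grid = c(1, 1.5, 2, 2.5, 3, 3.5, 4),
                         epochs = NULL, model_seed = seed) {
  if (is.null(profile)) profile <- night_profile(interval_seconds = interval_seconds,
                                                 seed = seed)
  if (is.null(spec)) spec <- anomaly_spec(seed = seed)
  if (is.null(labeler)) labeler <- labeler_config(seed = seed)
  nights <- simulate_participant(profile, spec, n_nights = 7L)
  trimmed <- lapply(nights, function(nt) {
    s <- trim_sleep_edges(nt$series)
    list(series = s, truth = trim_mask(nt$mask, nt$series))
  })
  labeled <- lapply(trimmed, function(nt) {
    list(series = nt$series, mask = label_anomalies(nt$series, labeler),
         truth = nt$truth)
  })
  split <- build_split(labeled)
  val_truth <- trimmed[[6]]$truth$flags
  test_truth <- trimmed[[7]]$truth$flags
  results <- list(); ks <- list(); fits <- list()
  for (m in models) {
    fit <- .fit_model(m, split, model_seed, epochs)
    tr_sc <- .train_scores(fit, split$train)
    v_sc <- hr_score(fit, split$validation$series)
    tk <- tune_k(v_sc$scores, val_truth[v_sc$indices], k_grid, tr_sc)
    res <- detect_anomalies(fit, split$test$series, test_truth, tr_sc, k = tk$k)
    results[[m]] <- res; ks[[m]] <- tk$k; fits[[m]] <- fit
  }
  list(results = results, k = ks, models = fits, split = split,
       truth = list(validation = val_truth, test = test_truth),
       labeler = labeler, profile = profile, spec = spec)
}

#' Synthetic benchmark: repeated runs of the protocol
#'
#' Repeats [run_protocol()] over `n_runs` master seeds and aggregates
#' adjusted (and raw) precision/recall/F1 per model.
#'
#' @param n_runs Number of repeated runs.
#' @param models Detector names.
#' @param interval_seconds Sampling interval.
#' @param seed Base seed; run r uses `seed * 100 + r`.
#' @param ... Passed on to [run_protocol()].
#' @return List with `summary` (per-model [aggregate_runs()] of adjusted
#'   metrics), `raw_summary` and `per_run` F1 values.
#' @export
run_benchmark <- function(n_runs = 20L, models = hr_models(),
                          interval_seconds = 60L, seed = 1L, ...) {
  adj <- list(); raw <- list()
  for (r in seq_len(n_runs)) {
    pr <- run_protocol(seed = (seed %% 10000L) * 100L + r, models = models,
                       interval_seconds = interval_seconds, ...)
    for (m in models) {
      res <- pr$results[[m]]
      adj[[m]] <- rbind(adj[[m]], data.frame(precision = res$adjusted$precision,
                                             recall = res$adjusted$recall,
                                             f1 = res$adjusted$f1))
      raw[[m]] <- rbind(raw[[m]], data.frame(precision = res$raw$precision,
                                             recall = res$raw$recall,
                                             f1 = res$raw$f1))
    }
  }
  list(summary = lapply(adj, aggregate_runs),
       raw_summary = lapply(raw, aggregate_runs),
       per_run = lapply(adj, `[[`, "f1"))
}

#' Validate an experiment configuration
#'
#' Reads a YAML or JSON configuration, fills study defaults (window n = 10,
#' latent d = 4, beta = 3, window fraction 3 percent, k grid 1..4), and
#' reports all schema violations at once.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @return An object of class `experiment_config`.
#' @export
validate_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (grepl("\\.ya?ml$", path)) {
      if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package required for YAML configs")
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
  }
  defaults <- list(participants = 1L, nights = 7L, interval_seconds = 60L,
                   models = "vae-bilstm", runs = 1L, seed = NULL,
                   window_length = 10L, latent_dim = 4L, beta = 3,
                   sw_window_fraction = 0.03, sw_k = 3, contamination = 0.02,
                   k_grid = c(1, 1.5, 2, 2.5, 3, 3.5, 4), out_dir = NULL)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  errs <- character(0)
  if (is.null(cfg$seed)) errs <- c(errs, "seed: required for reproducibility")
  if (!cfg$interval_seconds %in% c(30L, 60L)) errs <- c(errs, "interval_seconds: must be 30 or 60")
  if (cfg$beta <= 0) errs <- c(errs, "beta: must be > 0")
  if (cfg$window_length <= 1) errs <- c(errs, "window_length: must be > 1")
  if (!all(cfg$models %in% hr_models())) {
    errs <- c(errs, paste0("models: unknown name(s) ",
                           paste(setdiff(cfg$models, hr_models()), collapse = ", ")))
  }
  if (cfg$sw_window_fraction <= 0 || cfg$sw_window_fraction >= 1) {
    errs <- c(errs, "sw_window_fraction: must be in (0, 1)")
  }
  if (cfg$runs < 1) errs <- c(errs, "runs: must be >= 1")
  if (length(errs) > 0) {
    stop("invalid experiment configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  structure(cfg, class = "experiment_config")
}

#' Run a configured experiment end to end
#'
#' simulate -> label -> split/clean -> train -> detect -> evaluate for
#' every participant x model, writing per-night CSVs, per-detector label
#' masks, score CSVs, a metrics JSON and a run manifest under `out_dir`.
#'
#' @param config An `experiment_config` (see [validate_config()]).
#' @param out_dir Output directory (overrides the config's).
#' @return The manifest (invisibly): config snapshot, output files, and
#'   the metrics table.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (!inherits(config, "experiment_config")) config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  rows <- list()
  for (p in seq_len(config$participants)) {
    pseed <- (config$seed %% 100000L) * 10L + p
    for (r in seq_len(config$runs)) {
      pr <- run_protocol(seed = pseed, models = config$models,
                         interval_seconds = config$interval_seconds,
                         spec = anomaly_spec(seed = pseed),
                         labeler = labeler_config(contamination = config$contamination,
                                                  sw_window_fraction = config$sw_window_fraction,
                                                  sw_k = config$sw_k, seed = pseed),
                         k_grid = config$k_grid,
                         model_seed = pseed * 100L + r)
      night_dir <- file.path(out_dir, sprintf("participant%d", p))
      dir.create(night_dir, showWarnings = FALSE)
      if (r == 1L) {
        for (i in seq_along(pr$split$train)) {
          f <- file.path(night_dir, sprintf("train_night%d.csv", i))
          write_night_csv(pr$split$train[[i]], f, pr$split$train_masks[[i]])
          files <- c(files, f)
        }
        f <- file.path(night_dir, "test_night.csv")
        write_night_csv(pr$split$test$series, f, pr$split$test$mask)
        files <- c(files, f)
      }
      for (m in config$models) {
        res <- pr$results[[m]]
        f <- file.path(night_dir, sprintf("scores_%s_run%d.csv", gsub("-", "_", m), r))
        utils::write.csv(data.frame(timestamp_s = pr$split$test$series$t[res$indices],
                                    score = res$scores), f, row.names = FALSE)
        files <- c(files, f)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = p, run = r, model = m, k = pr$k[[m]],
          precision = res$adjusted$precision, recall = res$adjusted$recall,
          f1 = res$adjusted$f1, raw_f1 = res$raw$f1)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  mf <- file.path(out_dir, "metrics.csv")
  utils::write.csv(metrics, mf, row.names = FALSE)
  files <- c(files, mf)
  manifest <- list(config = unclass(config), created = as.character(Sys.time()),
                   files = files,
                   hashes = vapply(files, function(f) {
                     as.character(sum(as.integer(charToRaw(paste(readLines(f, warn = FALSE),
                                                                 collapse = "\n")))))
                   }, character(1)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(list(manifest = manifest, metrics = metrics))
}
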