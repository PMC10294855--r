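#' Labeler configuration for the ensemble auto-labeling rule
#'
#' Settings for the four constituent detectors of the auto-labeling rule:
#' isolation forest (IF), one-class SVM with radial-basis kernel (OCSVM),
#' Gaussian kernel density estimation (KDE), and the tumbling-window
#' three-sigma rule (SW). The combined label is
#' `(IF & OCSVM & KDE) | SW` pointwise.
#'
#' @param contamination Expected outlier fraction used by IF (score
#'   quantile), OCSVM (`nu`) and KDE (low-density quantile). In (0, 0.5).
#' @param sw_window_fraction Tumbling-window length as a fraction of the
#'   series length (the rule's segments).
#' @param sw_k SD multiplier of the window rule.
#' @param feature_mode `"value"` (1-D BPM feature, default) or
#'   `"value+diff"` (adds the local first difference).
#' @param if_trees,if_sample_size Isolation-forest ensemble settings.
#' @param ocsvm_nu One-class SVM training nu. This controls the smoothness
#'   of the decision surface, not the flagged share: a small nu yields a
#'   degenerate surface on which far outliers and mid-bulk points tie, so
#'   the default is 0.5 and the flagged fraction is always taken from the
#'   `contamination` quantile of the decision values.
#' @param kde_bandwidth `"silverman"` or a positive number.
#' @param sd_type `"population"` (divide by m) or `"sample"` for the window
#'   rule's SD.
#' @param seed Seed for the stochastic detectors (IF).
#' @return An object of class `labeler_config`.
#' @export
labeler_config <- function(contamination = 0.02, sw_window_fraction = 0.03,
                           sw_k = 3, feature_mode = c("value", "value+diff"),
                           if_trees = 100L, if_sample_size = 256L,
                           ocsvm_nu = 0.5,
                           kde_bandwidth = "silverman",
                           sd_type = c("population", "sample"), seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  sd_type <- match.arg(sd_type)
  if (contamination <= 0 || contamination >= 0.5) stop("contamination must be in (0, 0.5)")
  if (sw_window_fraction <= 0 || sw_window_fraction >= 1) {
    stop("sw_window_fraction must be in (0, 1)")
  }
  if (sw_k <= 0) stop("sw_k must be > 0")
  structure(list(contamination = contamination,
                 sw_window_fraction = sw_window_fraction, sw_k = sw_k,
                 feature_mode = feature_mode, if_trees = as.integer(if_trees),
                 if_sample_size = as.integer(if_sample_size),
                 ocsvm_nu = ocsvm_nu,
                 kde_bandwidth = kde_bandwidth, sd_type = sd_type,
                 seed = as.integer(seed)),
            class = "labeler_config")
}

#' Remove the first and last minutes of sleep
#'
#' Discards the falling-asleep and waking-up edges of a night, where heart
#' rate is irregular, and re-anchors timestamps to zero.
#'
#' @param series An [hr_series()].
#' @param trim_minutes Minutes to drop at each end (default 30).
#' @return The trimmed [hr_series()].
#' @export
trim_sleep_edges <- function(series, trim_minutes = 30) {
  k <- as.integer(trim_minutes * 60 / series$interval_seconds)
  n <- length(series$bpm)
  if (n <= 2L * k) stop("series too short: trimming would leave nothing")
  keep <- seq.int(k + 1L, n - k)
  out <- series
  out$t <- series$t[keep] - series$t[k + 1L]
  out$bpm <- series$bpm[keep]
  out
}

#' Apply trimming to a mask alongside its series
#' @export
trim_mask <- function(mask, series, trim_minutes = 30) {
  k <- as.integer(trim_minutes * 60 / series$interval_seconds)
  n <- length(mask$flags)
  keep <- seq.int(k + 1L, n - k)
  label_mask(mask$flags[keep],
             source = lapply(mask$source, function(m) m[keep]))
}

.featurize <- function(series, feature_mode) {
  x <- series$bpm
  if (feature_mode == "value") {
    matrix(x, ncol = 1)
  } else {
    d <- c(0, diff(x))
    cbind(x, d)
  }
}

#' One unsupervised point detector (IF, OCSVM or KDE)
#'
#' @param series A trimmed [hr_series()].
#' @param method `"if"`, `"ocsvm"` or `"kde"`.
#' @param config A [labeler_config()].
#' @return A [label_mask()].
#' @export
detect_unsupervised <- function(series, method = c("if", "ocsvm", "kde"),
                                config = labeler_config()) {
  method <- match.arg(method)
  X <- .featurize(series, config$feature_mode)
  n <- nrow(X)
  flags <- switch(method,
    "if" = {
      sc <- iforest_score(X, n_trees = config$if_trees,
                          sample_size = config$if_sample_size, seed = config$seed)
      thr <- stats::quantile(sc, 1 - config$contamination, type = 1)
      sc > thr
    },
    "ocsvm" = {
      Xs <- scale(X)
      Xs[is.nan(Xs)] <- 0
      fit <- e1071::svm(Xs, type = "one-classification", kernel = "radial",
                        nu = config$ocsvm_nu, scale = FALSE)
      # rank by the signed decision value and flag the configured fraction,
      # so the flagged share respects the contamination bound even when the
      # learned boundary would enclose a dense outlier cluster
      dv <- as.numeric(attr(stats::predict(fit, Xs, decision.values = TRUE),
                            "decision.values"))
      # far outliers saturate at the same minimal decision value, so the
      # cutoff is inclusive, guarded so a constant series flags nothing
      thr <- stats::quantile(dv, config$contamination, type = 1)
      dv <= thr & dv < max(dv)
    },
    "kde" = {
      x <- X[, 1]
      bw <- if (identical(config$kde_bandwidth, "silverman")) {
        max(stats::bw.nrd0(x), 1e-8)
      } else {
        config$kde_bandwidth
      }
      # Gaussian KDE evaluated at the sample points themselves
      dens <- vapply(x, function(xi) mean(stats::dnorm((xi - x) / bw)) / bw, numeric(1))
      thr <- stats::quantile(dens, config$contamination, type = 1)
      dens < thr
    })
  label_mask(flags)
}

#' Tumbling-window three-sigma rule
#'
#' The series is partitioned into consecutive non-overlapping segments of
#' length `round(window_fraction * N)` (minimum 3; a short trailing
#' remainder merges into the previous segment). A point is flagged when it
#' lies more than `k` segment SDs from the segment mean.
#'
#' @param series A trimmed [hr_series()].
#' @param window_fraction Segment length as a fraction of the series.
#' @param k SD multiplier.
#' @param sd_type `"population"` or `"sample"` SD within each segment.
#' @return A [label_mask()].
#' @export
detect_sliding_window <- function(series, window_fraction = 0.03, k = 3,
                                  sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- series$bpm
  n <- length(x)
  w <- max(3L, as.integer(floor(window_fraction * n + 0.5)))
  if (n < w) stop("series shorter than one window")
  n_win <- n %/% w
  flags <- rep(FALSE, n)
  for (j in seq_len(n_win)) {
    from <- (j - 1L) * w + 1L
    to <- if (j == n_win) n else j * w   # remainder merges into last window
    seg <- x[from:to]
    m <- mean(seg)
    s <- if (sd_type == "population") {
      sqrt(mean((seg - m)^2))
    } else {
      stats::sd(seg)
    }
    flags[from:to] <- abs(seg - m) > k * s
  }
  label_mask(flags)
}

#' Ensemble auto-labeling of one night
#'
#' Runs IF, OCSVM and KDE, intersects their flags (high-confidence, mainly
#' global outliers), and unions the result with the tumbling-window rule
#' (adds contextual outliers). Per-detector masks are kept in `source`.
#'
#' @param series A trimmed [hr_series()].
#' @param config A [labeler_config()].
#' @return A [label_mask()] with `source` entries `if`, `ocsvm`, `kde`,
#'   `sw` and `ensemble`.
#' @export
label_anomalies <- function(series, config = labeler_config()) {
  m_if <- detect_unsupervised(series, "if", config)$flags
  m_oc <- detect_unsupervised(series, "ocsvm", config)$flags
  m_kde <- detect_unsupervised(series, "kde", config)$flags
  m_sw <- detect_sliding_window(series, config$sw_window_fraction, config$sw_k,
                                config$sd_type)$flags
  ens <- m_if & m_oc & m_kde
  label_mask(ens | m_sw,
             source = list("if" = m_if, ocsvm = m_oc, kde = m_kde,
                           sw = m_sw, ensemble = ens))
}

#' Replace labeled anomalies by the previous non-anomalous value
#'
#' Every flagged point takes the value of the nearest preceding non-flagged
#' point; a flagged run at the head of the series takes the first
#' subsequent non-flagged value.
#'
#' @param series An [hr_series()].
#' @param mask A [label_mask()] aligned to it.
#' @return The cleaned [hr_series()].
#' @export
clean_training <- function(series, mask) {
  f <- mask$flags
  if (length(f) != length(series$bpm)) stop("mask length mismatch")
  if (all(f)) stop("all points flagged: no clean value to carry forward")
  x <- series$bpm
  clean_idx <- which(!f)
  if (f[1]) x[seq_len(clean_idx[1] - 1L)] <- x[clean_idx[1]]
  for (i in which(f)) {
    if (i > clean_idx[1]) {
      j <- max(clean_idx[clean_idx < i])
      x[i] <- x[j]
    }
  }
  out <- series
  out$bpm <- x
  out
}

#' Split a participant's nights into train/validation/test
#'
#' The first five nights (by night index) become training data, cleaned by
#' replacing their labeled anomalies; night 6 is validation and night 7 is
#' test, both kept as-is with their labels.
#'
#' @param nights List of `list(series, mask)` pairs, trimmed and labeled.
#' @return An object of class `split_dataset` with elements `train`
#'   (cleaned series), `train_masks`, `validation`, `test`.
#' @export
build_split <- function(nights) {
  if (length(nights) < 7L) stop("need at least 7 nights for a 5/1/1 split")
  nights <- nights[seq_len(7L)]
  train <- lapply(nights[1:5], function(nt) clean_training(nt$series, nt$mask))
  structure(list(train = train,
                 train_masks = lapply(nights[1:5], `[[`, "mask"),
                 validation = nights[[6]],
                 test = nights[[7]]),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("<split_dataset> 5 train / 1 validation / 1 test nights (%d samples/night)\n",
              length(x$train[[1]]$bpm)))
  invisible(x)
}
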