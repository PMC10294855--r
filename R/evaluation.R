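#' Detection threshold from training squared errors
#'
#' `threshold = mean + k * sd` of the squared one-step prediction errors on
#' the training set (population SD by default).
#'
#' @param train_scores Numeric vector of training squared errors (>= 2).
#' @param k SD multiplier.
#' @param sd_type `"population"` or `"sample"`.
#' @return An object of class `threshold_rule` with `threshold`, `k`,
#'   `mean`, `sd`.
#' @export
compute_threshold <- function(train_scores, k, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(train_scores) < 2L) stop("need at least 2 training scores")
  m <- mean(train_scores)
  s <- if (sd_type == "population") {
    sqrt(mean((train_scores - m)^2))
  } else {
    stats::sd(train_scores)
  }
  structure(list(threshold = m + k * s, k = k, mean = m, sd = s),
            class = "threshold_rule")
}

#' Segment adjustment of point predictions
#'
#' For every maximal contiguous run of true anomalies, a single detected
#' point inside the run credits the whole run: all its points are set to
#' flagged in the output. Predictions outside true runs are unchanged. The
#' adjustment is idempotent and only ever adds flags.
#'
#' @param pred,truth Logical vectors of equal length.
#' @return Adjusted logical prediction vector.
#' @export
adjust_predictions <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth must have equal length")
  pred <- as.logical(pred); truth <- as.logical(truth)
  out <- pred
  r <- rle(truth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    idx <- starts[j]:ends[j]
    if (any(pred[idx])) out[idx] <- TRUE
  }
  out
}

#' Precision, recall and F1 from point predictions
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2TP/(2TP+FP+FN)`. With `adjusted = TRUE` the segment adjustment
#' is applied first. Ratios with zero denominators are reported as 0 and
#' flagged in `undefined`.
#'
#' @param pred,truth Logical vectors of equal length.
#' @param adjusted Apply [adjust_predictions()] first.
#' @return List with `precision`, `recall`, `f1`, `counts` (TP/FP/FN/TN
#'   and mode) and `undefined`.
#' @export
compute_metrics <- function(pred, truth, adjusted = FALSE) {
  if (length(pred) != length(truth)) stop("pred and truth must have equal length")
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (adjusted) pred <- adjust_predictions(pred, truth)
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth)
  undef <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else { undef <- c(undef, "precision"); 0 }
  recall <- if (tp + fn > 0) tp / (tp + fn) else { undef <- c(undef, "recall"); 0 }
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else { undef <- c(undef, "f1"); 0 }
  list(precision = precision, recall = recall, f1 = f1,
       counts = list(TP = tp, FP = fp, FN = fn, TN = tn,
                     mode = if (adjusted) "adjusted" else "raw"),
       undefined = undef)
}

#' Tune the threshold multiplier k on the validation night
#'
#' Picks the grid value maximising segment-adjusted F1 on the validation
#' night; ties are broken towards the larger k (fewer alerts). With no
#' anomalies in the validation truth a warning is issued and the largest k
#' returned.
#'
#' @param validation_scores Squared errors on the validation night.
#' @param validation_mask Logical truth for the same points.
#' @param k_grid Candidate multipliers.
#' @param train_scores Training squared errors defining the threshold rule.
#' @param sd_type SD convention passed to [compute_threshold()].
#' @return List with `k`, `f1`, `per_k` (F1 per grid value).
#' @export
tune_k <- function(validation_scores, validation_mask,
                   k_grid = c(1, 1.5, 2, 2.5, 3, 3.5, 4),
                   train_scores, sd_type = "population") {
  if (length(k_grid) == 0L) stop("empty k grid")
  truth <- as.logical(validation_mask)
  if (!any(truth)) {
    warning("no anomalies in the validation night; returning the largest k")
    return(list(k = max(k_grid), f1 = NA_real_, per_k = NULL))
  }
  f1s <- vapply(k_grid, function(k) {
    thr <- compute_threshold(train_scores, k, sd_type)$threshold
    compute_metrics(validation_scores > thr, truth, adjusted = TRUE)$f1
  }, numeric(1))
  best <- max(f1s)
  k <- max(k_grid[f1s >= best - 1e-12])
  list(k = k, f1 = best, per_k = stats::setNames(f1s, k_grid))
}

#' Aggregate repeated runs into mean (SD) summaries
#'
#' @param per_run_metrics Data frame or list of per-run named metric
#'   vectors (e.g. precision/recall/f1).
#' @return An object of class `run_summary`: per-metric `mean`, `sd`
#'   (population of runs, sample SD), and the retained per-run values.
#' @export
aggregate_runs <- function(per_run_metrics) {
  if (is.list(per_run_metrics) && !is.data.frame(per_run_metrics)) {
    per_run_metrics <- as.data.frame(do.call(rbind, lapply(per_run_metrics, unlist)))
  }
  if (nrow(per_run_metrics) < 1L) stop("no runs to aggregate")
  structure(list(mean = vapply(per_run_metrics, mean, numeric(1)),
                 sd = vapply(per_run_metrics, function(x) {
                   if (length(x) > 1) stats::sd(x) else 0
                 }, numeric(1)),
                 runs = per_run_metrics),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, digits = 3, ...) {
  cat(sprintf("<run_summary> over %d runs\n", nrow(x$runs)))
  for (nm in names(x$mean)) {
    cat(sprintf("  %-10s %.*f (%.*f)\n", nm, digits, x$mean[nm], digits, x$sd[nm]))
  }
  invisible(x)
}

#' Apply a fitted detector to a night and evaluate it
#'
#' Scores the night, thresholds the squared errors, and computes raw and
#' segment-adjusted metrics against the truth restricted to the scorable
#' points.
#'
#' @param object A fitted `hr_detector`.
#' @param series The night to score.
#' @param truth Logical truth mask for the full night.
#' @param train_scores Squared errors on the training set (threshold
#'   reference distribution).
#' @param k SD multiplier (e.g. from [tune_k()]).
#' @param sd_type SD convention.
#' @return An object of class `detection_result`.
#' @export
detect_anomalies <- function(object, series, truth, train_scores, k = 3,
                             sd_type = "population") {
  sc <- hr_score(object, series)
  rule <- compute_threshold(train_scores, k, sd_type)
  pred <- sc$scores > rule$threshold
  tr <- as.logical(truth)[sc$indices]
  raw <- compute_metrics(pred, tr, adjusted = FALSE)
  adj <- compute_metrics(pred, tr, adjusted = TRUE)
  structure(list(scores = sc$scores, indices = sc$indices, pred = pred,
                 threshold = rule, truth = tr, raw = raw, adjusted = adj),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d scored points, threshold %.3f (k=%g)\n",
              length(x$scores), x$threshold$threshold, x$threshold$k))
  cat(sprintf("  raw      P %.3f R %.3f F1 %.3f\n", x$raw$precision,
              x$raw$recall, x$raw$f1))
  cat(sprintf("  adjusted P %.3f R %.3f F1 %.3f\n", x$adjusted$precision,
              x$adjusted$recall, x$adjusted$f1))
  invisible(x)
}
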