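#' Night profile for the synthetic nocturnal heart-rate generator
#'
#' Describes one night of evenly sampled sleep-time heart rate: a smooth
#' overnight drift (half-sine), piecewise-constant level shifts standing in
#' for sleep-stage transitions, and stationary AR(1) noise around the
#' baseline. Durations are in minutes, rates in beats per minute (BPM).
#'
#' @param duration_minutes Sleep length in minutes (typically 360-480).
#' @param interval_seconds Sampling interval, 30 or 60 seconds.
#' @param baseline_bpm Mean resting heart-rate level (typically 50-75).
#' @param drift_amplitude_bpm Amplitude of the slow overnight trend.
#' @param ultradian_amplitude_bpm Amplitude of the ~90-minute sleep-cycle
#'   oscillation (period drawn near `ultradian_period_min` per night).
#' @param ultradian_period_min Mean ultradian cycle period in minutes.
#' @param rem_amplitude_bpm Heart-rate elevation during the REM-like phase
#'   of each ultradian cycle (entered/left over a couple of samples).
#' @param n_stage_shifts Number of step level changes across the night
#'   (sleep-stage transitions; real nights show on the order of 10-20).
#' @param stage_shift_sd_bpm Standard deviation of each step's size
#'   (stage-related heart-rate differences are several BPM).
#' @param noise_sd_bpm Innovation SD of the AR(1) noise.
#' @param ar_coefficient AR(1) persistence, in (-1, 1).
#' @param seed Integer seed; the night is a pure function of the profile.
#' @return An object of class `night_profile`.
#' @export
night_profile <- function(duration_minutes = 420L, interval_seconds = 60L,
                          baseline_bpm = 60, drift_amplitude_bpm = 3,
                          ultradian_amplitude_bpm = 2,
                          ultradian_period_min = 90,
                          rem_amplitude_bpm = 0,
                          n_stage_shifts = 10L, stage_shift_sd_bpm = 6,
                          noise_sd_bpm = 1.5, ar_coefficient = 0.8,
                          seed = 1L) {
  p <- list(duration_minutes = as.integer(duration_minutes),
            interval_seconds = as.integer(interval_seconds),
            baseline_bpm = baseline_bpm,
            drift_amplitude_bpm = drift_amplitude_bpm,
            ultradian_amplitude_bpm = ultradian_amplitude_bpm,
            ultradian_period_min = ultradian_period_min,
            rem_amplitude_bpm = rem_amplitude_bpm,
            n_stage_shifts = as.integer(n_stage_shifts),
            stage_shift_sd_bpm = stage_shift_sd_bpm,
            noise_sd_bpm = noise_sd_bpm,
            ar_coefficient = ar_coefficient,
            seed = as.integer(seed))
  class(p) <- "night_profile"
  validate_night_profile(p)
  p
}

validate_night_profile <- function(p) {
  if (!p$interval_seconds %in% c(30L, 60L)) {
    stop("invalid profile field 'interval_seconds': must be 30 or 60")
  }
  n <- p$duration_minutes * 60 / p$interval_seconds
  if (n != round(n) || n < 2) {
    stop("invalid profile field 'duration_minutes': implies fewer than 2 samples")
  }
  if (p$noise_sd_bpm < 0) stop("invalid profile field 'noise_sd_bpm': must be >= 0")
  if (abs(p$ar_coefficient) >= 1) {
    stop("invalid profile field 'ar_coefficient': must satisfy |ar| < 1")
  }
  if (p$n_stage_shifts < 0) stop("invalid profile field 'n_stage_shifts': must be >= 0")
  if (p$baseline_bpm <= 0) stop("invalid profile field 'baseline_bpm': must be > 0")
  invisible(p)
}

#' Anomaly-injection settings
#'
#' Two anomaly classes are injected as short contiguous segments: global
#' anomalies land far outside the night's overall BPM range (offset in units
#' of the night's overall SD, anchored at the night mean), and contextual
#' anomalies are unusual only locally (offset in units of the local windowed
#' SD, kept inside the night's global range). Segments never overlap each
#' other or the first/last 30 minutes (the sleep-edge trim zone).
#'
#' @param n_global Number of global anomalous segments.
#' @param n_contextual Number of contextual anomalous segments.
#' @param global_magnitude_sd Global offset in units of the night SD.
#' @param contextual_magnitude_sd Contextual offset in units of local SD.
#' @param segment_length_range Integer min/max run length of a contextual
#'   segment.
#' @param global_segment_length_range Integer min/max run length of a
#'   global segment; default 1-2 because out-of-range spike episodes are
#'   brief compared with contextual deviations.
#' @param seed Integer seed for placement and signs.
#' @return An object of class `anomaly_spec`.
#' @export
anomaly_spec <- function(n_global = 3L, n_contextual = 4L,
                         global_magnitude_sd = 6, contextual_magnitude_sd = 3.5,
                         segment_length_range = c(1L, 4L),
                         global_segment_length_range = c(1L, 2L), seed = 1L) {
  s <- list(n_global = as.integer(n_global),
            n_contextual = as.integer(n_contextual),
            global_magnitude_sd = global_magnitude_sd,
            contextual_magnitude_sd = contextual_magnitude_sd,
            segment_length_range = as.integer(segment_length_range),
            global_segment_length_range = as.integer(global_segment_length_range),
            seed = as.integer(seed))
  class(s) <- "anomaly_spec"
  if (s$n_global < 0 || s$n_contextual < 0) stop("anomaly counts must be >= 0")
  if (s$global_magnitude_sd <= 0 || s$contextual_magnitude_sd <= 0) {
    stop("anomaly magnitudes must be > 0")
  }
  for (fld in c("segment_length_range", "global_segment_length_range")) {
    r <- s[[fld]]
    if (length(r) != 2L || r[1] < 1L || r[2] < r[1]) {
      stop(fld, " must be an increasing pair of positive integers")
    }
  }
  s
}

#' Construct a heart-rate series object
#'
#' @param t Timestamps in seconds from night start (uniform spacing).
#' @param bpm Heart-rate values in beats per minute.
#' @param interval_seconds Sampling interval.
#' @param participant_id Opaque participant identifier.
#' @param night_index Night number (0-based).
#' @return An object of class `hr_series`.
#' @export
hr_series <- function(t, bpm, interval_seconds, participant_id = "P1", night_index = 0L) {
  if (length(t) != length(bpm)) stop("t and bpm must have equal length")
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(abs(dt - interval_seconds) > 1e-8)) stop("timestamps must be uniformly spaced")
  }
  if (any(!is.finite(bpm)) || any(bpm <= 0)) stop("bpm values must be finite and positive")
  structure(list(participant_id = participant_id,
                 night_index = as.integer(night_index),
                 t = as.numeric(t), bpm = as.numeric(bpm),
                 interval_seconds = as.integer(interval_seconds)),
            class = "hr_series")
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("<hr_series> participant %s, night %d: %d samples @ %ds, %.1f-%.1f BPM\n",
              x$participant_id, x$night_index, length(x$bpm), x$interval_seconds,
              min(x$bpm), max(x$bpm)))
  invisible(x)
}

#' @export
length.hr_series <- function(x) length(x$bpm)

#' Per-point anomaly labels
#'
#' @param flags Logical vector, `TRUE` marks an anomalous point.
#' @param source Optional named list of per-detector logical sub-masks.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(flags, source = NULL) {
  structure(list(flags = as.logical(flags), source = source), class = "label_mask")
}

#' Simulate one clean night of nocturnal heart rate
#'
#' Clean-signal model: baseline + half-sine overnight drift + random
#' piecewise-constant stage shifts + stationary AR(1) noise. Deterministic
#' given the profile (including its seed).
#'
#' @param profile A [night_profile()].
#' @return An [hr_series()] of the implied length.
#' @export
simulate_night <- function(profile, participant_id = "P1", night_index = 0L) {
  validate_night_profile(profile)
  n <- as.integer(profile$duration_minutes * 60 / profile$interval_seconds)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(profile$seed)
    expr
  }
  withr_seed({
    tt <- (seq_len(n) - 1) * profile$interval_seconds
    u <- tt / max(tt[n], 1)
    # a participant's sleep architecture is consistent across nights:
    # phases fixed in the profile are reused with a small nightly jitter,
    # otherwise they are drawn fresh from the night seed
    phase <- if (!is.null(profile$drift_phase)) {
      profile$drift_phase + stats::rnorm(1, 0, 0.05)
    } else stats::runif(1, 0, pi / 2)
    drift <- profile$drift_amplitude_bpm * sin(pi * u + phase) -
      profile$drift_amplitude_bpm * mean(sin(pi * u + phase))
    if (!is.null(profile$ultradian_amplitude_bpm) &&
        profile$ultradian_amplitude_bpm > 0) {
      period_s <- if (!is.null(profile$ultradian_period_s)) {
        profile$ultradian_period_s * stats::runif(1, 0.97, 1.03)
      } else 60 * profile$ultradian_period_min * stats::runif(1, 0.85, 1.15)
      uphase <- if (!is.null(profile$ultradian_phase)) {
        profile$ultradian_phase + stats::rnorm(1, 0, 0.1)
      } else stats::runif(1, 0, 2 * pi)
      cyc <- sin(2 * pi * tt / period_s + uphase)
      ucyc <- profile$ultradian_amplitude_bpm * cyc
      drift <- drift + ucyc - mean(ucyc)
      rem_amp <- profile$rem_amplitude_bpm %||% 0
      if (rem_amp > 0) {
        # REM-like phase: HR elevated while the cycle is near its crest,
        # entered and left over a couple of samples (soft step)
        rem <- rem_amp * stats::plogis((cyc - 0.55) / 0.08)
        drift <- drift + rem - mean(rem)
      }
    }
    level <- numeric(n)
    if (profile$n_stage_shifts > 0) {
      # sleep stages are discrete: a three-rung ladder (deep / light /
      # REM-like) walked one rung at a time, deep at -1 and REM at +1
      # rung, with a small per-segment jitter. Bounded by construction,
      # so every night visits the same level set.
      cps <- sort(sample.int(n - 2L, profile$n_stage_shifts) + 1L)
      bounds <- c(1L, cps, n + 1L)
      state <- 0L
      for (k in seq_len(length(bounds) - 1L)) {
        state <- max(-1L, min(1L, state + sample(c(-1L, 1L), 1L)))
        level[bounds[k]:(bounds[k + 1L] - 1L)] <-
          state * profile$stage_shift_sd_bpm + stats::rnorm(1, 0, 0.5)
      }
      level <- level - mean(level)
    }
    noise <- numeric(n)
    if (profile$noise_sd_bpm > 0) {
      ar <- profile$ar_coefficient
      noise[1] <- stats::rnorm(1, 0, profile$noise_sd_bpm / sqrt(1 - ar^2))
      if (n > 1) {
        eps <- stats::rnorm(n - 1, 0, profile$noise_sd_bpm)
        for (i in 2:n) noise[i] <- ar * noise[i - 1] + eps[i - 1]
      }
    }
    bpm <- pmax(profile$baseline_bpm + drift + level + noise, 1e-3)
    hr_series(tt, bpm, profile$interval_seconds, participant_id, night_index)
  })
}

# Non-overlapping anomaly segment placement outside the edge trim zones.
.place_segments <- function(n, interval_seconds, len_ranges, trim_minutes = 30) {
  guard <- as.integer(trim_minutes * 60 / interval_seconds)
  lo <- guard + 1L
  hi <- n - guard
  taken <- rep(FALSE, n)
  n_seg <- length(len_ranges)
  segs <- vector("list", n_seg)
  for (k in seq_len(n_seg)) {
    len_range <- len_ranges[[k]]
    len <- if (len_range[1] == len_range[2]) len_range[1] else
      sample(seq.int(len_range[1], len_range[2]), 1L)
    ok_starts <- which(vapply(lo:(hi - len + 1L), function(s) {
      all(!taken[max(lo, s - 1L):min(hi, s + len)])  # keep a 1-point gap
    }, logical(1)))
    if (length(ok_starts) == 0L) {
      stop("series too short to host the requested anomaly segments")
    }
    s <- (lo:(hi - len + 1L))[ok_starts[sample.int(length(ok_starts), 1L)]]
    taken[s:(s + len - 1L)] <- TRUE
    segs[[k]] <- seq.int(s, s + len - 1L)
  }
  segs
}

#' Inject global and contextual anomalies into a clean night
#'
#' Global segments are rewritten to `night mean +/- global_magnitude_sd *
#' SD(night)` (plus a small within-segment jitter), which places them
#' outside the clean night's observed range. Contextual segments are offset
#' by `contextual_magnitude_sd` local SDs (15-point neighbourhood) and
#' clipped to remain inside the clean global range.
#'
#' @param series A clean [hr_series()].
#' @param spec An [anomaly_spec()].
#' @return A list with elements `series` (perturbed) and `mask`
#'   (a [label_mask()] marking exactly the perturbed points).
#' @export
inject_anomalies <- function(series, spec) {
  stopifnot(inherits(series, "hr_series"), inherits(spec, "anomaly_spec"))
  n <- length(series$bpm)
  flags <- rep(FALSE, n)
  n_seg <- spec$n_global + spec$n_contextual
  if (n_seg == 0L) return(list(series = series, mask = label_mask(flags)))
  guard <- as.integer(30 * 60 / series$interval_seconds)
  need <- 2L * guard + spec$n_global * (spec$global_segment_length_range[2] + 1L) +
    spec$n_contextual * (spec$segment_length_range[2] + 1L)
  if (n < need) stop("series too short to host the requested anomaly segments")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  clean <- series$bpm
  sd_night <- stats::sd(clean)
  mu_night <- mean(clean)
  lo_clean <- min(clean)
  hi_clean <- max(clean)
  kinds <- c(rep("global", spec$n_global), rep("contextual", spec$n_contextual))
  len_ranges <- lapply(kinds, function(k) {
    if (k == "global") spec$global_segment_length_range else spec$segment_length_range
  })
  segs <- .place_segments(n, series$interval_seconds, len_ranges)
  bpm <- clean
  for (k in seq_len(n_seg)) {
    idx <- segs[[k]]
    sgn <- sample(c(-1, 1), 1L)
    if (kinds[k] == "global") {
      # per-point magnitude >= global_magnitude_sd night-SDs, spread upward
      # so spike episodes vary in amplitude as real ones do
      sdn <- max(sd_night, 1e-8)
      mag <- (spec$global_magnitude_sd + abs(stats::rnorm(length(idx), 0, 0.75))) * sdn
      bpm[idx] <- pmax(mu_night + sgn * mag, 1e-3)
    } else {
      w <- 30L
      # tapered onset: shoulders at ~max(3, m - 0.5) local SDs, peak at the
      # configured magnitude, so the episode builds up rather than stepping
      L <- length(idx)
      taper <- if (L == 1L) spec$contextual_magnitude_sd else {
        lo <- max(spec$contextual_magnitude_sd - 0.5, 3)
        lo + (spec$contextual_magnitude_sd - lo) * sin(pi * seq_len(L) / (L + 1L))
      }
      for (j in seq_along(idx)) {
        i <- idx[j]
        # local scale over a one-hour neighbourhood (stable estimate of
        # the night's short-range variability)
        nb <- setdiff(max(1L, i - w):min(n, i + w), idx)
        loc_sd <- max(stats::sd(clean[nb]), 1e-8)
        cand <- clean[i] + sgn * taper[j] * loc_sd
        if (cand > hi_clean || cand < lo_clean) {
          cand <- clean[i] - sgn * spec$contextual_magnitude_sd * loc_sd
        }
        eps_rng <- 1e-6 * max(1, abs(hi_clean))
        cand <- min(max(cand, lo_clean + eps_rng), hi_clean - eps_rng)
        if (abs(cand - clean[i]) < 1e-9) cand <- clean[i] + loc_sd  # degenerate night
        bpm[i] <- max(cand, 1e-3)
      }
    }
    flags[idx] <- TRUE
  }
  out <- series
  out$bpm <- bpm
  src <- list(global = rep(FALSE, n), contextual = rep(FALSE, n))
  for (k in seq_len(n_seg)) src[[kinds[k]]][segs[[k]]] <- TRUE
  list(series = out, mask = label_mask(flags, source = src))
}

#' Simulate a participant: several nights with injected anomalies
#'
#' Nights share the profile but use distinct derived seeds
#' (`master seed * 1000 + night index` for the signal, `+500` offset for
#' injection), so adding nights never reshuffles earlier ones.
#'
#' @param profile A [night_profile()]; its `seed` acts as the master seed.
#' @param spec An [anomaly_spec()] applied to every night.
#' @param n_nights Number of nights (>= 3; the study design uses 7).
#' @return A list of `n_nights` elements, each `list(series, mask)`.
#' @export
simulate_participant <- function(profile, spec, n_nights = 7L, participant_id = "P1") {
  if (n_nights < 3L) stop("n_nights must be >= 3 (train/validation/test split impossible)")
  if (is.null(profile$drift_phase)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed((profile$seed %% 1000000L) * 7L + 3L)
    profile$drift_phase <- stats::runif(1, 0, pi / 2)
    profile$ultradian_period_s <- 60 * profile$ultradian_period_min * stats::runif(1, 0.85, 1.15)
    profile$ultradian_phase <- stats::runif(1, 0, 2 * pi)
  }
  lapply(seq_len(n_nights) - 1L, function(night) {
    p <- profile
    p$seed <- (profile$seed %% 1000000L) * 1000L + night
    s <- spec
    s$seed <- (spec$seed %% 1000000L) * 1000L + 500L + night
    night_series <- simulate_night(p, participant_id, night)
    inject_anomalies(night_series, s)
  })
}

#' Write / read one night as CSV (+ JSON sidecar)
#'
#' Columns: `timestamp_s,bpm[,label]`. The sidecar stores the generating
#' profile/spec when supplied.
#'
#' @rdname night_io
#' @export
write_night_csv <- function(series, path, mask = NULL, sidecar = NULL) {
  df <- data.frame(timestamp_s = series$t, bpm = series$bpm)
  if (!is.null(mask)) df$label <- as.integer(mask$flags)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname night_io
#' @export
read_night_csv <- function(path, interval_seconds = NULL,
                           participant_id = "P1", night_index = 0L) {
  df <- utils::read.csv(path)
  if (!all(c("timestamp_s", "bpm") %in% names(df))) {
    stop("night CSV must have columns timestamp_s,bpm[,label]")
  }
  if (is.null(interval_seconds)) {
    interval_seconds <- as.integer(round(stats::median(diff(df$timestamp_s))))
  }
  s <- hr_series(df$timestamp_s, df$bpm, interval_seconds, participant_id, night_index)
  mask <- if ("label" %in% names(df)) label_mask(df$label != 0) else NULL
  list(series = s, mask = mask)
}
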