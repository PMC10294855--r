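# Small fixtures shared across test files; everything is generated in code.

quiet_profile <- function(duration_minutes = 120L, ...) {
  night_profile(duration_minutes = duration_minutes, interval_seconds = 60L,
                drift_amplitude_bpm = 0, ultradian_amplitude_bpm = 0,
                n_stage_shifts = 0L, noise_sd_bpm = 0, ...)
}

series_from <- function(bpm, interval = 60L) {
  hr_series((seq_along(bpm) - 1) * interval, bpm, interval)
}

# independent oracle for the tumbling-window rule: explicit loop over
# enumerated windows, recomputing mean and SD from scratch
sw_oracle <- function(x, window_fraction = 0.03, k = 3) {
  n <- length(x)
  w <- max(3L, as.integer(floor(window_fraction * n + 0.5)))
  n_win <- n %/% w
  flags <- rep(FALSE, n)
  for (j in seq_len(n_win)) {
    from <- (j - 1L) * w + 1L
    to <- if (j == n_win) n else j * w
    seg <- x[from:to]
    mu <- sum(seg) / length(seg)
    sdp <- sqrt(sum((seg - mu)^2) / length(seg))
    for (i in from:to) flags[i] <- abs(x[i] - mu) > k * sdp
  }
  flags
}

# hand-enumerated point-adjust oracle
adjust_oracle <- function(pred, truth) {
  out <- pred
  i <- 1L
  n <- length(truth)
  while (i <= n) {
    if (truth[i]) {
      j <- i
      while (j < n && truth[j + 1L]) j <- j + 1L
      if (any(pred[i:j])) out[i:j] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}
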