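test_that("a profile with all stochastic terms disabled yields a constant night", {
  s <- simulate_night(quiet_profile(baseline_bpm = 60))
  expect_length(s$bpm, 120L)
  expect_true(all(s$bpm == 60))
  expect_equal(diff(s$t), rep(60, 119))
})

test_that("simulation is a pure function of the profile seed", {
  p <- night_profile(duration_minutes = 420L, interval_seconds = 60L, seed = 7L)
  s1 <- simulate_night(p)
  s2 <- simulate_night(p)
  expect_identical(s1$bpm, s2$bpm)
  p2 <- night_profile(duration_minutes = 420L, interval_seconds = 30L, seed = 7L)
  expect_length(simulate_night(p2)$bpm, 840L)
})

test_that("invalid profiles name the offending field", {
  expect_error(night_profile(interval_seconds = 45L), "interval_seconds")
  expect_error(night_profile(ar_coefficient = 1.2), "ar_coefficient")
  expect_error(night_profile(noise_sd_bpm = -1), "noise_sd_bpm")
})

test_that("detrended AR(1) noise has the configured lag-1 autocorrelation", {
  # sample-ACF oracle over long runs; drift/shift terms disabled so the
  # noise process is observed directly
  acfs <- vapply(1:20, function(sd) {
    p <- night_profile(duration_minutes = 480L, interval_seconds = 30L,
                       drift_amplitude_bpm = 0, ultradian_amplitude_bpm = 0,
                       n_stage_shifts = 0L, noise_sd_bpm = 1.5,
                       ar_coefficient = 0.8, seed = sd)
    x <- simulate_night(p)$bpm
    stats::acf(x - mean(x), lag.max = 1, plot = FALSE)$acf[2]
  }, numeric(1))
  expect_lt(abs(mean(acfs) - 0.8), 0.1)
})

test_that("the clean-signal marginal SD matches the AR(1) stationary value", {
  p <- night_profile(duration_minutes = 480L, interval_seconds = 30L,
                     drift_amplitude_bpm = 0, ultradian_amplitude_bpm = 0,
                     n_stage_shifts = 0L, noise_sd_bpm = 2,
                     ar_coefficient = 0.6, seed = 3L)
  implied <- 2 / sqrt(1 - 0.6^2)
  sds <- vapply(1:10, function(sd) {
    p$seed <- sd
    stats::sd(simulate_night(p)$bpm)
  }, numeric(1))
  expect_true(all(sds > implied * 0.5 & sds < implied * 1.5))
})

test_that("an empty anomaly spec leaves the night untouched", {
  s <- simulate_night(night_profile(seed = 5L))
  out <- inject_anomalies(s, anomaly_spec(n_global = 0L, n_contextual = 0L))
  expect_identical(out$series$bpm, s$bpm)
  expect_false(any(out$mask$flags))
})

test_that("global anomalies offset by at least the configured night-SD multiple", {
  p <- night_profile(duration_minutes = 420L, drift_amplitude_bpm = 0,
                     ultradian_amplitude_bpm = 0, n_stage_shifts = 0L,
                     noise_sd_bpm = 2, ar_coefficient = 0, seed = 21L)
  s <- simulate_night(p)
  sp <- anomaly_spec(n_global = 1L, n_contextual = 0L,
                     global_segment_length_range = c(1L, 1L), seed = 21L)
  out <- inject_anomalies(s, sp)
  i <- which(out$mask$flags)
  expect_length(i, 1L)
  # recompute the offset from the night's realized SD and mean
  expect_gte(abs(out$series$bpm[i] - mean(s$bpm)), 6 * stats::sd(s$bpm))
})

test_that("the truth mask marks exactly the perturbed points", {
  s <- simulate_night(night_profile(seed = 9L))
  out <- inject_anomalies(s, anomaly_spec(seed = 9L))
  changed <- out$series$bpm != s$bpm
  expect_identical(out$mask$flags, changed)
  expect_identical(sum(out$mask$flags),
                   sum(out$mask$source$global) + sum(out$mask$source$contextual))
})

test_that("anomalous segments avoid the 30-minute edge trim zones", {
  for (sd in 1:5) {
    s <- simulate_night(night_profile(seed = sd))
    out <- inject_anomalies(s, anomaly_spec(seed = sd))
    idx <- which(out$mask$flags)
    expect_true(all(idx > 30 & idx <= length(s$bpm) - 30))
  }
})

test_that("a short series cannot host the requested segments", {
  s <- simulate_night(night_profile(duration_minutes = 70L, seed = 1L))
  expect_error(inject_anomalies(s, anomaly_spec(seed = 1L)), "too short")
})

test_that("global anomalies leave the clean range and contextual ones stay inside", {
  n_out <- 0L; n_glob <- 0L; n_in <- 0L; n_ctx <- 0L
  for (sd in 1:25) {
    s <- simulate_night(night_profile(seed = sd))
    out <- inject_anomalies(s, anomaly_spec(seed = sd + 100L))
    rng <- range(s$bpm)
    g <- which(out$mask$source$global)
    ctx <- which(out$mask$source$contextual)
    n_glob <- n_glob + length(g)
    n_out <- n_out + sum(out$series$bpm[g] < rng[1] | out$series$bpm[g] > rng[2])
    n_ctx <- n_ctx + length(ctx)
    n_in <- n_in + sum(out$series$bpm[ctx] >= rng[1] & out$series$bpm[ctx] <= rng[2])
  }
  expect_gte(n_out / n_glob, 0.9)
  expect_gte(n_in / n_ctx, 0.9)
})

test_that("a participant's nights are distinct, seeded and sized on request", {
  prof <- night_profile(seed = 31L)
  sp <- anomaly_spec(seed = 31L)
  nights <- simulate_participant(prof, sp, n_nights = 7L)
  expect_length(nights, 7L)
  for (a in 1:6) for (b in (a + 1):7) {
    expect_false(identical(nights[[a]]$series$bpm, nights[[b]]$series$bpm))
  }
  again <- simulate_participant(prof, sp, n_nights = 7L)
  expect_identical(nights[[7]]$series$bpm, again[[7]]$series$bpm)
  expect_identical(nights[[7]]$mask$flags, again[[7]]$mask$flags)
  expect_error(simulate_participant(prof, sp, n_nights = 2L), "n_nights")
})

test_that("the generator can be sized to a prescribed test-night anomaly count", {
  # 33 anomalous points, the largest per-night count reported for the
  # 30-second sampling scenario
  prof <- night_profile(interval_seconds = 30L, seed = 13L)
  sp <- anomaly_spec(n_global = 11L, n_contextual = 22L,
                     segment_length_range = c(1L, 1L),
                     global_segment_length_range = c(1L, 1L), seed = 13L)
  nights <- simulate_participant(prof, sp, n_nights = 7L)
  expect_identical(sum(nights[[7]]$mask$flags), 33L)
})

test_that("night CSV round-trips values, labels and spacing", {
  s <- simulate_night(night_profile(seed = 2L))
  out <- inject_anomalies(s, anomaly_spec(seed = 2L))
  f <- tempfile(fileext = ".csv")
  write_night_csv(out$series, f, out$mask, sidecar = list(seed = 2L))
  back <- read_night_csv(f)
  expect_equal(back$series$bpm, out$series$bpm)
  expect_identical(back$mask$flags, out$mask$flags)
  expect_identical(back$series$interval_seconds, 60L)
  expect_true(file.exists(sub("\\.csv$", ".json", f)))
  unlink(c(f, sub("\\.csv$", ".json", f)))
})
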