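test_that("sleep-edge trimming removes 30 minutes per side and re-anchors time", {
  s60 <- simulate_night(night_profile(duration_minutes = 420L, interval_seconds = 60L, seed = 1L))
  t60 <- trim_sleep_edges(s60)
  expect_length(t60$bpm, 360L)
  expect_identical(t60$t[1], 0)
  s30 <- simulate_night(night_profile(duration_minutes = 420L, interval_seconds = 30L, seed = 1L))
  expect_length(trim_sleep_edges(s30)$bpm, 720L)
  s_short <- simulate_night(quiet_profile(duration_minutes = 50L))
  expect_error(trim_sleep_edges(s_short), "too short")
})

test_that("unsupervised detectors respect the contamination bound on a constant series", {
  s <- series_from(rep(60, 200))
  cfg <- labeler_config(contamination = 0.02, seed = 1L)
  for (m in c("if", "ocsvm", "kde")) {
    fl <- detect_unsupervised(s, m, cfg)$flags
    expect_lte(mean(fl), 0.02 + 1e-9)
  }
})

test_that("a 6-SD spike is flagged by all three unsupervised detectors", {
  set.seed(5)
  x <- rnorm(400, 60, 2)
  x[123] <- 60 + 6 * sd(x)
  s <- series_from(x)
  cfg <- labeler_config(contamination = 0.02, seed = 5L)
  for (m in c("if", "ocsvm", "kde")) {
    expect_true(detect_unsupervised(s, m, cfg)$flags[123],
                label = paste("spike flagged by", m))
  }
  # the spike also tops each method's own ranking: highest isolation
  # score and lowest density
  sc_if <- iforest_score(matrix(x, ncol = 1), seed = 5L)
  expect_identical(which.max(sc_if), 123L)
  bw <- stats::bw.nrd0(x)
  dens <- vapply(x, function(xi) mean(stats::dnorm((xi - x) / bw)) / bw, numeric(1))
  expect_identical(which.min(dens), 123L)
})

test_that("unsupervised detection is deterministic given the config seed", {
  s <- simulate_night(night_profile(seed = 8L))
  cfg <- labeler_config(seed = 17L)
  for (m in c("if", "ocsvm", "kde")) {
    expect_identical(detect_unsupervised(s, m, cfg)$flags,
                     detect_unsupervised(s, m, cfg)$flags)
  }
})

test_that("the tumbling-window rule never flags a constant series", {
  s <- series_from(rep(72, 300))
  expect_false(any(detect_sliding_window(s)$flags))
})

test_that("a single extreme point inflates its segment SD enough to escape the rule", {
  # hand-computed: segment [60 x9, 100]: mean 64, population SD
  # sqrt((9*16 + 36^2)/10) = 12, |100-64| = 36 <= 3*12 -> not flagged;
  # sample SD 12.65 gives the same verdict
  seg <- c(rep(60, 9), 100)
  m <- mean(seg)
  expect_equal(m, 64)
  sd_pop <- sqrt(mean((seg - m)^2))
  expect_equal(sd_pop, 12)
  s <- series_from(seg)
  expect_false(any(detect_sliding_window(s, window_fraction = 1, k = 3)$flags))
  expect_false(any(detect_sliding_window(s, window_fraction = 1, k = 3,
                                         sd_type = "sample")$flags))
})

test_that("the window rule matches a brute-force oracle on random series", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(200:2000, 1)
    interval <- sample(c(30L, 60L), 1)
    x <- rnorm(n, 60, 3)
    x[sample(n, 5)] <- x[sample(n, 5)] + rnorm(5, 0, 15)
    s <- series_from(x, interval)
    expect_identical(detect_sliding_window(s)$flags, sw_oracle(x),
                     label = paste("series", rep))
  }
})

test_that("lowering the window-rule multiplier never removes a flag", {
  set.seed(7)
  x <- rnorm(500, 60, 3) + rt(500, df = 3)
  s <- series_from(x)
  f3 <- detect_sliding_window(s, k = 3)$flags
  f2 <- detect_sliding_window(s, k = 2)$flags
  expect_true(all(f2[f3]))
})

test_that("the combined label follows (IF & OCSVM & KDE) | SW exactly", {
  s <- simulate_night(night_profile(seed = 19L))
  out <- inject_anomalies(s, anomaly_spec(seed = 19L))
  m <- label_anomalies(trim_sleep_edges(out$series), labeler_config(seed = 19L))
  src <- m$source
  expect_identical(m$flags, (src$`if` & src$ocsvm & src$kde) | src$sw)
  expect_identical(src$ensemble, src$`if` & src$ocsvm & src$kde)
  # independent set-algebra oracle over index sets
  union_oracle <- sort(union(
    intersect(intersect(which(src$`if`), which(src$ocsvm)), which(src$kde)),
    which(src$sw)))
  expect_identical(which(m$flags), as.integer(union_oracle))
})

test_that("clean_training carries the previous non-anomalous value forward", {
  s <- series_from(c(60, 61, 95, 62))
  out <- clean_training(s, label_mask(c(FALSE, FALSE, TRUE, FALSE)))
  expect_equal(out$bpm, c(60, 61, 61, 62))
  s2 <- series_from(c(60, 95, 96, 62))
  out2 <- clean_training(s2, label_mask(c(FALSE, TRUE, TRUE, FALSE)))
  expect_equal(out2$bpm, c(60, 60, 60, 62))
  # all-false mask is the identity
  expect_equal(clean_training(s, label_mask(rep(FALSE, 4)))$bpm, s$bpm)
  # flagged head takes the first subsequent clean value
  s3 <- series_from(c(95, 96, 60, 62))
  out3 <- clean_training(s3, label_mask(c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(out3$bpm, c(60, 60, 60, 62))
  expect_error(clean_training(s, label_mask(rep(TRUE, 4))), "clean")
})

test_that("build_split produces a cleaned 5/1/1 split by night order", {
  prof <- night_profile(seed = 23L)
  sp <- anomaly_spec(seed = 23L)
  nights <- simulate_participant(prof, sp, n_nights = 7L)
  labeled <- lapply(nights, function(nt) {
    s <- trim_sleep_edges(nt$series)
    list(series = s, mask = label_anomalies(s, labeler_config(seed = 23L)))
  })
  split <- build_split(labeled)
  expect_length(split$train, 5L)
  for (i in 1:5) {
    flags <- split$train_masks[[i]]$flags
    # every flagged position now holds the value of a preceding clean point
    cleaned <- split$train[[i]]$bpm
    orig <- labeled[[i]]$series$bpm
    expect_true(all(cleaned[!flags] == orig[!flags]))
    expect_true(all(cleaned[flags] != orig[flags] | !flags[flags]))
  }
  expect_identical(split$validation$series$bpm, labeled[[6]]$series$bpm)
  expect_identical(split$test$series$bpm, labeled[[7]]$series$bpm)
  expect_error(build_split(labeled[1:6]), "7 nights")
})

test_that("auto-labeling recalls most injected global anomalies", {
  # the intersection of the three detectors is meant to find global
  # outliers with high confidence; average recall over seeds
  tot <- 0L; caught <- 0L
  for (sd in 1:12) {
    nights <- simulate_participant(night_profile(seed = sd), anomaly_spec(seed = sd), 7L)
    nt <- nights[[7]]
    s <- trim_sleep_edges(nt$series)
    truth_g <- trim_mask(nt$mask, nt$series)$source$global
    m <- label_anomalies(s, labeler_config(seed = sd))
    tot <- tot + sum(truth_g)
    caught <- caught + sum(m$flags & truth_g)
  }
  expect_gte(caught / tot, 0.8)
})
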