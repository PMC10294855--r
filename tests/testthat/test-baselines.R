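test_that("the ADF check separates random walks from stationary noise", {
  set.seed(1)
  walk_flags <- vapply(1:20, function(i) adf_check(cumsum(rnorm(300)))$is_stationary,
                       logical(1))
  expect_gte(sum(!walk_flags), 18)
  noise_flags <- vapply(1:20, function(i) adf_check(rnorm(300, 60, 2))$is_stationary,
                        logical(1))
  expect_gte(sum(noise_flags), 18)
  expect_error(adf_check(rep(60, 50)), "constant")
  expect_error(adf_check(rnorm(10)), "at least 20")
})

test_that("AIC order selection recovers simple generating processes", {
  # AR(2) with coefficients (0.6, -0.3): the true order should win most seeds
  hits <- 0L
  for (sd in 1:8) {
    set.seed(sd)
    y <- as.numeric(arima.sim(list(ar = c(0.6, -0.3)), n = 800)) + 60
    ord <- select_arma_order(y, max_p = 3L, max_q = 2L)
    hits <- hits + (ord$p == 2L && ord$q == 0L)
  }
  expect_gte(hits, 6L)
  # white noise prefers (0,0)
  wn_hits <- 0L
  for (sd in 1:8) {
    set.seed(100 + sd)
    ord <- select_arma_order(rnorm(600, 60, 2), max_p = 2L, max_q = 2L)
    wn_hits <- wn_hits + (ord$p == 0L && ord$q == 0L)
  }
  expect_gte(wn_hits, 5L)
  # degenerate grid
  ord0 <- select_arma_order(rnorm(200, 60, 2), max_p = 0L, max_q = 0L)
  expect_identical(c(ord0$p, ord0$q), c(0L, 0L))
})

test_that("ARIMA squared one-step errors are zero on constant data and rank spikes first", {
  const_nights <- list(series_from(rep(60, 150)), series_from(rep(60, 150)))
  fit0 <- hr_arima(const_nights, order = c(0L, 0L))
  sc0 <- hr_score(fit0, series_from(rep(60, 100)))
  expect_true(all(sc0$scores < 1e-10))
  # an injected spike has the night's largest squared error
  set.seed(12)
  nights <- lapply(1:2, function(i) {
    series_from(60 + as.numeric(arima.sim(list(ar = 0.7), n = 300, sd = 1.5)))
  })
  fit <- hr_arima(nights, max_p = 2L, max_q = 1L)
  x <- 60 + as.numeric(arima.sim(list(ar = 0.7), n = 300, sd = 1.5))
  x[170] <- x[170] + 6 * sd(x)
  sc <- hr_score(fit, series_from(x))
  expect_identical(sc$indices[which.max(sc$scores)], 170L)
  expect_identical(length(sc$scores), 300L)
})

test_that("one LSTM cell step follows the gate equations exactly", {
  # independent scalar implementation of the forget/input/output gate
  # update, checked against the vectorised layer to 1e-10
  set.seed(5)
  H <- 3L
  p <- hranomaly:::lstm_init(2L, H)
  x <- matrix(rnorm(2), 1, 2)
  sig <- function(a) 1 / (1 + exp(-a))
  h0 <- rep(0, H); c0 <- rep(0, H)
  z <- as.numeric(x %*% p$W) + as.numeric(h0 %*% p$U) + as.numeric(p$b)
  i_g <- sig(z[1:3]); f_g <- sig(z[4:6]); c_c <- tanh(z[7:9]); o_g <- sig(z[10:12])
  c1 <- f_g * c0 + i_g * c_c
  h1 <- o_g * tanh(c1)
  expect_true(all(i_g > 0 & i_g < 1))
  expect_true(all(abs(c_c) < 1))
  tape <- hranomaly:::ad_tape()
  hs <- hranomaly:::lstm_seq(tape, list(x), p$W, p$U, p$b, H)
  expect_lt(max(abs(hranomaly:::ad_val(hs[[1]]) - h1)), 1e-10)
})

test_that("a forecaster trained on constant nights predicts the constant", {
  nights <- lapply(1:2, function(i) series_from(rep(60, 120)))
  cfg <- net_config(layer_sizes = c(8L, 4L), input_window = 8L,
                    dropout_rate = 0, batch_size = 64L, max_epochs = 80L,
                    learning_rate = 3e-3, seed = 2L)
  fit <- hr_lstm(nights, config = cfg)
  pred <- predict(fit, series_from(rep(60, 60)))
  expect_true(all(abs(pred - 60) < 0.5))
})

test_that("max-norm keeps every weight and bias norm within the bound", {
  set.seed(3)
  nights <- list(series_from(60 + rnorm(200, 0, 3)))
  cfg <- net_config(layer_sizes = c(8L, 4L), input_window = 8L,
                    batch_size = 64L, max_epochs = 10L, maxnorm_bound = 3,
                    seed = 3L)
  fit <- hr_bilstm(nights, config = cfg)
  expect_lte(hranomaly:::maxnorm_max(fit$params), 3 + 1e-6)
})

test_that("a noiseless sine wave is learnable to a small one-step error", {
  x <- 60 + 5 * sin(seq(0, 14 * pi, length.out = 420))
  nights <- list(series_from(x[1:300]))
  cfg <- net_config(layer_sizes = c(16L, 8L), input_window = 16L,
                    dropout_rate = 0, batch_size = 128L, max_epochs = 150L,
                    learning_rate = 3e-3, seed = 8L)
  fit <- hr_lstm(nights, config = cfg)
  held <- series_from(x[301:420])
  sc <- hr_score(fit, held)
  expect_lt(mean(sc$scores), 0.01 * var(held$bpm))
})

test_that("training reports divergence with advice instead of NaNs", {
  # max-norm keeps the detector configs from ever overflowing, so the
  # guard is exercised directly with a loss that goes non-finite
  params <- list(w = matrix(0, 1, 1))
  bad_loss <- function(tape, pn, idx) hranomaly:::.ad_push(tape, NaN)
  expect_error(hranomaly:::nn_train(params, bad_loss, n_obs = 8L),
               "learning rate")
})

test_that("the CAE compresses 32-point windows to 4-dim embeddings and mirrors back", {
  set.seed(9)
  W <- matrix(rnorm(40 * 32), 40, 32)
  cae_untrained <- structure(list(params = hranomaly:::.cae_init(cae_config()),
                                  config = cae_config()), class = "hr_cae")
  z <- cae_encode(cae_untrained, W)
  expect_identical(dim(z), c(40L, 4L))
  xr <- cae_decode(cae_untrained, z)
  expect_identical(dim(xr), c(40L, 32L))
  expect_error(cae_config(sample_length = 30L), "latent_dim")
})

test_that("CAE training beats an untrained model by a wide margin", {
  set.seed(10)
  t <- seq(0, 4 * pi, length.out = 32)
  Xtr <- t(vapply(1:150, function(i) {
    sin(t + runif(1, 0, 2 * pi)) * runif(1, 0.5, 1.5)
  }, numeric(32)))
  cfg <- cae_config(batch_size = 32L, max_epochs = 300L, learning_rate = 5e-3,
                    dropout_rate = 0, seed = 10L)
  before <- local({
    cae0 <- structure(list(params = local({
      set.seed(10); hranomaly:::.cae_init(cfg)
    }), config = cfg), class = "hr_cae")
    mean((cae_decode(cae0, cae_encode(cae0, Xtr)) - Xtr)^2)
  })
  cae <- fit_cae(Xtr, cfg)
  after <- mean((cae_decode(cae, cae_encode(cae, Xtr)) - Xtr)^2)
  expect_lt(after * 10, before)
  # constant windows reconstruct almost exactly
  Xc <- matrix(0.5, 60, 32)
  cae_c <- fit_cae(Xc, cae_config(batch_size = 32L, max_epochs = 200L,
                                  learning_rate = 5e-3,
                                  dropout_rate = 0, seed = 2L))
  expect_lt(mean((cae_decode(cae_c, cae_encode(cae_c, Xc)) - Xc)^2), 0.01)
})

test_that("the CAE-LSTM detector assigns window scores to the right points", {
  prof <- night_profile(seed = 55L)
  nights <- simulate_participant(prof, anomaly_spec(seed = 55L), 7L)
  trimmed <- lapply(nights, function(nt) trim_sleep_edges(nt$series))
  cfg <- cae_config(max_epochs = 15L, batch_size = 128L, seed = 55L)
  fit <- hr_cae_lstm(trimmed[1:5], trimmed[[6]], cfg)
  sc <- hr_score(fit, trimmed[[7]])
  n <- length(trimmed[[7]]$bpm)
  K <- n %/% 32L
  expect_identical(sc$indices, 65:(K * 32L))
  # the top-scoring window contains the top-scoring true segment
  truth_g <- trim_mask(nights[[7]]$mask, nights[[7]]$series)$source$global
  covered <- truth_g[sc$indices]
  if (any(covered)) {
    expect_gt(max(sc$scores[covered]), stats::quantile(sc$scores, 0.9))
  }
})
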