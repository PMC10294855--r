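test_that("window partition bookkeeping is exact and round-trips", {
  x <- seq_len(360) + 0.5
  wb <- make_windows(x, 10L)
  expect_identical(wb$n_windows, 36L)
  expect_length(wb$remainder, 0L)
  x2 <- seq_len(365)
  wb2 <- make_windows(x2, 10L)
  expect_identical(wb2$n_windows, 36L)
  expect_identical(wb2$remainder, 361:365)
  # concatenating windows plus remainder reproduces the series
  expect_identical(c(as.numeric(t(wb2$X)), x2[wb2$remainder]), as.numeric(x2))
  expect_identical(wb2$point_index[[3]], 21:30)
  expect_error(make_windows(1:15, 10L), "two windows")
})

test_that("reparameterization follows the printed sampling rule", {
  mu <- c(0.5, -1, 2, 0)
  s2 <- c(1, 0.5, 2, 0.1)
  expect_equal(reparameterize(mu, s2, rep(0, 4)), mu)
  expect_equal(reparameterize(rep(0, 4), rep(1, 4), c(1, -2, 3, 0.5)),
               c(1, -2, 3, 0.5))
  eps <- c(1, 1, 1, 1)
  expect_equal(reparameterize(mu, s2, eps, "variance"), mu + s2)
  expect_equal(reparameterize(mu, s2, eps, "sd"), mu + sqrt(s2))
  expect_error(reparameterize(mu, c(1, 0, 1, 1), eps), "positive")
})

test_that("sampled z reproduces the moments implied by each convention", {
  set.seed(14)
  mu <- 0.7; s2 <- 1.6
  n <- 1e5
  eps <- rnorm(n)
  zv <- reparameterize(rep(mu, n), rep(s2, n), eps, "variance")
  expect_lt(abs(mean(zv) - mu), 0.02 * s2)
  expect_lt(abs(sd(zv) - s2), 0.02)          # SD = sigma^2 under the printed rule
  zs <- reparameterize(rep(mu, n), rep(s2, n), eps, "sd")
  expect_lt(abs(sd(zs) - sqrt(s2)), 0.02)
})

test_that("the VAE loss decomposes into reconstruction and weighted KL", {
  x <- c(1, 2, 3)
  # perfect reconstruction at the prior: both terms vanish
  l0 <- vae_loss(x, x, mu = rep(0, 4), sigma2 = rep(1, 4), beta = 3)
  expect_equal(l0$total, 0)
  # KL of a unit-mean one-hot posterior is mu^2 / 2 = 0.5
  l1 <- vae_loss(x, x, mu = c(1, 0, 0, 0), sigma2 = rep(1, 4), beta = 3)
  expect_equal(l1$kl_term, 0.5)
  expect_equal(l1$total, 1.5)
  # reconstruction is the squared Euclidean distance
  l2 <- vae_loss(c(1, 2), c(0, 0), mu = rep(0, 2), sigma2 = rep(1, 2), beta = 1)
  expect_equal(l2$recon_term, 5)
  expect_error(vae_loss(x, x, 0, -1), "positive")
  expect_error(vae_loss(x, x[1:2], 0, 1), "equal length")
})

test_that("closed-form KL matches a Monte-Carlo estimate within 3 SE", {
  set.seed(33)
  n_mc <- 1e5
  for (rep in 1:25) {
    mu <- rnorm(1, 0, 1.5)
    s2 <- exp(rnorm(1, 0, 0.7))
    closed <- 0.5 * (s2 + mu^2 - 1 - log(s2))
    z <- rnorm(n_mc, mu, sqrt(s2))
    # E_q[log q(z) - log p(z)]
    diff <- dnorm(z, mu, sqrt(s2), log = TRUE) - dnorm(z, 0, 1, log = TRUE)
    se <- sd(diff) / sqrt(n_mc)
    expect_lt(abs(mean(diff) - closed), 3 * se + 1e-8)
  }
  expect_equal(0.5 * (1 + 0 - 1 - log(1)), 0)  # KL(N(0,1) || N(0,1)) = 0
})

test_that("a fitted VAE reconstructs constant data and is seed-deterministic", {
  nights <- lapply(1:2, function(i) series_from(rep(60, 120)))
  cfg <- vae_config(max_epochs = 30L, batch_size = 12L, seed = 4L)
  v1 <- fit_beta_vae(nights, cfg, std = list(mean = 60, sd = 1))
  Z <- vae_encode(v1, matrix(0, 5, 10))
  XR <- vae_decode(v1, Z$mu)
  expect_true(all(abs(XR) < 0.1))
  v2 <- fit_beta_vae(nights, cfg, std = list(mean = 60, sd = 1))
  expect_identical(v1$params, v2$params)
})

test_that("a heavier KL weight shrinks the KL term at convergence", {
  kl_of <- function(beta, sd) {
    set.seed(sd)
    x <- 60 + 4 * sin(seq(0, 8 * pi, length.out = 240)) + rnorm(240)
    nights <- list(series_from(x))
    cfg <- vae_config(beta = beta, max_epochs = 40L, batch_size = 24L, seed = sd)
    v <- fit_beta_vae(nights, cfg)
    enc <- vae_encode(v, nights[[1]])
    mean(0.5 * rowSums(enc$sigma2 + enc$mu^2 - 1 - log(enc$sigma2)))
  }
  wins <- sum(vapply(1:5, function(sd) kl_of(3, sd) < kl_of(0.1, sd), logical(1)))
  expect_gte(wins, 4)
})

test_that("the latent forecaster learns deterministic embedding patterns", {
  # constant embeddings forecast the constant
  Zc <- matrix(0.5, 30, 4)
  cfg <- vae_config(max_epochs = 60L, batch_size = 16L, seed = 6L)
  fc <- fit_latent_forecaster(list(Zc), cfg)
  pred <- hranomaly:::latent_forecast(fc, Zc[1:2, ])
  expect_equal(dim(pred), c(1L, 4L))
  expect_true(all(abs(pred - 0.5) < 0.1))
  # alternating two-state sequence is learnable from two-step context
  Za <- matrix(rep(c(1, -1), length.out = 40), 40, 4)
  fc2 <- fit_latent_forecaster(list(Za), vae_config(max_epochs = 150L,
                                                    batch_size = 38L, seed = 6L))
  p1 <- hranomaly:::latent_forecast(fc2, Za[1:2, ])   # next is Za[3,] = 1
  expect_lt(mean((p1 - Za[3, ])^2), 0.15)
  expect_error(fit_latent_forecaster(list(Zc[1:2, ]), cfg), "too few")
})

test_that("the full detector scores every window after the context and ranks spikes first", {
  prof <- night_profile(seed = 41L)
  nights <- simulate_participant(prof, anomaly_spec(seed = 41L), 7L)
  trimmed <- lapply(nights, function(nt) trim_sleep_edges(nt$series))
  cfg <- vae_config(max_epochs = 25L, batch_size = 64L, seed = 41L)
  fit <- hr_vae_bilstm(trimmed[1:5], trimmed[[6]], cfg)
  sc <- hr_score(fit, trimmed[[7]])
  n <- length(trimmed[[7]]$bpm)
  K <- n %/% 10
  expect_identical(sc$indices, 21:(K * 10))
  expect_length(sc$scores, length(sc$indices))
  expect_true(all(sc$scores >= 0))
  # the top-scoring point lies in a true global anomaly segment
  truth_g <- trim_mask(nights[[7]]$mask, nights[[7]]$series)$source$global
  top <- sc$indices[which.max(sc$scores)]
  expect_true(truth_g[top])
})
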