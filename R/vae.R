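#' Configuration for the beta-VAE-BiLSTM detector
#'
#' The proposed detector: non-overlapping windows of `window_length` (n =
#' 10) standardized samples are compressed by a variational autoencoder
#' whose encoder and decoder are each a single layer of 64 bidirectional
#' LSTM units with hyperbolic-tangent activation, into latent embeddings of
#' dimensionality `latent_dim` (d = 4). The KL regularisation term is
#' weighted by `beta` (default 3; beta > 1 encourages a disentangled
#' latent space). A BiLSTM module with the detector layer plan
#' (32, 16, 8 cells) is trained over the embeddings z_t to forecast
#' z_{t+1} from the previous and current embeddings; the decoded forecast
#' is compared element-wise with the observed window to score anomalies.
#'
#' @param window_length Window length n (> 1).
#' @param latent_dim Latent dimensionality d (>= 1).
#' @param beta KL weight (> 0); sensitivity grid in the study:
#'   0.1, 0.5, 1, 3, 10.
#' @param units Bidirectional LSTM units in encoder and decoder.
#' @param reparam `"variance"` implements the sampling rule as printed
#'   (z = mu + sigma^2 * eps); `"sd"` uses the conventional
#'   z = mu + sigma * eps.
#' @param forecaster_layers Layer plan of the latent BiLSTM forecaster.
#' @param context_windows Embeddings fed to the forecaster (default 2:
#'   the current and the previous one).
#' @param learning_rate,batch_size,max_epochs,patience,seed Training-loop
#'   settings.
#' @return An object of class `vae_config`.
#' @export
vae_config <- function(window_length = 10L, latent_dim = 4L, beta = 3,
                       units = 64L, reparam = c("variance", "sd"),
                       forecaster_layers = c(32L, 16L, 8L),
                       context_windows = 2L, learning_rate = 1e-3,
                       batch_size = 32L, max_epochs = 60L, patience = 10L,
                       seed = 1L) {
  reparam <- match.arg(reparam)
  if (window_length <= 1L) stop("window_length must be > 1")
  if (latent_dim < 1L) stop("latent_dim must be >= 1")
  if (beta <= 0) stop("beta must be > 0")
  structure(list(window_length = as.integer(window_length),
                 latent_dim = as.integer(latent_dim), beta = beta,
                 units = as.integer(units), reparam = reparam,
                 forecaster_layers = as.integer(forecaster_layers),
                 context_windows = as.integer(context_windows),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "vae_config")
}

#' Partition a night into non-overlapping windows
#'
#' Consecutive disjoint windows of `n` points; a trailing remainder of
#' fewer than `n` points is excluded from windowing but recorded, so that
#' concatenating windows and remainder reproduces the series exactly.
#'
#' @param series An [hr_series()] or numeric vector of length >= 2n.
#' @param n Window length.
#' @return List with `X` (windows-by-n matrix), `n`, `n_windows`,
#'   `point_index` (list mapping window k to its point indices) and
#'   `remainder` (indices of unwindowed trailing points).
#' @export
make_windows <- function(series, n = 10L) {
  x <- if (inherits(series, "hr_series")) series$bpm else as.numeric(series)
  N <- length(x)
  if (N < 2L * n) stop("series shorter than two windows")
  K <- N %/% n
  X <- matrix(x[seq_len(K * n)], K, n, byrow = TRUE)
  point_index <- lapply(seq_len(K), function(k) ((k - 1L) * n + 1L):(k * n))
  remainder <- if (K * n < N) seq.int(K * n + 1L, N) else integer(0)
  list(X = X, n = as.integer(n), n_windows = K, point_index = point_index,
       remainder = remainder)
}

#' Reparameterization: sample z from (mu, sigma2) with external noise
#'
#' `z = mu + sigma2 * eps` elementwise under the `"variance"` convention
#' (the rule as printed), or `z = mu + sqrt(sigma2) * eps` under `"sd"`.
#'
#' @param mu Mean matrix/vector.
#' @param sigma2 Variance matrix/vector (strictly positive).
#' @param epsilon Noise of the same shape.
#' @param convention `"variance"` or `"sd"`.
#' @return The sampled z.
#' @export
reparameterize <- function(mu, sigma2, epsilon, convention = c("variance", "sd")) {
  convention <- match.arg(convention)
  if (any(sigma2 <= 0)) stop("sigma2 must be strictly positive")
  if (convention == "variance") mu + sigma2 * epsilon else mu + sqrt(sigma2) * epsilon
}

#' VAE loss: squared reconstruction error plus beta-weighted KL
#'
#' `total = ||x - x_recon||^2 + beta * KL(N(mu, diag sigma2) || N(0, I))`
#' with the closed-form KL `0.5 * sum(sigma2 + mu^2 - 1 - log sigma2)`.
#'
#' @param x,x_recon Observed and reconstructed windows.
#' @param mu,sigma2 Latent Gaussian parameters.
#' @param beta KL weight.
#' @return List with `total`, `recon_term`, `kl_term`.
#' @export
vae_loss <- function(x, x_recon, mu, sigma2, beta = 3) {
  if (length(x) != length(x_recon)) stop("x and x_recon must have equal length")
  if (any(sigma2 <= 0)) stop("sigma2 must be strictly positive")
  recon <- sum((x - x_recon)^2)
  kl <- 0.5 * sum(sigma2 + mu^2 - 1 - log(sigma2))
  list(total = recon + beta * kl, recon_term = recon, kl_term = kl)
}

.vae_init <- function(cfg) {
  H <- cfg$units; d <- cfg$latent_dim
  list(enc_f = lstm_init(1L, H), enc_b = lstm_init(1L, H),
       mu_head = dense_init(2L * H, d), lv_head = dense_init(2L * H, d),
       dec_f = lstm_init(d, H), dec_b = lstm_init(d, H),
       out_head = dense_init(2L * H, 1L))
}

# Encoder forward: X (B x n) -> list(mu, lv) nodes (B x d).
.vae_encode_fwd <- function(tape, pn, X, cfg) {
  xs <- lapply(seq_len(ncol(X)), function(t) X[, t, drop = FALSE])
  hf <- lstm_seq(tape, xs, pn$enc_f$W, pn$enc_f$U, pn$enc_f$b, cfg$units)
  hb <- lstm_seq(tape, rev(xs), pn$enc_b$W, pn$enc_b$U, pn$enc_b$b, cfg$units)
  hh <- ad_cbind(tape, hf[[length(hf)]], hb[[length(hb)]])
  list(mu = ad_bias(tape, ad_mm(tape, hh, pn$mu_head$W), pn$mu_head$b),
       lv = ad_bias(tape, ad_mm(tape, hh, pn$lv_head$W), pn$lv_head$b))
}

# Decoder forward: z node/matrix (B x d) -> reconstruction node (B x n).
# The embedding is repeated n times as the decoder input sequence.
.vae_decode_fwd <- function(tape, pn, z, cfg) {
  xs <- rep(list(z), cfg$window_length)
  hs <- bilstm_seq(tape, xs, pn$dec_f, pn$dec_b, cfg$units)
  out <- NULL
  for (t in seq_along(hs)) {
    yt <- ad_bias(tape, ad_mm(tape, hs[[t]], pn$out_head$W), pn$out_head$b)
    out <- if (is.null(out)) yt else ad_cbind(tape, out, yt)
  }
  out
}

#' Fit the beta-VAE on the cleaned training nights
#'
#' The encoder is parameterized through log sigma^2 for numerical
#' stability; sampling follows the configured reparameterization
#' convention. The loss per window is the squared reconstruction error
#' plus beta times the closed-form KL divergence; minibatch means are
#' optimised with Adam and early stopping monitors the total loss on the
#' validation night (noise-free validation encoding, z = mu).
#'
#' @param train_nights Cleaned training [hr_series()] list.
#' @param config A [vae_config()].
#' @param validation Optional validation [hr_series()].
#' @param std Optional standardizer (defaults to training-night moments).
#' @return An object of class `hr_vae` with `params`, `config`, `std`.
#' @export
fit_beta_vae <- function(train_nights, config = vae_config(), validation = NULL,
                         std = NULL) {
  if (is.null(std)) std <- std_fit(train_nights)
  n <- config$window_length
  st <- config$train_stride %||% n
  Xtr <- do.call(rbind, lapply(train_nights, function(s) {
    x <- std_apply(s$bpm, std)
    starts <- seq.int(1L, length(x) - n + 1L, by = st)
    t(vapply(starts, function(i) x[i:(i + n - 1L)], numeric(n)))
  }))
  fit_beta_vae_windows(Xtr, config, validation, std)
}

fit_beta_vae_windows <- function(Xtr, config, validation = NULL, std) {
  n <- config$window_length
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  params <- .vae_init(config)
  B_all <- nrow(Xtr)
  sample_z <- function(tape, mu, lv, eps) {
    if (config$reparam == "variance") {
      ad_add(tape, mu, ad_mul(tape, ad_exp(tape, lv), eps))
    } else {
      ad_add(tape, mu, ad_mul(tape, ad_exp(tape, ad_scale(tape, lv, 0.5)), eps))
    }
  }
  loss_parts <- function(tape, pn, X, eps) {
    enc <- .vae_encode_fwd(tape, pn, X, config)
    z <- sample_z(tape, enc$mu, enc$lv, eps)
    xr <- .vae_decode_fwd(tape, pn, z, config)
    d <- ad_sub(tape, xr, X)
    recon <- ad_sum(tape, ad_mul(tape, d, d))
    s2 <- ad_exp(tape, enc$lv)
    mu2 <- ad_mul(tape, enc$mu, enc$mu)
    kl <- ad_scale(tape, ad_sub(tape, ad_sum(tape, ad_add(tape, s2, mu2)),
                                ad_sum(tape, ad_add(tape, enc$lv,
                                                    matrix(1, nrow(X), config$latent_dim)))),
                   0.5)
    list(recon = recon, kl = kl)
  }
  loss_fn <- function(tape, pn, idx) {
    X <- Xtr[idx, , drop = FALSE]
    eps <- matrix(stats::rnorm(length(idx) * config$latent_dim),
                  length(idx), config$latent_dim)
    lp <- loss_parts(tape, pn, X, eps)
    ad_scale(tape, ad_add(tape, lp$recon, ad_scale(tape, lp$kl, config$beta)),
             1 / length(idx))
  }
  val_fn <- NULL
  if (!is.null(validation)) {
    Xv <- make_windows(std_apply(validation$bpm, std), n)$X
    val_fn <- function(p) {
      tape <- ad_tape()
      pn <- params_to_nodes(tape, p)
      lp <- loss_parts(tape, pn, Xv, matrix(0, nrow(Xv), config$latent_dim))
      (ad_val(lp$recon) + config$beta * ad_val(lp$kl)) / nrow(Xv)
    }
  }
  fit <- nn_train(params, loss_fn, B_all, batch_size = config$batch_size,
                  max_epochs = config$max_epochs, lr = config$learning_rate,
                  val_fn = val_fn, patience = config$patience)
  structure(list(params = fit$params, config = config, std = std,
                 history = fit$history, epochs = fit$epochs), class = "hr_vae")
}

#' Encode a night (or window matrix) into the latent space
#'
#' Returns the per-window posterior mean and variance; at inference the
#' deterministic embedding mu is used (no sampling).
#'
#' @param vae A fitted `hr_vae`.
#' @param x An [hr_series()], numeric vector or windows matrix (already
#'   standardized when a matrix).
#' @return List with `mu` and `sigma2` (windows x d matrices).
#' @export
vae_encode <- function(vae, x) {
  X <- if (is.matrix(x)) x else {
    v <- if (inherits(x, "hr_series")) x$bpm else as.numeric(x)
    make_windows(std_apply(v, vae$std), vae$config$window_length)$X
  }
  tape <- ad_tape()
  pn <- params_to_nodes(tape, vae$params)
  enc <- .vae_encode_fwd(tape, pn, X, vae$config)
  list(mu = ad_val(enc$mu), sigma2 = exp(ad_val(enc$lv)))
}

#' Decode latent embeddings back to (standardized) windows
#' @param vae A fitted `hr_vae`.
#' @param z Embeddings matrix (windows x d).
#' @export
vae_decode <- function(vae, z) {
  tape <- ad_tape()
  pn <- params_to_nodes(tape, vae$params)
  ad_val(.vae_decode_fwd(tape, pn, z, vae$config))
}

#' Fit the BiLSTM latent forecaster over VAE embeddings
#'
#' Trains a bidirectional stacked LSTM (layer plan from the config) to
#' predict z_{t+1} from the `context_windows` preceding embeddings (the
#' current and previous embeddings by default).
#'
#' @param Z_train List of per-night embedding matrices (windows x d).
#' @param config A [vae_config()].
#' @param Z_val Optional list of validation embedding matrices.
#' @return A latent forecaster (see [fit_latent_forecaster_core()]).
#' @export
fit_latent_forecaster <- function(Z_train, config = vae_config(), Z_val = NULL) {
  ok <- vapply(Z_train, function(Z) nrow(Z) >= config$context_windows + 1L, logical(1))
  if (!any(ok)) stop("too few windows per night to train the latent forecaster")
  fit_latent_forecaster_core(Z_train[ok], Z_val, context = config$context_windows,
                             layer_sizes = config$forecaster_layers,
                             bidirectional = TRUE, dropout_rate = 0,
                             learning_rate = config$learning_rate,
                             batch_size = config$batch_size,
                             max_epochs = config$max_epochs,
                             patience = config$patience, seed = config$seed)
}

#' Fit the complete beta-VAE-BiLSTM anomaly detector
#'
#' @param train_nights Cleaned training [hr_series()] list.
#' @param validation Optional validation [hr_series()] for early stopping.
#' @param config A [vae_config()].
#' @return An object of classes `hr_vae_bilstm`, `hr_detector`.
#' @export
hr_vae_bilstm <- function(train_nights, validation = NULL, config = vae_config()) {
  vae <- fit_beta_vae(train_nights, config, validation)
  Z_train <- lapply(train_nights, function(s) vae_encode(vae, s)$mu)
  Z_val <- if (!is.null(validation)) list(vae_encode(vae, validation)$mu) else NULL
  fc <- fit_latent_forecaster(Z_train, config, Z_val)
  structure(list(vae = vae, forecaster = fc, std = vae$std, config = config),
            class = c("hr_vae_bilstm", "hr_detector"))
}

#' @export
print.hr_vae_bilstm <- function(x, ...) {
  cat(sprintf("<hr_vae_bilstm> beta-VAE (n=%d, d=%d, beta=%g, %d BiLSTM units) + BiLSTM latent forecaster [%s]\n",
              x$config$window_length, x$config$latent_dim, x$config$beta,
              x$config$units, paste(x$config$forecaster_layers, collapse = ",")))
  invisible(x)
}

#' @export
summary.hr_vae_bilstm <- function(object, ...) {
  cat(sprintf("beta-VAE-BiLSTM detector\n  window n = %d, latent d = %d, beta = %g\n",
              object$config$window_length, object$config$latent_dim, object$config$beta))
  cat(sprintf("  VAE trained %d epochs; forecaster trained %d epochs\n",
              object$vae$epochs, object$forecaster$epochs))
  cat(sprintf("  standardizer: mean %.2f BPM, sd %.2f BPM\n",
              object$std$mean, object$std$sd))
  invisible(object)
}

#' @export
hr_score.hr_vae_bilstm <- function(object, series, ...) {
  cfg <- object$config
  n <- cfg$window_length
  ctx <- cfg$context_windows
  x <- std_apply(series$bpm, object$std)
  wb <- make_windows(x, n)
  K <- wb$n_windows
  if (K < ctx + 1L) stop("night too short to score with the beta-VAE-BiLSTM detector")
  mu <- vae_encode(object$vae, wb$X)$mu
  tgt <- seq.int(ctx + 1L, K)
  Xarr <- array(0, dim = c(length(tgt), ctx, cfg$latent_dim))
  for (i in seq_along(tgt)) Xarr[i, , ] <- mu[seq.int(tgt[i] - ctx, tgt[i] - 1L), ]
  Zhat <- latent_forecast_batch(object$forecaster, Xarr)
  Xhat <- vae_decode(object$vae, Zhat)
  scores <- numeric(0); indices <- integer(0)
  for (i in seq_along(tgt)) {
    pts <- wb$point_index[[tgt[i]]]
    err <- (std_invert(Xhat[i, ], object$std) - series$bpm[pts])^2
    scores <- c(scores, err)
    indices <- c(indices, pts)
  }
  list(scores = scores, indices = indices)
}
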