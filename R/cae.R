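#' Configuration for the convolutional autoencoder (CAE) detector
#'
#' Encoder: three 1-D convolutions with 16, 8 and 1 filters, kernel sizes
#' 5, 5 and 1, all stride 2 with 'same' padding, so a raw sample of length
#' n = 32 compresses to a latent embedding of dimensionality d = 4
#' (32 / 2^3 positions x 1 filter). ReLU activations on the hidden
#' convolutions, linear bottleneck and output. The decoder mirrors the
#' encoder with zero-stuffing upsampling. An LSTM forecaster is then
#' trained over the embedding sequence to predict the next embedding.
#'
#' @param sample_length Window length n fed to the encoder.
#' @param latent_dim Latent dimensionality d.
#' @param encoder_filters,kernel_sizes,strides Convolution plan.
#' @param train_stride Stride between training windows (scoring windows are
#'   always non-overlapping).
#' @param context_windows Number of past embeddings fed to the forecaster.
#' @param dropout_rate,learning_rate,batch_size,max_epochs,patience,seed
#'   Training-loop settings shared by the CAE and the LSTM stage.
#' @return An object of class `cae_config`.
#' @export
cae_config <- function(sample_length = 32L, latent_dim = 4L,
                       encoder_filters = c(16L, 8L, 1L),
                       kernel_sizes = c(5L, 5L, 1L), strides = c(2L, 2L, 2L),
                       train_stride = 4L, context_windows = 2L,
                       dropout_rate = 0.2, learning_rate = 1e-3,
                       batch_size = 32L, max_epochs = 60L, patience = 10L,
                       seed = 1L) {
  n <- sample_length
  if (n %% prod(strides) != 0 ||
      (n / prod(strides)) * encoder_filters[3] != latent_dim) {
    stop("configuration error: sample_length / prod(strides) * final filters must equal latent_dim")
  }
  structure(list(sample_length = as.integer(sample_length),
                 latent_dim = as.integer(latent_dim),
                 encoder_filters = as.integer(encoder_filters),
                 kernel_sizes = as.integer(kernel_sizes),
                 strides = as.integer(strides),
                 train_stride = as.integer(train_stride),
                 context_windows = as.integer(context_windows),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "cae_config")
}

.cae_init <- function(cfg) {
  kf <- cfg$kernel_sizes; ef <- cfg$encoder_filters
  list(
    e1 = list(W = .glorot(kf[1] * 1L, ef[1]), b = matrix(0, 1, ef[1])),
    e2 = list(W = .glorot(kf[2] * ef[1], ef[2]), b = matrix(0, 1, ef[2])),
    e3 = list(W = .glorot(kf[3] * ef[2], ef[3]), b = matrix(0, 1, ef[3])),
    d1 = list(W = .glorot(1L * ef[3], ef[2]), b = matrix(0, 1, ef[2])),
    d2 = list(W = .glorot(kf[2] * ef[2], ef[1]), b = matrix(0, 1, ef[1])),
    d3 = list(W = .glorot(kf[1] * ef[1], 1L), b = matrix(0, 1, 1)))
}

# X: (B x n) matrix of standardized windows -> latent node (B x d)
.cae_encode_fwd <- function(tape, pn, X, cfg) {
  a <- array(X, dim = c(nrow(X), ncol(X), 1L))
  h1 <- ad_relu(tape, ad_conv1d(tape, a, pn$e1$W, pn$e1$b, cfg$kernel_sizes[1], cfg$strides[1]))
  h2 <- ad_relu(tape, ad_conv1d(tape, h1, pn$e2$W, pn$e2$b, cfg$kernel_sizes[2], cfg$strides[2]))
  h3 <- ad_conv1d(tape, h2, pn$e3$W, pn$e3$b, cfg$kernel_sizes[3], cfg$strides[3])
  ad_squeeze3(tape, h3)   # (B, 4, 1) -> (B, 4)
}

# z: (B x d) node/matrix -> reconstruction node (B x n)
.cae_decode_fwd <- function(tape, pn, z, cfg) {
  a <- ad_expand3(tape, z)
  u1 <- ad_upsample(tape, a, cfg$strides[3])
  h1 <- ad_relu(tape, ad_conv1d(tape, u1, pn$d1$W, pn$d1$b, cfg$kernel_sizes[3], 1L))
  u2 <- ad_upsample(tape, h1, cfg$strides[2])
  h2 <- ad_relu(tape, ad_conv1d(tape, u2, pn$d2$W, pn$d2$b, cfg$kernel_sizes[2], 1L))
  u3 <- ad_upsample(tape, h2, cfg$strides[1])
  h3 <- ad_conv1d(tape, u3, pn$d3$W, pn$d3$b, cfg$kernel_sizes[1], 1L)
  ad_squeeze3(tape, h3)
}

#' Fit the convolutional autoencoder on standardized windows
#'
#' @param train_windows Matrix (rows = length-`sample_length` windows).
#' @param config A [cae_config()].
#' @param validation_windows Optional windows monitored for early stopping.
#' @return List with `params`, `config`, `history`; use [cae_encode()] /
#'   [cae_decode()].
#' @export
fit_cae <- function(train_windows, config = cae_config(), validation_windows = NULL) {
  if (ncol(train_windows) != config$sample_length) {
    stop("configuration error: window width != sample_length")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  params <- .cae_init(config)
  loss_fn <- function(tape, pn, idx) {
    Xb <- train_windows[idx, , drop = FALSE]
    z <- .cae_encode_fwd(tape, pn, Xb, config)
    xr <- .cae_decode_fwd(tape, pn, z, config)
    d <- ad_sub(tape, xr, Xb)
    ad_scale(tape, ad_sum(tape, ad_mul(tape, d, d)), 1 / nrow(Xb))
  }
  val_fn <- NULL
  if (!is.null(validation_windows)) {
    val_fn <- function(p) {
      tape <- ad_tape()
      pn <- params_to_nodes(tape, p)
      xr <- ad_val(.cae_decode_fwd(tape, pn, .cae_encode_fwd(tape, pn, validation_windows, config), config))
      mean((xr - validation_windows)^2)
    }
  }
  fit <- nn_train(params, loss_fn, nrow(train_windows), batch_size = config$batch_size,
                  max_epochs = config$max_epochs, lr = config$learning_rate,
                  val_fn = val_fn, patience = config$patience)
  structure(list(params = fit$params, config = config, history = fit$history,
                 epochs = fit$epochs), class = "hr_cae")
}

#' @rdname fit_cae
#' @export
cae_encode <- function(cae, windows) {
  tape <- ad_tape()
  pn <- params_to_nodes(tape, cae$params)
  ad_val(.cae_encode_fwd(tape, pn, windows, cae$config))
}

#' @rdname fit_cae
#' @export
cae_decode <- function(cae, z) {
  tape <- ad_tape()
  pn <- params_to_nodes(tape, cae$params)
  ad_val(.cae_decode_fwd(tape, pn, z, cae$config))
}

# LSTM forecaster over latent embedding sequences: context_windows
# embeddings in, next embedding out.
.latent_pairs <- function(Z_list, context) {
  ins <- list(); outs <- list()
  for (Z in Z_list) {
    K <- nrow(Z)
    if (K < context + 1L) next
    for (t in seq.int(context + 1L, K)) {
      ins[[length(ins) + 1L]] <- Z[seq.int(t - context, t - 1L), , drop = FALSE]
      outs[[length(outs) + 1L]] <- Z[t, ]
    }
  }
  if (length(ins) == 0L) stop("too few windows to train the latent forecaster")
  d <- ncol(Z_list[[1]])
  X <- array(0, dim = c(length(ins), context, d))
  for (i in seq_along(ins)) X[i, , ] <- ins[[i]]
  list(X = X, Y = do.call(rbind, outs))
}

.latent_forecaster_fwd <- function(tape, pn, Xarr, layer_sizes, bidirectional,
                                   drop_masks = NULL) {
  xs <- lapply(seq_len(dim(Xarr)[2]), function(t) {
    matrix(Xarr[, t, ], nrow = dim(Xarr)[1])
  })
  hs <- lstm_stack_seq(tape, xs, pn, layer_sizes, bidirectional, drop_masks)
  last <- hs[[length(hs)]]
  ad_bias(tape, ad_mm(tape, last, pn$head$W), pn$head$b)
}

fit_latent_forecaster_core <- function(Z_train, Z_val = NULL, context = 2L,
                                       layer_sizes = c(32L, 16L, 8L),
                                       bidirectional = FALSE, dropout_rate = 0,
                                       learning_rate = 1e-3, batch_size = 32L,
                                       max_epochs = 60L, patience = 10L, seed = 1L) {
  tp <- .latent_pairs(Z_train, context)
  d <- dim(tp$X)[3]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 1L)
  params <- lstm_stack_init(d, layer_sizes, bidirectional)
  params$head <- dense_init(attr(params, "out_dim"), d)
  mult <- if (bidirectional) 2L else 1L
  loss_fn <- function(tape, pn, idx) {
    B <- length(idx)
    masks <- if (dropout_rate > 0) {
      lapply(layer_sizes, function(H) {
        matrix((stats::runif(B * H * mult) > dropout_rate) / (1 - dropout_rate), B, H * mult)
      })
    } else NULL
    pred <- .latent_forecaster_fwd(tape, pn, tp$X[idx, , , drop = FALSE],
                                   layer_sizes, bidirectional, masks)
    dd <- ad_sub(tape, pred, tp$Y[idx, , drop = FALSE])
    ad_scale(tape, ad_sum(tape, ad_mul(tape, dd, dd)), 1 / B)
  }
  val_fn <- NULL
  if (!is.null(Z_val)) {
    vp <- tryCatch(.latent_pairs(Z_val, context), error = function(e) NULL)
    if (!is.null(vp)) {
      val_fn <- function(p) {
        tape <- ad_tape()
        pn <- params_to_nodes(tape, p)
        pred <- ad_val(.latent_forecaster_fwd(tape, pn, vp$X, layer_sizes, bidirectional))
        mean((pred - vp$Y)^2)
      }
    }
  }
  fit <- nn_train(params, loss_fn, dim(tp$X)[1], batch_size = batch_size,
                  max_epochs = max_epochs, lr = learning_rate,
                  val_fn = val_fn, patience = patience)
  list(params = fit$params, context = context, layer_sizes = layer_sizes,
       bidirectional = bidirectional, history = fit$history, epochs = fit$epochs)
}

latent_forecast <- function(fc, Zctx) {
  Xarr <- array(Zctx, dim = c(1L, nrow(Zctx), ncol(Zctx)))
  tape <- ad_tape()
  pn <- params_to_nodes(tape, fc$params)
  ad_val(.latent_forecaster_fwd(tape, pn, Xarr, fc$layer_sizes, fc$bidirectional))
}

# Batched forecast: Xarr (B, context, d)
latent_forecast_batch <- function(fc, Xarr) {
  tape <- ad_tape()
  pn <- params_to_nodes(tape, fc$params)
  ad_val(.latent_forecaster_fwd(tape, pn, Xarr, fc$layer_sizes, fc$bidirectional))
}

#' Fit the CAE-LSTM anomaly detector
#'
#' Trains the convolutional autoencoder on standardized length-32 windows
#' of the cleaned training nights, encodes the non-overlapping window
#' sequence of each night, trains an LSTM to forecast the next embedding,
#' and scores a night by decoding the forecast embedding and measuring
#' element-wise squared error against the observed window.
#'
#' @param train_nights Cleaned training [hr_series()] list.
#' @param validation Optional validation [hr_series()].
#' @param config A [cae_config()].
#' @return An object of classes `hr_cae_lstm`, `hr_detector`.
#' @export
hr_cae_lstm <- function(train_nights, validation = NULL, config = cae_config()) {
  std <- std_fit(train_nights)
  n <- config$sample_length
  slide <- function(x, stride) {
    starts <- seq.int(1L, length(x) - n + 1L, by = stride)
    t(vapply(starts, function(s) x[s:(s + n - 1L)], numeric(n)))
  }
  Xtr <- do.call(rbind, lapply(train_nights, function(s) slide(std_apply(s$bpm, std), config$train_stride)))
  Xval <- if (!is.null(validation)) slide(std_apply(validation$bpm, std), n) else NULL
  cae <- fit_cae(Xtr, config, Xval)
  Z_train <- lapply(train_nights, function(s) {
    cae_encode(cae, slide(std_apply(s$bpm, std), n))
  })
  Z_val <- if (!is.null(validation)) list(cae_encode(cae, Xval)) else NULL
  fc <- fit_latent_forecaster_core(Z_train, Z_val, context = config$context_windows,
                                   bidirectional = FALSE,
                                   dropout_rate = config$dropout_rate,
                                   learning_rate = config$learning_rate,
                                   batch_size = config$batch_size,
                                   max_epochs = config$max_epochs,
                                   patience = config$patience, seed = config$seed)
  structure(list(cae = cae, forecaster = fc, std = std, config = config),
            class = c("hr_cae_lstm", "hr_detector"))
}

#' @export
print.hr_cae_lstm <- function(x, ...) {
  cat(sprintf("<hr_cae_lstm> conv encoder [%s] n=%d -> d=%d + LSTM latent forecaster\n",
              paste(x$config$encoder_filters, collapse = ","),
              x$config$sample_length, x$config$latent_dim))
  invisible(x)
}

#' @export
hr_score.hr_cae_lstm <- function(object, series, ...) {
  cfg <- object$config
  n <- cfg$sample_length
  ctx <- object$forecaster$context
  x <- std_apply(series$bpm, object$std)
  K <- length(x) %/% n
  if (K < ctx + 1L) stop("night too short to score with the CAE-LSTM detector")
  W <- t(vapply(seq_len(K), function(k) x[((k - 1L) * n + 1L):(k * n)], numeric(n)))
  Z <- cae_encode(object$cae, W)
  tgt <- seq.int(ctx + 1L, K)
  Xarr <- array(0, dim = c(length(tgt), ctx, cfg$latent_dim))
  for (i in seq_along(tgt)) Xarr[i, , ] <- Z[seq.int(tgt[i] - ctx, tgt[i] - 1L), ]
  Zhat <- latent_forecast_batch(object$forecaster, Xarr)
  Xhat <- cae_decode(object$cae, Zhat)
  scores <- numeric(0); indices <- integer(0)
  for (i in seq_along(tgt)) {
    k <- tgt[i]
    pts <- ((k - 1L) * n + 1L):(k * n)
    err <- (std_invert(Xhat[i, ], object$std) - series$bpm[pts])^2
    scores <- c(scores, err)
    indices <- c(indices, pts)
  }
  list(scores = scores, indices = indices)
}
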