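#' Network configuration for the LSTM/BiLSTM forecasting detectors
#'
#' Three stacked recurrent layers (32, 16, 8 cells) with hyperbolic-tangent
#' cell activations, dropout after each hidden layer, a max-norm bound of 3
#' on all weights and biases, Adam optimisation and early stopping on
#' validation loss. The network reads `input_window` consecutive
#' standardized samples and predicts the next one.
#'
#' @param layer_sizes Cells per stacked layer.
#' @param dropout_rate Dropout probability in [0, 1).
#' @param maxnorm_bound Max-norm constraint on weight/bias norms.
#' @param learning_rate Adam step size.
#' @param input_window History length fed to the network.
#' @param train_stride Stride between successive training windows (1 uses
#'   every one-step pair; larger strides subsample the training pairs).
#' @param batch_size,max_epochs,patience Training-loop settings.
#' @param seed Seed for initialisation, shuffling and dropout.
#' @return An object of class `net_config`.
#' @export
net_config <- function(layer_sizes = c(32L, 16L, 8L), dropout_rate = 0.2,
                       maxnorm_bound = 3, learning_rate = 1e-3,
                       input_window = 32L, train_stride = 1L,
                       batch_size = 32L, max_epochs = 60L, patience = 10L,
                       seed = 1L) {
  if (maxnorm_bound <= 0) stop("maxnorm_bound must be > 0")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(list(layer_sizes = as.integer(layer_sizes), dropout_rate = dropout_rate,
                 maxnorm_bound = maxnorm_bound, learning_rate = learning_rate,
                 input_window = as.integer(input_window),
                 train_stride = as.integer(train_stride),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "net_config")
}

# Per-participant standardization from the training nights.
std_fit <- function(train_nights) {
  y <- unlist(lapply(train_nights, `[[`, "bpm"))
  list(mean = mean(y), sd = max(stats::sd(y), 1e-8))
}
std_apply <- function(x, std) (x - std$mean) / std$sd
std_invert <- function(z, std) z * std$sd + std$mean

# Sliding one-step training pairs within one night (windows never cross
# night boundaries). Returns X (B x w) and target y (length B).
.one_step_windows <- function(x, w, stride = 1L) {
  n <- length(x)
  if (n <= w) return(list(X = matrix(0, 0, w), y = numeric(0)))
  starts <- seq.int(1L, n - w, by = stride)
  X <- matrix(0, length(starts), w)
  for (j in seq_len(w)) X[, j] <- x[starts + j - 1L]
  list(X = X, y = x[starts + w])
}

.forecaster_forward <- function(tape, pn, X, layer_sizes, bidirectional,
                                drop_masks = NULL) {
  xs <- lapply(seq_len(ncol(X)), function(t) X[, t, drop = FALSE])
  hs <- lstm_stack_seq(tape, xs, pn, layer_sizes, bidirectional, drop_masks)
  last <- hs[[length(hs)]]
  ad_bias(tape, ad_mm(tape, last, pn$head$W), pn$head$b)
}

#' Fit a stacked LSTM or BiLSTM one-step forecaster
#'
#' @param train_nights Cleaned training [hr_series()] list.
#' @param config A [net_config()].
#' @param bidirectional Use bidirectional layers.
#' @param validation Optional validation [hr_series()] monitored for early
#'   stopping (training loss is monitored when absent).
#' @return An object of classes `hr_lstm`/`hr_bilstm`, `hr_forecaster`,
#'   `hr_detector`.
#' @export
fit_nn_forecaster <- function(train_nights, config = net_config(),
                              bidirectional = FALSE, validation = NULL) {
  std <- std_fit(train_nights)
  w <- config$input_window
  parts <- lapply(train_nights, function(s) {
    .one_step_windows(std_apply(s$bpm, std), w, config$train_stride)
  })
  X <- do.call(rbind, lapply(parts, `[[`, "X"))
  y <- unlist(lapply(parts, `[[`, "y"))
  if (nrow(X) < 2L) stop("training nights too short for the input window")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  params <- lstm_stack_init(1L, config$layer_sizes, bidirectional)
  out_dim <- attr(params, "out_dim")
  params$head <- dense_init(out_dim, 1L)
  mult <- if (bidirectional) 2L else 1L
  rate <- config$dropout_rate
  loss_fn <- function(tape, pn, idx) {
    B <- length(idx)
    masks <- if (rate > 0) {
      lapply(config$layer_sizes, function(H) {
        matrix((stats::runif(B * H * mult) > rate) / (1 - rate), B, H * mult)
      })
    } else NULL
    pred <- .forecaster_forward(tape, pn, X[idx, , drop = FALSE],
                                config$layer_sizes, bidirectional, masks)
    d <- ad_sub(tape, pred, matrix(y[idx], ncol = 1))
    ad_scale(tape, ad_sum(tape, ad_mul(tape, d, d)), 1 / B)
  }
  val_fn <- NULL
  if (!is.null(validation)) {
    vp <- .one_step_windows(std_apply(validation$bpm, std), w)
    val_fn <- function(p) {
      tape <- ad_tape()
      pn <- params_to_nodes(tape, p)
      pred <- .forecaster_forward(tape, pn, vp$X, config$layer_sizes, bidirectional)
      mean((ad_val(pred) - vp$y)^2)
    }
  }
  fit <- nn_train(params, loss_fn, nrow(X), batch_size = config$batch_size,
                  max_epochs = config$max_epochs, lr = config$learning_rate,
                  val_fn = val_fn, patience = config$patience,
                  maxnorm = config$maxnorm_bound)
  structure(list(params = fit$params, config = config, std = std,
                 bidirectional = bidirectional, history = fit$history,
                 epochs = fit$epochs),
            class = c(if (bidirectional) "hr_bilstm" else "hr_lstm",
                      "hr_forecaster", "hr_detector"))
}

#' @rdname fit_nn_forecaster
#' @export
hr_lstm <- function(train_nights, validation = NULL, config = net_config()) {
  fit_nn_forecaster(train_nights, config, bidirectional = FALSE, validation = validation)
}

#' @rdname fit_nn_forecaster
#' @export
hr_bilstm <- function(train_nights, validation = NULL, config = net_config()) {
  fit_nn_forecaster(train_nights, config, bidirectional = TRUE, validation = validation)
}

#' @export
print.hr_forecaster <- function(x, ...) {
  cat(sprintf("<%s> stacked %s forecaster [%s], window %d, trained %d epochs\n",
              class(x)[1], if (x$bidirectional) "BiLSTM" else "LSTM",
              paste(x$config$layer_sizes, collapse = ","),
              x$config$input_window, x$epochs))
  invisible(x)
}

#' One-step-ahead predictions (BPM scale) for a night
#' @export
predict.hr_forecaster <- function(object, series, ...) {
  w <- object$config$input_window
  wp <- .one_step_windows(std_apply(series$bpm, object$std), w)
  tape <- ad_tape()
  pn <- params_to_nodes(tape, object$params)
  pred <- .forecaster_forward(tape, pn, wp$X, object$config$layer_sizes,
                              object$bidirectional)
  std_invert(as.numeric(ad_val(pred)), object$std)
}

#' @export
hr_score.hr_forecaster <- function(object, series, ...) {
  w <- object$config$input_window
  pred <- predict(object, series)
  n <- length(series$bpm)
  idx <- seq.int(w + 1L, n)
  list(scores = (series$bpm[idx] - pred)^2, indices = idx)
}
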