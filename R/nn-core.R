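# Building blocks shared by the neural detectors: LSTM/BiLSTM sequence
# layers, dense heads, Glorot initialisation, Adam, max-norm projection and
# a generic minibatch training loop with early stopping.

.glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

# Parameters for one LSTM layer: input W (D x 4H), recurrent U (H x 4H),
# bias b (1 x 4H) with forget-gate bias initialised to 1.
lstm_init <- function(input_dim, hidden) {
  b <- matrix(0, 1, 4 * hidden)
  b[1, hidden + seq_len(hidden)] <- 1
  list(W = .glorot(input_dim, 4 * hidden), U = .glorot(hidden, 4 * hidden), b = b)
}

dense_init <- function(input_dim, output_dim) {
  list(W = .glorot(input_dim, output_dim), b = matrix(0, 1, output_dim))
}

# One direction of an LSTM over a list of (B x D) inputs (nodes or
# matrices), using the fused cell step. Returns the list of per-step
# hidden-state nodes.
lstm_seq <- function(tape, xs, W, U, b, hidden) {
  B <- nrow(ad_val(xs[[1]]))
  hc <- matrix(0, B, 2L * hidden)
  hs <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    hc <- ad_lstm_step(tape, xs[[t]], hc, W, U, b, hidden)
    hs[[t]] <- ad_cols(tape, hc, seq_len(hidden))
  }
  hs
}

# Bidirectional layer: forward pass + backward pass over the reversed
# sequence; per-step outputs are the concatenation [h_fw(t), h_bw(t)].
bilstm_seq <- function(tape, xs, pf, pb, hidden) {
  hf <- lstm_seq(tape, xs, pf$W, pf$U, pf$b, hidden)
  hb <- lstm_seq(tape, rev(xs), pb$W, pb$U, pb$b, hidden)
  Tn <- length(xs)
  lapply(seq_len(Tn), function(t) ad_cbind(tape, hf[[t]], hb[[Tn - t + 1L]]))
}

# Parameter set for a stacked (optionally bidirectional) LSTM tower.
lstm_stack_init <- function(input_dim, layer_sizes, bidirectional) {
  params <- list()
  d <- input_dim
  for (l in seq_along(layer_sizes)) {
    H <- layer_sizes[l]
    params[[paste0("l", l, "_f")]] <- lstm_init(d, H)
    if (bidirectional) params[[paste0("l", l, "_b")]] <- lstm_init(d, H)
    d <- if (bidirectional) 2L * H else H
  }
  attr(params, "out_dim") <- d
  params
}

# Forward through the tower; drop_masks is NULL (inference) or a list of
# per-layer keep-masks applied to each step's output (inverted dropout).
lstm_stack_seq <- function(tape, xs, pn, layer_sizes, bidirectional, drop_masks = NULL) {
  hs <- xs
  for (l in seq_along(layer_sizes)) {
    H <- layer_sizes[l]
    pf <- pn[[paste0("l", l, "_f")]]
    if (bidirectional) {
      pb <- pn[[paste0("l", l, "_b")]]
      hs <- bilstm_seq(tape, hs, pf, pb, H)
    } else {
      hs <- lstm_seq(tape, hs, pf$W, pf$U, pf$b, H)
    }
    if (!is.null(drop_masks) && !is.null(drop_masks[[l]])) {
      hs <- lapply(hs, function(h) ad_mask(tape, h, drop_masks[[l]]))
    }
  }
  hs
}

# Wrap a flat (possibly nested) parameter list into tape nodes.
params_to_nodes <- function(tape, params) {
  rapply(params, function(m) ad_param(tape, m), classes = "matrix", how = "replace")
}

node_grads <- function(pn) {
  rapply(pn, function(n) n$grad %||% (n$val * 0), classes = "environment", how = "replace")
}

.flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    x <- p[[nm]]
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(x)) out <- c(out, .flatten_params(x, key)) else out[[key]] <- x
  }
  out
}

.unflatten_into <- function(p, flat, prefix = "") {
  for (nm in names(p)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(p[[nm]])) p[[nm]] <- .unflatten_into(p[[nm]], flat, key)
    else p[[nm]] <- flat[[key]]
  }
  p
}

adam_new <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$b1 <- beta1; e$b2 <- beta2; e$eps <- eps
  e$t <- 0L; e$m <- NULL; e$v <- NULL
  e
}

adam_step <- function(opt, params, grads) {
  fp <- .flatten_params(params)
  fg <- .flatten_params(grads)
  if (is.null(opt$m)) {
    opt$m <- lapply(fp, function(x) x * 0)
    opt$v <- lapply(fp, function(x) x * 0)
  }
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$b1^opt$t
  c2 <- 1 - opt$b2^opt$t
  for (nm in names(fp)) {
    g <- fg[[nm]]
    opt$m[[nm]] <- opt$b1 * opt$m[[nm]] + (1 - opt$b1) * g
    opt$v[[nm]] <- opt$b2 * opt$v[[nm]] + (1 - opt$b2) * g * g
    fp[[nm]] <- fp[[nm]] - opt$lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + opt$eps)
  }
  .unflatten_into(params, fp)
}

# Max-norm constraint: rescale any weight column (and the bias vector as a
# whole) whose Euclidean norm exceeds `bound`.
maxnorm_project <- function(params, bound) {
  clamp_mat <- function(M) {
    n <- sqrt(colSums(M * M))
    over <- n > bound
    if (any(over)) M[, over] <- sweep(M[, over, drop = FALSE], 2, bound / n[over], `*`)
    M
  }
  fp <- .flatten_params(params)
  for (nm in names(fp)) {
    M <- fp[[nm]]
    if (nrow(M) == 1L) {                       # bias row vector
      n <- sqrt(sum(M * M))
      if (n > bound) M <- M * (bound / n)
    } else {
      M <- clamp_mat(M)
    }
    fp[[nm]] <- M
  }
  .unflatten_into(params, fp)
}

maxnorm_max <- function(params) {
  fp <- .flatten_params(params)
  mx <- 0
  for (M in fp) {
    n <- if (nrow(M) == 1L) sqrt(sum(M * M)) else max(sqrt(colSums(M * M)))
    mx <- max(mx, n)
  }
  mx
}

# Generic minibatch trainer. loss_fn(tape, pn, idx) must return a scalar
# mean-loss node over the rows `idx`; val_fn(params), when given, returns a
# numeric validation loss used for early stopping (patience in epochs).
nn_train <- function(params, loss_fn, n_obs, batch_size = 128L, max_epochs = 60L,
                     lr = 1e-3, val_fn = NULL, patience = 10L, maxnorm = NULL,
                     min_epochs = 1L) {
  opt <- adam_new(lr = lr)
  best <- params
  best_val <- Inf
  wait <- 0L
  history <- numeric(0)
  for (ep in seq_len(max_epochs)) {
    ord <- sample.int(n_obs)
    nb <- max(1L, ceiling(n_obs / batch_size))
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[seq.int((bi - 1L) * batch_size + 1L, min(bi * batch_size, n_obs))]
      tape <- ad_tape()
      pn <- params_to_nodes(tape, params)
      loss <- loss_fn(tape, pn, idx)
      lv <- ad_val(loss)
      if (!is.finite(lv)) {
        stop("training diverged (non-finite loss); try a lower learning rate")
      }
      ep_loss <- ep_loss + lv * length(idx)
      ad_backward(tape, loss)
      params <- adam_step(opt, params, node_grads(pn))
      if (!is.null(maxnorm)) params <- maxnorm_project(params, maxnorm)
    }
    history <- c(history, ep_loss / n_obs)
    if (!is.null(val_fn)) {
      vl <- val_fn(params)
      if (vl < best_val - 1e-9) {
        best_val <- vl
        best <- params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience && ep >= min_epochs) break
      }
    } else {
      best <- params
    }
  }
  list(params = if (is.null(val_fn)) params else best,
       history = history, best_val = best_val, epochs = length(history))
}
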