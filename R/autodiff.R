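# Minimal reverse-mode automatic differentiation on matrices.
#
# A tape records nodes in creation order; backward() replays it in reverse.
# Nodes are environments holding $val, $grad and a $back closure that
# scatters the incoming gradient to the node's parents. Operations accept
# either a node or a plain numeric (treated as a constant with no gradient).
# This is deliberately small: just the ops the LSTM/conv/VAE models need.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 4096L)
  t$k <- 0L
  t
}

.ad_push <- function(tape, val, back = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$back <- back
  k <- tape$k + 1L
  if (k > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[k]] <- n
  tape$k <- k
  n
}

ad_is_node <- function(x) is.environment(x)

ad_val <- function(x) if (is.environment(x)) x$val else x

.ad_accum <- function(x, g) {
  if (is.environment(x)) {
    x$grad <- if (is.null(x$grad)) g else x$grad + g
  }
  invisible(NULL)
}

# Leaf holding a parameter matrix; gradient is accumulated into $grad.
ad_param <- function(tape, val) .ad_push(tape, val)

ad_mm <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  .ad_push(tape, av %*% bv, back = function(g) {
    .ad_accum(a, g %*% t(bv))
    .ad_accum(b, crossprod(av, g))
  })
}

ad_add <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  .ad_push(tape, av + bv, back = function(g) {
    .ad_accum(a, g)
    .ad_accum(b, g)
  })
}

# matrix + row-vector bias (recycled across rows)
ad_bias <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  .ad_push(tape, av + rep(bv, each = nrow(av)), back = function(g) {
    .ad_accum(a, g)
    .ad_accum(b, colSums(g))
  })
}

ad_sub <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  .ad_push(tape, av - bv, back = function(g) {
    .ad_accum(a, g)
    .ad_accum(b, -g)
  })
}

ad_mul <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  .ad_push(tape, av * bv, back = function(g) {
    .ad_accum(a, g * bv)
    .ad_accum(b, g * av)
  })
}

ad_scale <- function(tape, a, s) {
  av <- ad_val(a)
  .ad_push(tape, av * s, back = function(g) .ad_accum(a, g * s))
}

ad_tanh <- function(tape, a) {
  v <- tanh(ad_val(a))
  .ad_push(tape, v, back = function(g) .ad_accum(a, g * (1 - v * v)))
}

ad_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-ad_val(a)))
  .ad_push(tape, v, back = function(g) .ad_accum(a, g * v * (1 - v)))
}

ad_relu <- function(tape, a) {
  av <- ad_val(a)
  v <- av * (av > 0)
  .ad_push(tape, v, back = function(g) .ad_accum(a, g * (av > 0)))
}

ad_exp <- function(tape, a) {
  v <- exp(ad_val(a))
  .ad_push(tape, v, back = function(g) .ad_accum(a, g * v))
}

ad_sum <- function(tape, a) {
  av <- ad_val(a)
  .ad_push(tape, sum(av), back = function(g) {
    .ad_accum(a, array(g, dim = dim(av) %||% length(av)))
  })
}

ad_cols <- function(tape, a, idx) {
  av <- ad_val(a)
  .ad_push(tape, av[, idx, drop = FALSE], back = function(g) {
    z <- matrix(0, nrow(av), ncol(av))
    z[, idx] <- g
    .ad_accum(a, z)
  })
}

ad_cbind <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  na <- ncol(av)
  .ad_push(tape, cbind(av, bv), back = function(g) {
    .ad_accum(a, g[, seq_len(na), drop = FALSE])
    .ad_accum(b, g[, -seq_len(na), drop = FALSE])
  })
}

# elementwise multiply by a fixed (non-differentiated) mask, e.g. dropout
ad_mask <- function(tape, a, m) {
  .ad_push(tape, ad_val(a) * m, back = function(g) .ad_accum(a, g * m))
}

# 1-D convolution over a (batch, L, C_in) array with 'same' padding and
# integer stride, via im2col. W: (K * C_in) x F matrix, b: length-F vector.
ad_conv1d <- function(tape, x, W, b, kernel, stride) {
  xv <- ad_val(x); Wv <- ad_val(W); bv <- ad_val(b)
  dm <- dim(xv)
  B <- dm[1]; L <- dm[2]; Cin <- dm[3]
  Lout <- ceiling(L / stride)
  # 'same' padding: total pad so that centres align as ceil division
  pad_total <- max((Lout - 1L) * stride + kernel - L, 0L)
  pl <- pad_total %/% 2L
  starts <- (seq_len(Lout) - 1L) * stride - pl  # 0-based start of each patch
  K <- kernel
  # patches: (B * Lout) x (K * Cin)
  cols <- matrix(0, B * Lout, K * Cin)
  srcpos <- vector("list", Lout)
  for (j in seq_len(Lout)) {
    pos <- starts[j] + seq_len(K)       # 1-based positions into x
    ok <- pos >= 1L & pos <= L
    srcpos[[j]] <- list(pos = pos, ok = ok)
    blk <- matrix(0, B, K * Cin)
    for (c in seq_len(Cin)) {
      blk[, (c - 1L) * K + which(ok)] <- xv[, pos[ok], c]
    }
    cols[(j - 1L) * B + seq_len(B), ] <- blk
  }
  z <- cols %*% Wv
  z <- z + rep(bv, each = nrow(z))
  Fn <- ncol(Wv)
  out <- array(0, dim = c(B, Lout, Fn))
  for (j in seq_len(Lout)) out[, j, ] <- z[(j - 1L) * B + seq_len(B), ]
  .ad_push(tape, out, back = function(g) {
    gz <- matrix(0, B * Lout, Fn)
    for (j in seq_len(Lout)) gz[(j - 1L) * B + seq_len(B), ] <- g[, j, ]
    .ad_accum(W, crossprod(cols, gz))
    .ad_accum(b, colSums(gz))
    if (ad_is_node(x)) {
      gcols <- gz %*% t(Wv)
      gx <- array(0, dim = dm)
      for (j in seq_len(Lout)) {
        pos <- srcpos[[j]]$pos; ok <- srcpos[[j]]$ok
        blk <- gcols[(j - 1L) * B + seq_len(B), , drop = FALSE]
        for (c in seq_len(Cin)) {
          w <- which(ok)
          gx[, pos[w], c] <- gx[, pos[w], c] + blk[, (c - 1L) * K + w]
        }
      }
      .ad_accum(x, gx)
    }
  })
}

# zero-stuffing upsample along the length axis of a (B, L, C) array;
# output length L * stride with original samples at positions 1, 1+s, ...
ad_upsample <- function(tape, x, stride) {
  xv <- ad_val(x)
  dm <- dim(xv)
  out <- array(0, dim = c(dm[1], dm[2] * stride, dm[3]))
  keep <- (seq_len(dm[2]) - 1L) * stride + 1L
  out[, keep, ] <- xv
  .ad_push(tape, out, back = function(g) {
    .ad_accum(x, g[, keep, , drop = FALSE])
  })
}

# Fused LSTM cell step with a hand-coded backward pass: one tape node per
# time step instead of ~16, which dominates runtime otherwise. The node's
# value is cbind(h, c); callers slice the h half with ad_cols.
# Gate layout in the fused projection: [input, forget, candidate, output].
ad_lstm_step <- function(tape, x, hc_prev, W, U, b, hidden) {
  xv <- ad_val(x)
  hcv <- ad_val(hc_prev)
  Wv <- ad_val(W); Uv <- ad_val(U); bv <- ad_val(b)
  hi <- seq_len(hidden)
  hprev <- hcv[, hi, drop = FALSE]
  cprev <- hcv[, hidden + hi, drop = FALSE]
  z <- xv %*% Wv + hprev %*% Uv
  z <- z + rep(bv, each = nrow(z))
  ig <- 1 / (1 + exp(-z[, hi, drop = FALSE]))
  fg <- 1 / (1 + exp(-z[, hidden + hi, drop = FALSE]))
  gg <- tanh(z[, 2L * hidden + hi, drop = FALSE])
  og <- 1 / (1 + exp(-z[, 3L * hidden + hi, drop = FALSE]))
  cc <- fg * cprev + ig * gg
  tc <- tanh(cc)
  h <- og * tc
  .ad_push(tape, cbind(h, cc), back = function(G) {
    dh <- G[, hi, drop = FALSE]
    dc <- G[, hidden + hi, drop = FALSE] + dh * og * (1 - tc * tc)
    dzo <- (dh * tc) * og * (1 - og)
    dzi <- (dc * gg) * ig * (1 - ig)
    dzg <- (dc * ig) * (1 - gg * gg)
    dzf <- (dc * cprev) * fg * (1 - fg)
    dz <- cbind(dzi, dzf, dzg, dzo)
    .ad_accum(W, crossprod(xv, dz))
    .ad_accum(U, crossprod(hprev, dz))
    .ad_accum(b, colSums(dz))
    if (ad_is_node(x)) .ad_accum(x, dz %*% t(Wv))
    .ad_accum(hc_prev, cbind(dz %*% t(Uv), dc * fg))
  })
}

# (B, L, 1) array -> (B, L) matrix and back
ad_squeeze3 <- function(tape, x) {
  xv <- ad_val(x)
  dm <- dim(xv)
  .ad_push(tape, matrix(xv, dm[1], dm[2]), back = function(g) {
    .ad_accum(x, array(g, dim = dm))
  })
}

ad_expand3 <- function(tape, x) {
  xv <- ad_val(x)
  .ad_push(tape, array(xv, dim = c(nrow(xv), ncol(xv), 1L)), back = function(g) {
    .ad_accum(x, matrix(g, nrow(xv), ncol(xv)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run the backward pass from a scalar loss node.
ad_backward <- function(tape, loss) {
  loss$grad <- 1
  for (k in rev(seq_len(tape$k))) {
    n <- tape$nodes[[k]]
    if (!is.null(n$grad) && !is.null(n$back)) n$back(n$grad)
  }
  invisible(NULL)
}
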