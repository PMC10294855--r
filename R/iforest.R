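# Isolation forest (Liu, Ting & Zhou), the classic formulation: random
# axis-parallel splits on subsamples, anomaly score 2^(-E[h(x)]/c(psi)).
# Implemented here because no isolation-forest package ships with the
# environment; kept deliberately plain (matrix input, recursive trees).

.if_cfactor <- function(n) {
  if (n <= 1) return(0)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

.if_grow <- function(X, depth, max_depth) {
  n <- nrow(X)
  if (depth >= max_depth || n <= 1L) {
    return(list(leaf = TRUE, size = n))
  }
  rng <- apply(X, 2, range)
  splittable <- which(rng[2, ] > rng[1, ])
  if (length(splittable) == 0L) return(list(leaf = TRUE, size = n))
  q <- splittable[sample.int(length(splittable), 1L)]
  p <- stats::runif(1, rng[1, q], rng[2, q])
  left <- X[, q] < p
  list(leaf = FALSE, q = q, p = p,
       l = .if_grow(X[left, , drop = FALSE], depth + 1L, max_depth),
       r = .if_grow(X[!left, , drop = FALSE], depth + 1L, max_depth))
}

.if_path <- function(tree, x, depth = 0) {
  if (tree$leaf) return(depth + .if_cfactor(tree$size))
  if (x[tree$q] < tree$p) .if_path(tree$l, x, depth + 1) else .if_path(tree$r, x, depth + 1)
}

# batch descent: route all rows through the tree at once
.if_path_all <- function(tree, X, idx, depth, out) {
  if (length(idx) == 0L) return(out)
  if (tree$leaf) {
    out[idx] <- depth + .if_cfactor(tree$size)
    return(out)
  }
  left <- X[idx, tree$q] < tree$p
  out <- .if_path_all(tree$l, X, idx[left], depth + 1, out)
  .if_path_all(tree$r, X, idx[!left], depth + 1, out)
}

#' Isolation-forest anomaly scores
#'
#' @param X Numeric matrix (rows = observations).
#' @param n_trees Number of isolation trees.
#' @param sample_size Subsample size per tree (capped at nrow(X)).
#' @param seed Integer seed; scoring is deterministic given it.
#' @return Numeric vector of anomaly scores in (0, 1); larger = more anomalous.
#' @export
iforest_score <- function(X, n_trees = 100L, sample_size = 256L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  psi <- min(sample_size, n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  max_depth <- ceiling(log2(max(psi, 2)))
  paths <- matrix(0, n, n_trees)
  for (b in seq_len(n_trees)) {
    idx <- sample.int(n, psi)
    tree <- .if_grow(X[idx, , drop = FALSE], 0L, max_depth)
    paths[, b] <- .if_path_all(tree, X, seq_len(n), 0, numeric(n))
  }
  eh <- rowMeans(paths)
  2^(-eh / .if_cfactor(psi))
}
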