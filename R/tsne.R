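# Exact t-SNE (van der Maaten & Hinton): perplexity calibration by
# bisection, symmetrised affinities, Student-t low-dimensional kernel,
# gradient descent with momentum and early exaggeration. Written here
# because the environment ships no t-SNE package; the latent maps involve
# only a few dozen windows, so the exact O(N^2) form is appropriate.

.tsne_p <- function(D2, perplexity) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      p <- exp(-d * beta)
      sp <- sum(p)
      if (sp == 0) { p <- rep(1 / length(d), length(d)); break }
      H <- log(sp) + beta * sum(d * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Map latent embeddings to the unit square with t-SNE
#'
#' Runs exact t-SNE on the embeddings and min-max scales each axis of the
#' 2-D map to [0, 1] (removing the impact of the original scale). Labels
#' are carried through for plotting (normal vs abnormal windows).
#'
#' @param embeddings Numeric matrix (windows x d).
#' @param labels Optional logical/character labels per row.
#' @param seed Integer seed (t-SNE is stochastic).
#' @param perplexity Perplexity (must be < number of rows).
#' @param max_iter Gradient-descent iterations.
#' @return An object of class `latent_map`: `coords` (rows x 2 in
#'   [0,1]^2) and `labels`.
#' @export
map_latent_tsne <- function(embeddings, labels = NULL, seed = 1L,
                            perplexity = 5, max_iter = 400L) {
  X <- as.matrix(embeddings)
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 embeddings for a t-SNE map")
  if (perplexity >= n) stop("perplexity must be smaller than the number of embeddings")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  D2 <- as.matrix(stats::dist(X))^2
  P <- .tsne_p(D2, perplexity)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  eta <- 100
  for (it in seq_len(max_iter)) {
    Pe <- if (it <= 100) P * 4 else P      # early exaggeration
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    mom <- if (it <= 20) 0.5 else 0.8
    dY <- mom * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  rng <- apply(Y, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-12)
  coords <- sweep(sweep(Y, 2, rng[1, ]), 2, span, "/")
  structure(list(coords = coords, labels = labels), class = "latent_map")
}

#' @export
plot.latent_map <- function(x, ...) {
  col <- if (is.null(x$labels)) "steelblue" else ifelse(as.logical(x$labels), "red", "blue")
  plot(x$coords, col = col, pch = 19, xlab = "t-SNE 1", ylab = "t-SNE 2",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  invisible(x)
}

#' Mean pairwise dispersion of latent embeddings
#'
#' The raw-latent spread statistic used to study how beta affects the
#' latent space: mean pairwise Euclidean distance among a night's
#' embeddings.
#'
#' @param embeddings Numeric matrix (windows x d).
#' @return Mean pairwise distance.
#' @export
latent_dispersion <- function(embeddings) {
  mean(stats::dist(as.matrix(embeddings)))
}

#' Latent uniformity: how evenly embeddings fill their occupied region
#'
#' The ratio of the mean nearest-neighbour distance to the mean pairwise
#' distance, which is scale-free. Tightly clustered embeddings give a
#' small ratio (close neighbours, distant clusters); embeddings spread
#' evenly over their region give a larger one. As the KL weight beta
#' grows, posteriors are pulled toward the standard normal, the cluster
#' structure dissolves, and this ratio increases — the scale-free
#' counterpart of latent clusters becoming "less dense and more spread
#' out" (raw dispersion itself shrinks with beta, because the KL term
#' contracts the means toward the origin).
#'
#' @param embeddings Numeric matrix (windows x d), at least 3 rows.
#' @return Mean nearest-neighbour distance over mean pairwise distance.
#' @export
latent_uniformity <- function(embeddings) {
  E <- as.matrix(embeddings)
  if (nrow(E) < 3L) stop("need at least 3 embeddings")
  D <- as.matrix(stats::dist(E))
  diag(D) <- Inf
  mean(apply(D, 1, min)) / mean(D[is.finite(D)])
}
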