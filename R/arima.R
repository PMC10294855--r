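# ARIMA residual detector: ADF stationarity check, AIC order selection over
# an (p, q) grid, fit on the concatenated cleaned training nights, and
# one-step-ahead squared prediction errors as anomaly scores.

# Dickey-Fuller tau_mu quantiles (regression with constant), interpolated
# over sample size and probability, as tabulated in Fuller (1976).
.adf_table <- list(
  n = c(25, 50, 100, 250, 500, 1e5),
  p = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
  q = rbind(
    c(-3.75, -3.33, -3.00, -2.62, -0.37, 0.00, 0.34, 0.72),
    c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
    c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
    c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
    c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
    c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)))

#' Augmented Dickey-Fuller stationarity check
#'
#' Unit-root regression with a constant term:
#' `diff(y)_t ~ 1 + y_{t-1} + lagged diffs`, with the default lag order
#' `trunc((n - 1)^(1/3))`. The p-value is interpolated from the standard
#' Dickey-Fuller tau table (constant case) and clipped to [0.01, 0.99].
#'
#' @param series An [hr_series()] or numeric vector (>= 20 points).
#' @param alpha Significance level; stationarity is declared when
#'   `p_value < alpha` (unit root rejected).
#' @param lags Number of augmenting lag differences.
#' @return List with `statistic`, `p_value`, `is_stationary`, `lags`.
#' @export
adf_check <- function(series, alpha = 0.05, lags = NULL) {
  y <- if (inherits(series, "hr_series")) series$bpm else as.numeric(series)
  n <- length(y)
  if (n < 20) stop("ADF check needs at least 20 points")
  if (stats::sd(y) == 0) stop("constant series: stationarity undetermined (zero variance)")
  if (is.null(lags)) lags <- trunc((n - 1)^(1 / 3))
  dy <- diff(y)
  k <- lags
  m <- length(dy)
  idx <- seq.int(k + 1L, m)
  X <- cbind(1, y[idx])                       # constant + level
  if (k > 0) {
    L <- sapply(seq_len(k), function(j) dy[idx - j])
    X <- cbind(X, L)
  }
  yy <- dy[idx]
  fit <- stats::lm.fit(X, yy)
  res <- fit$residuals
  s2 <- sum(res^2) / (length(yy) - ncol(X))
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * XtXinv[2, 2])
  tau <- fit$coefficients[2] / se
  tab <- .adf_table
  qs <- vapply(seq_along(tab$p), function(j) {
    stats::approx(tab$n, tab$q[, j], xout = min(n, 1e5), rule = 2)$y
  }, numeric(1))
  p <- stats::approx(qs, tab$p, xout = tau, rule = 2)$y
  p <- min(max(p, 0.01), 0.99)
  list(statistic = unname(tau), p_value = p, is_stationary = p < alpha, lags = k)
}

#' Select an ARMA(p, q) order by AIC grid search
#'
#' Fits all orders up to `(max_p, max_q)` with `stats::arima` (d = 0, with
#' mean) and returns the AIC-minimising order; ties prefer smaller p + q,
#' then smaller p.
#'
#' @param series An [hr_series()] or numeric vector (stationary).
#' @param max_p,max_q Grid bounds.
#' @return List with `p`, `q`, `aic` and the fitted `model`.
#' @export
select_arma_order <- function(series, max_p = 5L, max_q = 5L) {
  y <- if (inherits(series, "hr_series")) series$bpm else as.numeric(series)
  grid <- expand.grid(p = 0:max_p, q = 0:max_q)
  fits <- vector("list", nrow(grid))
  aics <- rep(Inf, nrow(grid))
  errs <- character(0)
  for (i in seq_len(nrow(grid))) {
    f <- tryCatch(stats::arima(y, order = c(grid$p[i], 0L, grid$q[i]),
                               method = "CSS-ML"),
                  error = function(e) e, warning = function(w) {
                    suppressWarnings(stats::arima(y, order = c(grid$p[i], 0L, grid$q[i]),
                                                  method = "CSS-ML"))
                  })
    if (inherits(f, "Arima")) {
      fits[[i]] <- f
      aics[i] <- stats::AIC(f)
    } else {
      errs <- c(errs, sprintf("(%d,%d): %s", grid$p[i], grid$q[i], conditionMessage(f)))
    }
  }
  if (all(!is.finite(aics))) {
    stop("all ARMA fits failed: ", paste(errs, collapse = "; "))
  }
  ord <- order(aics, grid$p + grid$q, grid$p)
  best <- ord[1]
  list(p = grid$p[best], q = grid$q[best], aic = aics[best], model = fits[[best]])
}

#' Fit the ARIMA anomaly detector
#'
#' Checks stationarity with [adf_check()] (so d = 0), selects the ARMA
#' order by AIC on the concatenated cleaned training nights, and keeps the
#' fitted coefficients. Scoring a night applies the fixed coefficients and
#' returns squared one-step-ahead prediction errors. The fit is fully
#' deterministic.
#'
#' @param train_nights List of cleaned [hr_series()].
#' @param max_p,max_q AIC grid bounds.
#' @param order Optional fixed `c(p, q)` to skip selection.
#' @return An object of classes `hr_arima`, `hr_detector`.
#' @export
hr_arima <- function(train_nights, max_p = 3L, max_q = 3L, order = NULL) {
  y <- unlist(lapply(train_nights, `[[`, "bpm"))
  if (stats::sd(y) == 0) {
    # degenerate constant input: the process mean is the only parameter
    return(structure(list(order = c(p = 0L, d = 0L, q = 0L),
                          coef = c(intercept = y[1]), aic = -Inf, sigma2 = 0,
                          adf = NULL, train_scores = rep(0, length(y)),
                          model = NULL, constant_mean = y[1]),
                     class = c("hr_arima", "hr_detector")))
  }
  adf <- tryCatch(adf_check(y), error = function(e) NULL)
  if (is.null(order)) {
    sel <- select_arma_order(y, max_p, max_q)
  } else {
    sel <- list(p = order[1], q = order[2],
                model = stats::arima(y, order = c(order[1], 0L, order[2])),
                aic = NA_real_)
    sel$aic <- stats::AIC(sel$model)
  }
  train_scores <- as.numeric(stats::residuals(sel$model))^2
  structure(list(order = c(p = sel$p, d = 0L, q = sel$q),
                 coef = stats::coef(sel$model), aic = sel$aic,
                 sigma2 = sel$model$sigma2, adf = adf,
                 train_scores = train_scores, model = sel$model),
            class = c("hr_arima", "hr_detector"))
}

#' @export
print.hr_arima <- function(x, ...) {
  cat(sprintf("<hr_arima> ARMA(%d,%d) detector, AIC %.1f, sigma^2 %.3f\n",
              x$order["p"], x$order["q"], x$aic, x$sigma2))
  if (!is.null(x$adf)) {
    cat(sprintf("  ADF tau %.2f (p %s %.2f) -> d = 0\n", x$adf$statistic,
                if (x$adf$is_stationary) "<" else ">=", x$adf$p_value))
  }
  invisible(x)
}

#' Score a night with a fitted detector
#'
#' Generic: returns per-point squared prediction errors plus the indices
#' (into the night) that the detector can score.
#'
#' @param object A fitted `hr_detector`.
#' @param series The night to score.
#' @return List with `scores` and `indices`.
#' @export
hr_score <- function(object, series, ...) UseMethod("hr_score")

#' @export
hr_score.hr_arima <- function(object, series, ...) {
  y <- series$bpm
  if (!is.null(object$constant_mean)) {
    return(list(scores = (y - object$constant_mean)^2, indices = seq_along(y)))
  }
  p <- object$order["p"]; q <- object$order["q"]
  # Kalman one-step residuals under the frozen coefficients: refit with all
  # parameters fixed performs no optimisation, only filtering.
  cf <- object$coef
  fixed <- unname(cf)
  f <- suppressWarnings(stats::arima(y, order = c(p, 0L, q), fixed = fixed,
                                     transform.pars = FALSE, include.mean = TRUE))
  sc <- as.numeric(stats::residuals(f))^2
  list(scores = sc, indices = seq_along(y))
}
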