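#' Fit a multivariate autoregressive model by least squares
#'
#' Fits the order-p MVAR model
#' \deqn{x(t) = \sum_{k=1}^{p} A_k x(t-k) + \epsilon(t)}
#' by ordinary least squares on the lagged design over `t = p+1, ..., T`.
#' Channels are demeaned before fitting (the model describes zero-mean
#' signals; no intercept is estimated). The residual covariance uses the
#' effective sample size `T_eff = T - p`.
#'
#' @param recording An [sse_recording()].
#' @param p Model order (number of lags, >= 1).
#' @return An object of class `sse_mvar` with elements `A` (m x m x p array of
#'   lag matrices), `Sigma` (m x m residual covariance), `p`, `fs`,
#'   `channel_labels`, `t_eff` and `n_samples`.
#' @export
#' @examples
#' rec <- sse_recording(matrix(rnorm(2 * 2000), 2), fs = 100)
#' model <- fit_mvar(rec, p = 3)
#' stability_index(model)
fit_mvar <- function(recording, p) {
  stopifnot(inherits(recording, "sse_recording"))
  p <- as.integer(p)
  if (p < 1L) stop("model order `p` must be >= 1")
  m <- nrow(recording$data)
  T <- ncol(recording$data)
  if (T - p <= m * p)
    stop(sprintf("too few samples (T = %d) for m = %d channels at order %d",
                 T, m, p))
  x <- recording$data - rowMeans(recording$data)
  E <- stats::embed(t(x), p + 1L)         # (T - p) x m(p + 1)
  Y <- E[, seq_len(m), drop = FALSE]      # x(t)
  X <- E[, -seq_len(m), drop = FALSE]     # lag blocks x(t-1), ..., x(t-p)
  XtX <- crossprod(X)
  qrX <- qr(XtX)
  if (qrX$rank < ncol(X)) {
    dep <- unique(((seq_len(ncol(X)) - 1L) %% m) + 1L)
    bad <- dep[colSums(abs(stats::cor(X[, seq_len(m), drop = FALSE]) -
                             diag(m)) > 0.9999) > 0]
    stop("rank-deficient lagged design; check for duplicated or constant ",
         "channels (candidates: ",
         paste(recording$channel_labels[if (length(bad)) bad else dep],
               collapse = ", "), ")")
  }
  B <- solve(XtX, crossprod(X, Y))        # mp x m
  res <- Y - X %*% B
  t_eff <- T - p
  Sigma <- crossprod(res) / t_eff
  A <- array(0, dim = c(m, m, p))
  for (k in seq_len(p))
    A[, , k] <- t(B[(k - 1L) * m + seq_len(m), , drop = FALSE])
  structure(
    list(A = A, Sigma = Sigma, p = p, fs = recording$fs,
         channel_labels = recording$channel_labels,
         t_eff = t_eff, n_samples = T),
    class = "sse_mvar"
  )
}

#' @export
print.sse_mvar <- function(x, ...) {
  cat(sprintf("<sse_mvar> m = %d channels, order p = %d, fs = %g Hz\n",
              dim(x$A)[1], x$p, x$fs))
  cat(sprintf("  stability index: %.4f\n", stability_index(x)))
  invisible(x)
}

mvar_residuals <- function(model, recording) {
  m <- dim(model$A)[1]
  p <- model$p
  x <- recording$data - rowMeans(recording$data)
  E <- stats::embed(t(x), p + 1L)
  Y <- E[, seq_len(m), drop = FALSE]
  X <- E[, -seq_len(m), drop = FALSE]
  B <- matrix(0, m * p, m)
  for (k in seq_len(p))
    B[(k - 1L) * m + seq_len(m), ] <- t(model$A[, , k])
  Y - X %*% B
}

#' Stability index of a fitted model
#'
#' The largest modulus over the eigenvalues of the companion matrix. Values
#' below 1 indicate a stable (stationary) model; the index is also the
#' magnitude of the least-damped mode.
#'
#' @param model An [fit_mvar()] model.
#' @return Non-negative scalar.
#' @export
stability_index <- function(model) {
  stopifnot(inherits(model, "sse_mvar"))
  C <- companion(model)
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Durbin-Watson statistic of the model residuals
#'
#' Per-channel `sum((e_t - e_{t-1})^2) / sum(e_t^2)`. Values near 2 indicate
#' no first-order residual autocorrelation; near 0 strong positive, near 4
#' strong negative autocorrelation.
#'
#' @param model An [fit_mvar()] model.
#' @param recording The recording the model was fitted to.
#' @return Named numeric vector, one value in `[0, 4]` per channel.
#' @export
durbin_watson <- function(model, recording) {
  res <- mvar_residuals(model, recording)
  v <- colSums(res^2)
  if (any(v == 0)) stop("zero-variance residuals; Durbin-Watson undefined")
  dw <- colSums(diff(res)^2) / v
  stats::setNames(dw, model$channel_labels)
}

#' Variance explained by the model
#'
#' Per-channel percentage of signal variance captured by the one-step-ahead
#' predictions: `100 * (1 - var(residual) / var(signal))`. The signal variance
#' is taken over the same `t = p+1, ..., T` window as the residuals, per
#' channel (demeaned).
#'
#' @inheritParams durbin_watson
#' @return Named numeric vector of percentages.
#' @export
variance_explained <- function(model, recording) {
  res <- mvar_residuals(model, recording)
  x <- recording$data - rowMeans(recording$data)
  y <- t(x)[(model$p + 1L):ncol(x), , drop = FALSE]
  ve <- 100 * (1 - apply(res, 2, stats::var) / apply(y, 2, stats::var))
  stats::setNames(ve, model$channel_labels)
}

#' Akaike information criterion of a fitted model
#'
#' Computed as `T_eff * log det(Sigma) + 2 * m^2 * p` with
#' `T_eff = T - p`: the Gaussian log-likelihood term plus a penalty of two per
#' estimated autoregressive parameter. Lower is better. AIC alone often
#' decreases monotonically with order on real data, so combine it with the
#' spectral diagnostics when choosing `p`.
#'
#' @param model An [fit_mvar()] model.
#' @return Scalar AIC value.
#' @export
aic <- function(model) {
  stopifnot(inherits(model, "sse_mvar"))
  ld <- determinant(model$Sigma, logarithm = TRUE)
  if (ld$sign <= 0)
    stop("residual covariance is singular or not positive definite")
  m <- dim(model$A)[1]
  model$t_eff * as.numeric(ld$modulus) + 2 * m^2 * model$p
}

#' Model diagnostics summary
#'
#' Convenience wrapper returning the stability index, per-channel
#' Durbin-Watson and variance-explained values, and AIC for a fitted model.
#'
#' @inheritParams durbin_watson
#' @return A list of class `sse_diagnostics`.
#' @export
model_diagnostics <- function(model, recording) {
  structure(list(
    stability_index = stability_index(model),
    durbin_watson = durbin_watson(model, recording),
    variance_explained_pct = variance_explained(model, recording),
    aic = aic(model)
  ), class = "sse_diagnostics")
}

#' @export
print.sse_diagnostics <- function(x, ...) {
  cat(sprintf("<sse_diagnostics> SI = %.4f, AIC = %.1f\n",
              x$stability_index, x$aic))
  cat(sprintf("  Durbin-Watson: mean %.3f (range %.3f-%.3f)\n",
              mean(x$durbin_watson), min(x$durbin_watson),
              max(x$durbin_watson)))
  cat(sprintf("  variance explained: mean %.1f%% (range %.1f-%.1f%%)\n",
              mean(x$variance_explained_pct), min(x$variance_explained_pct),
              max(x$variance_explained_pct)))
  invisible(x)
}
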