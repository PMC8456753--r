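#' Frequency grid helper
#'
#' Evenly spaced frequencies on `[f_min, f_max]`. The default analysis grid is
#' 100 points on 0-48 Hz; the grid is fully configurable and must stay within
#' the Nyquist frequency of the model it is evaluated on.
#'
#' @param f_max Upper edge in Hz.
#' @param n Number of grid points (default 100).
#' @param f_min Lower edge in Hz (default 0).
#' @return Numeric vector of strictly increasing frequencies.
#' @export
frequency_grid <- function(f_max = 48, n = 100, f_min = 0) {
  if (f_max <= f_min) stop("`f_max` must exceed `f_min`")
  seq(f_min, f_max, length.out = n)
}

check_grid <- function(freqs, fs) {
  if (!length(freqs) || any(!is.finite(freqs)))
    stop("frequency grid must be finite and non-empty")
  if (is.unsorted(freqs, strictly = TRUE))
    stop("frequency grid must be strictly increasing")
  if (min(freqs) < 0 || max(freqs) > fs / 2)
    stop(sprintf("frequency grid must lie within [0, Nyquist = %g Hz]", fs / 2))
  freqs
}

#' Frequency response of the AR parameter matrix
#'
#' Evaluates `A(f) = sum_k A_k z^{-k}` with `z = exp(i 2 pi f / fs)` on a
#' frequency grid: the discrete-time Fourier transform of the lag sequence.
#'
#' @param model An [fit_mvar()] model.
#' @param freqs Numeric vector of frequencies in Hz (within Nyquist).
#' @return Complex array `nf x m x m`.
#' @export
a_of_f <- function(model, freqs) {
  stopifnot(inherits(model, "sse_mvar"))
  check_grid(freqs, model$fs)
  m <- dim(model$A)[1]
  p <- model$p
  out <- array(0i, dim = c(length(freqs), m, m))
  omega <- 2 * pi * freqs / model$fs
  for (k in seq_len(p)) {
    zk <- exp(-1i * omega * k)
    Ak <- model$A[, , k]
    for (fi in seq_along(freqs))
      out[fi, , ] <- out[fi, , ] + Ak * zk[fi]
  }
  out
}

#' Fourier-form transfer function
#'
#' `H(f) = (I - A(f))^{-1}` per frequency: the frequency-domain map from the
#' innovation process to the observed channels. Equal to the modal-form
#' transfer function summed over all modes (see [modal_transfer()]).
#'
#' @inheritParams a_of_f
#' @return An object of class `sse_transfer`: list with complex array `H`
#'   (`nf x m x m`), `freqs` and `fs`.
#' @export
transfer_function <- function(model, freqs) {
  Af <- a_of_f(model, freqs)
  m <- dim(Af)[2]
  H <- array(0i, dim = dim(Af))
  I <- diag(m)
  for (fi in seq_along(freqs)) {
    M <- I - Af[fi, , ]
    Hf <- tryCatch(solve(M), error = function(e) NULL)
    if (is.null(Hf))
      stop(sprintf("I - A(f) is singular at f = %g Hz (pole on the unit circle)",
                   freqs[fi]))
    H[fi, , ] <- Hf
  }
  structure(list(H = H, freqs = freqs, fs = model$fs), class = "sse_transfer")
}

#' Spectral (cross-spectral density) matrix
#'
#' `S(f) = H(f) Sigma H*(f)`: the model power spectrum of each channel on the
#' diagonal and the cross-spectrum between channels off the diagonal. Every
#' frequency slice is Hermitian with a real non-negative diagonal.
#'
#' @param H An [transfer_function()] object, or a single complex `m x m`
#'   matrix (then a single slice is returned).
#' @param Sigma Residual covariance matrix (positive semi-definite).
#' @return An object of class `sse_spectrum` (`S`, `freqs`, `fs`), or an
#'   `m x m` matrix when `H` is a single matrix.
#' @export
spectral_matrix <- function(H, Sigma) {
  if (is.matrix(H)) return(H %*% Sigma %*% Conj(t(H)))
  stopifnot(inherits(H, "sse_transfer"))
  S <- array(0i, dim = dim(H$H))
  for (fi in seq_along(H$freqs)) {
    Hf <- H$H[fi, , ]
    S[fi, , ] <- Hf %*% Sigma %*% Conj(t(Hf))
  }
  structure(list(S = S, freqs = H$freqs, fs = H$fs), class = "sse_spectrum")
}

#' Band-averaged spectral matrix
#'
#' Arithmetic mean of the spectral matrix over grid points inside the closed
#' band `[f_lo, f_hi]` -- the classical band-integrated network estimate that
#' the modal decomposition is compared against.
#'
#' @param S An [spectral_matrix()] object.
#' @param f_lo,f_hi Band edges in Hz (closed interval; a grid point on a
#'   boundary belongs to the band).
#' @return Complex `m x m` matrix.
#' @export
band_average <- function(S, f_lo, f_hi) {
  stopifnot(inherits(S, "sse_spectrum"))
  sel <- which(S$freqs >= f_lo & S$freqs <= f_hi)
  if (!length(sel))
    stop(sprintf("no grid points in band [%g, %g] Hz", f_lo, f_hi))
  out <- 0i * S$S[1, , ]
  for (fi in sel) out <- out + S$S[fi, , ]
  out / length(sel)
}
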