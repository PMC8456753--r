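#' Companion matrix of an MVAR model
#'
#' Rewrites the order-p model as an order-1 system over the delay embedding
#' `X(t) = {x(t), x(t-1), ..., x(t-p+1)}`: the top block row holds
#' `[A_1 ... A_p]` and identity blocks on the sub-diagonal shift the embedding
#' down. The eigenvalues of this `mp x mp` matrix are the poles of the fitted
#' system.
#'
#' @param model An [fit_mvar()] model.
#' @return Real `mp x mp` matrix.
#' @export
companion <- function(model) {
  stopifnot(inherits(model, "sse_mvar"))
  m <- dim(model$A)[1]
  p <- model$p
  C <- matrix(0, m * p, m * p)
  for (k in seq_len(p))
    C[seq_len(m), (k - 1L) * m + seq_len(m)] <- model$A[, , k]
  if (p > 1L) {
    idx <- seq_len(m * (p - 1L))
    C[cbind(m + idx, idx)] <- 1
  }
  C
}

#' Peak frequency of a pole
#'
#' The characteristic frequency of an eigenvalue of the companion matrix:
#' `rho = fs * |arg(lambda)| / (2 pi)` Hz. Positive real poles sit at 0 Hz,
#' negative real poles at Nyquist; conjugate pairs share one positive
#' frequency.
#'
#' @param lam Complex eigenvalue(s), non-zero.
#' @param fs Sampling rate in Hz.
#' @return Frequency (Hz) in `[0, fs/2]`, vectorised over `lam`.
#' @export
peak_frequency <- function(lam, fs) {
  if (any(lam == 0)) stop("peak frequency undefined for a zero eigenvalue")
  fs * abs(Arg(lam)) / (2 * pi)
}

#' Damping time of a pole
#'
#' `delta = -1 / log|lambda|` samples: the time for an impulse-excited mode's
#' envelope to decay by a factor `e`. Longer damping times mark less damped,
#' dynamically important modes. Only defined for `0 < |lambda| < 1`.
#'
#' @param lam Complex eigenvalue(s).
#' @param fs Sampling rate in Hz (for the seconds conversion).
#' @return A list with numeric vectors `samples` and `seconds`.
#' @export
damping_time <- function(lam, fs) {
  md <- Mod(lam)
  if (any(md <= 0)) stop("damping time undefined for a zero eigenvalue")
  if (any(md >= 1))
    stop("damping time undefined for |lambda| >= 1 (unstable mode); ",
         "refusing to return an infinite value")
  s <- -1 / log(md)
  list(samples = s, seconds = s / fs)
}

#' Modal decomposition of an MVAR model
#'
#' Eigendecomposes the companion matrix into `mp` modes. Right eigenvectors
#' `V` come from the eigensolver; left eigenvectors are taken as the rows of
#' `V^{-1}` so that biorthogonality `W V = I` holds exactly (up to the
#' reported residual) and the partial-fraction residues need no further
#' scaling. Each mode carries its eigenvalue, peak frequency, damping time and
#' rank-1 residue matrix `R_j` (outer product of the first `m` entries of the
#' right and left vectors). Modes are sorted by descending damping time and
#' conjugate partners are linked.
#'
#' @param model An [fit_mvar()] model.
#' @return An object of class `sse_modal`: list with `lambda` (length `mp`
#'   complex), `rho_hz`, `delta_samples`, `delta_s`, `magnitude`,
#'   `conjugate_partner` (index or `NA`), `residues` (list of `m x m` complex
#'   matrices), `V_red`/`W_red` (`m x mp` reduced right / `mp x m` reduced
#'   left vectors), `biorth_residual`, `m`, `p`, `fs`, `Sigma`,
#'   `channel_labels`.
#' @export
modal_decomposition <- function(model) {
  stopifnot(inherits(model, "sse_mvar"))
  m <- dim(model$A)[1]
  p <- model$p
  C <- companion(model)
  eg <- eigen(C)
  # keep complex storage even when all eigenvalues happen to be real
  V <- eg$vectors + 0i
  lam <- eg$values + 0i
  W <- solve(V)
  biorth <- max(Mod(W %*% V - diag(m * p)))

  if (length(lam) > 1) {
    d <- outer(lam, lam, function(a, b) Mod(a - b))
    diag(d) <- Inf
    if (min(d) < 1e-10)
      warning("nearly repeated eigenvalues detected (spacing < 1e-10); ",
              "the simple partial-fraction expansion may be ill-conditioned")
  }

  delta <- -1 / log(pmin(Mod(lam), 1 - 1e-15))
  ord <- order(delta, decreasing = TRUE)
  lam <- lam[ord]
  V <- V[, ord, drop = FALSE]
  W <- W[ord, , drop = FALSE]
  delta <- delta[ord]

  # link conjugate partners by nearest conjugate eigenvalue
  n <- length(lam)
  partner <- rep(NA_integer_, n)
  tol <- 1e-8 * max(1, max(Mod(lam)))
  for (j in seq_len(n)) {
    if (abs(Im(lam[j])) < tol) next
    if (!is.na(partner[j])) next
    d <- Mod(lam - Conj(lam[j]))
    d[j] <- Inf
    d[!is.na(partner)] <- Inf
    k <- which.min(d)
    if (is.finite(d[k]) && d[k] < 1e-6 * max(1, Mod(lam[j]))) {
      partner[j] <- k
      partner[k] <- j
    }
  }

  V_red <- V[seq_len(m), , drop = FALSE]
  W_red <- W[, seq_len(m), drop = FALSE]
  residues <- lapply(seq_len(n), function(j)
    V_red[, j] %o% W_red[j, ])

  structure(list(
    lambda = lam,
    rho_hz = peak_frequency(lam, model$fs),
    delta_samples = delta,
    delta_s = delta / model$fs,
    magnitude = Mod(lam),
    conjugate_partner = partner,
    residues = residues,
    V_red = V_red, W_red = W_red,
    biorth_residual = biorth,
    m = m, p = p, fs = model$fs,
    Sigma = model$Sigma,
    channel_labels = model$channel_labels
  ), class = "sse_modal")
}

#' @export
print.sse_modal <- function(x, ...) {
  cat(sprintf("<sse_modal> %d modes (m = %d, p = %d, fs = %g Hz)\n",
              length(x$lambda), x$m, x$p, x$fs))
  cat(sprintf("  longest damping times (samples): %s\n",
              paste(sprintf("%.1f", utils::head(x$delta_samples, 3)),
                    collapse = ", ")))
  invisible(x)
}

expand_with_partners <- function(decomposition, modes) {
  modes <- unique(as.integer(modes))
  if (any(modes < 1 | modes > length(decomposition$lambda)))
    stop("mode index out of range")
  partners <- decomposition$conjugate_partner[modes]
  sort(unique(c(modes, partners[!is.na(partners)])))
}

#' Modal (partial-fraction) form of the transfer function
#'
#' Evaluates `H(f) = sum_j R_j z / (z - lambda_j)` with `z = exp(i 2 pi f /
#' fs)` over a subset of modes. With all `mp` modes the result equals the
#' Fourier form `(I - A(f))^{-1}` exactly; with a subset it is the reduced
#' transfer function isolating those resonances. When an oscillatory mode is
#' requested its conjugate partner is automatically included so the reduced
#' system corresponds to a real-valued signal.
#'
#' @param decomposition An [modal_decomposition()].
#' @param freqs Frequencies in Hz (within Nyquist).
#' @param modes Integer indices of modes to include (default all). An empty
#'   subset gives the zero transfer function.
#' @param include_partners Automatically add conjugate partners (default
#'   `TRUE`).
#' @return An `sse_transfer` object (see [transfer_function()]).
#' @export
modal_transfer <- function(decomposition, freqs, modes = NULL,
                           include_partners = TRUE) {
  stopifnot(inherits(decomposition, "sse_modal"))
  check_grid(freqs, decomposition$fs)
  n <- length(decomposition$lambda)
  if (is.null(modes)) modes <- seq_len(n)
  if (length(modes) && include_partners)
    modes <- expand_with_partners(decomposition, modes)
  m <- decomposition$m
  H <- array(0i, dim = c(length(freqs), m, m))
  z <- exp(1i * 2 * pi * freqs / decomposition$fs)
  for (j in modes) {
    lamj <- decomposition$lambda[j]
    if (any(Mod(z - lamj) < 1e-14))
      stop(sprintf("grid point coincides with pole at %g Hz; H undefined there",
                   decomposition$rho_hz[j]))
    g <- z / (z - lamj)
    Rj <- decomposition$residues[[j]]
    for (fi in seq_along(freqs))
      H[fi, , ] <- H[fi, , ] + Rj * g[fi]
  }
  structure(list(H = H, freqs = freqs, fs = decomposition$fs),
            class = "sse_transfer")
}

#' Spectral matrix of a mode subset at one frequency
#'
#' Evaluates the reduced transfer function of the given modes at a single
#' frequency (by default the peak frequency of the first requested mode) and
#' forms `S = H Sigma H*`: the network matrix of those resonances, with node
#' power on the diagonal and connection strength off it.
#'
#' @inheritParams modal_transfer
#' @param Sigma Residual covariance; defaults to the one stored in the
#'   decomposition.
#' @param at_frequency Evaluation frequency in Hz; default is the peak
#'   frequency of `modes[1]`.
#' @return Complex `m x m` matrix.
#' @export
mode_spectral_matrix <- function(decomposition, modes, Sigma = NULL,
                                 at_frequency = NULL,
                                 include_partners = TRUE) {
  stopifnot(inherits(decomposition, "sse_modal"))
  if (is.null(Sigma)) Sigma <- decomposition$Sigma
  if (is.null(at_frequency)) {
    if (!length(modes)) stop("`at_frequency` required for an empty subset")
    at_frequency <- decomposition$rho_hz[modes[1]]
  }
  H <- modal_transfer(decomposition, at_frequency, modes,
                      include_partners = include_partners)
  Hf <- H$H[1, , ]
  Hf %*% Sigma %*% Conj(t(Hf))
}

#' Extract the spatio-spectral eigenmodes
#'
#' Collapses the `mp` raw modes to one SSE per non-negative-frequency mode
#' (each conjugate pair is represented once, its partner retained internally)
#' and attaches, for each SSE, its transfer function and spectral matrix
#' evaluated at its own peak frequency: the triple of peak frequency, damping
#' time and spatial network that defines a spatio-spectral eigenmode.
#'
#' @param decomposition An [modal_decomposition()].
#' @param Sigma Residual covariance (defaults to the stored one).
#' @param include_partners Evaluate each SSE's transfer function with its
#'   conjugate partner included (default `TRUE`, so the network corresponds
#'   to a real signal).
#' @return An object of class `sse_set`: list with `table` (data frame: one
#'   row per SSE with `mode`, `partner`, `rho_hz`, `delta_samples`,
#'   `delta_s`, `magnitude`, `is_real_pole`, `selected`), `H_rho` and
#'   `S_rho` (lists of `m x m` complex matrices), plus `decomposition`
#'   metadata. `selected` is `NA` until [select_modes()] is applied.
#' @export
extract_sses <- function(decomposition, Sigma = NULL,
                         include_partners = TRUE) {
  stopifnot(inherits(decomposition, "sse_modal"))
  if (is.null(Sigma)) Sigma <- decomposition$Sigma
  keep <- which(Im(decomposition$lambda) >= 0 |
                  abs(Im(decomposition$lambda)) <
                    1e-12 * pmax(1, Mod(decomposition$lambda)))
  tab <- data.frame(
    mode = keep,
    partner = decomposition$conjugate_partner[keep],
    rho_hz = decomposition$rho_hz[keep],
    delta_samples = decomposition$delta_samples[keep],
    delta_s = decomposition$delta_s[keep],
    magnitude = decomposition$magnitude[keep],
    is_real_pole = is.na(decomposition$conjugate_partner[keep]),
    selected = NA
  )
  H_rho <- vector("list", nrow(tab))
  S_rho <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    H <- modal_transfer(decomposition, tab$rho_hz[i], tab$mode[i],
                        include_partners = include_partners)
    Hf <- H$H[1, , ]
    H_rho[[i]] <- Hf
    S_rho[[i]] <- Hf %*% Sigma %*% Conj(t(Hf))
  }
  structure(list(table = tab, H_rho = H_rho, S_rho = S_rho,
                 decomposition = decomposition,
                 m = decomposition$m, fs = decomposition$fs,
                 provenance = list()),
            class = "sse_set")
}

#' @export
print.sse_set <- function(x, ...) {
  nsel <- sum(x$table$selected, na.rm = TRUE)
  cat(sprintf("<sse_set> %d SSEs over %d nodes", nrow(x$table), x$m))
  if (any(!is.na(x$table$selected)))
    cat(sprintf(" (%d selected)", nsel))
  cat("\n")
  print(utils::head(x$table[order(-x$table$delta_samples),
                            c("rho_hz", "delta_samples", "magnitude",
                              "is_real_pole", "selected")], 5))
  invisible(x)
}

#' Individual alpha frequency
#'
#' The damping-time-weighted mean peak frequency of SSEs in a band (default
#' 6-14 Hz): `sum(delta_j rho_j) / sum(delta_j)`. When a permutation
#' selection has been applied only selected SSEs enter; otherwise all in-band
#' SSEs do.
#'
#' @param sse_set An [extract_sses()] set.
#' @param f_lo,f_hi Band edges in Hz (closed interval).
#' @return Scalar frequency in Hz.
#' @export
individual_alpha_frequency <- function(sse_set, f_lo = 6, f_hi = 14) {
  stopifnot(inherits(sse_set, "sse_set"))
  tab <- sse_set$table
  inband <- tab$rho_hz >= f_lo & tab$rho_hz <= f_hi
  if (any(!is.na(tab$selected)))
    inband <- inband & !is.na(tab$selected) & tab$selected
  if (!any(inband))
    stop(sprintf("no SSEs with peak frequency in [%g, %g] Hz", f_lo, f_hi))
  w <- tab$delta_samples[inband]
  sum(w * tab$rho_hz[inband]) / sum(w)
}

#' SSE table export
#'
#' Returns the per-mode summary table (peak frequency, damping time,
#' magnitude, real-pole flag and selection flag), suitable for writing as
#' TSV.
#'
#' @param sse_set An [extract_sses()] set.
#' @return A data frame.
#' @export
sse_table <- function(sse_set) {
  stopifnot(inherits(sse_set, "sse_set"))
  sse_set$table
}
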