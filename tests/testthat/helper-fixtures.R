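# Shared fixtures: hand-built MVAR models and small simulation specs.

# Construct an sse_mvar object directly from parameter matrices (no fitting).
make_mvar <- function(A, Sigma = NULL, fs = 128, t_eff = 1000) {
  if (is.matrix(A)) A <- array(A, dim = c(nrow(A), ncol(A), 1L))
  m <- dim(A)[1]
  if (is.null(Sigma)) Sigma <- diag(m)
  structure(
    list(A = A, Sigma = Sigma, p = dim(A)[3], fs = fs,
         channel_labels = sprintf("ch%02d", seq_len(m)),
         t_eff = t_eff, n_samples = t_eff + dim(A)[3]),
    class = "sse_mvar"
  )
}

# Random stable MVAR model: random lag matrices rescaled so the companion
# spectral radius equals target_si (scaling A_k by s^k scales eigenvalues by s).
random_stable_model <- function(m, p, fs = 128, target_si = 0.9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- array(stats::rnorm(m * m * p, sd = 0.3 / sqrt(m * p)), dim = c(m, m, p))
  model <- make_mvar(A, fs = fs)
  si <- stability_index(model)
  s <- target_si / si
  for (k in seq_len(p)) A[, , k] <- A[, , k] * s^k
  L <- matrix(stats::rnorm(m * m, sd = 0.3), m)
  make_mvar(A, Sigma = diag(m) + tcrossprod(L) * 0.1, fs = fs)
}

# Small, fast variant of the stock two-network simulation.
small_alpha_spec <- function(duration_s = 60, fs = 64, ...) {
  alpha_network_spec(duration_s = duration_s, fs = fs, ...)
}

# Minimal sse_set with given peak frequencies / damping times / matrices,
# for exercising band selection, stacking and IAF logic without a fit.
make_fake_sse_set <- function(rho_hz, delta_samples, S_list,
                              selected = NA, fs = 128) {
  n <- length(rho_hz)
  m <- nrow(S_list[[1]])
  tab <- data.frame(
    mode = seq_len(n), partner = NA_integer_, rho_hz = rho_hz,
    delta_samples = delta_samples, delta_s = delta_samples / fs,
    magnitude = exp(-1 / delta_samples), is_real_pole = rho_hz == 0,
    selected = selected
  )
  structure(list(table = tab, H_rho = S_list, S_rho = S_list,
                 decomposition = NULL, m = m, fs = fs, provenance = list()),
            class = "sse_set")
}

# Welch-style smoothed periodogram peak frequency of a single series.
periodogram_peak_hz <- function(x, fs) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = c(101, 101),
                          plot = FALSE, detrend = TRUE)
  sp$freq[which.max(sp$spec)]
}
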