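#' Score network recovery on a simulated group
#'
#' Runs the full analysis chain on each realisation of a simulated group and
#' scores it against the planted ground truth: fit an MVAR, decompose into
#' modes, select dynamically important modes by the damping-time permutation
#' null, then correlate (Pearson, over vectorised `m x m` matrices)
#' \itemize{
#'   \item each planted mode's rank-1 ground-truth network against the
#'     spectral matrix of the selected SSEs assigned to it (`modal_truth_r`),
#'   \item the same truth against the Fourier band-integrated network of the
#'     corresponding band (`fourier_truth_r`),
#'   \item the Fourier band network of the oscillatory band against the
#'     residual network, i.e. the band-averaged spectral matrix of the modes
#'     NOT surviving the permutation threshold (`fourier_residual_r`),
#'   \item the selected oscillatory modal network against that same residual
#'     network (`modal_residual_r`).
#' }
#' A selected SSE is assigned to a planted mode when its peak frequency lies
#' within `assign_tol_hz` of the planted frequency; Fourier bands are
#' `band_lo` for the 0 Hz mode and `band_hi` for the oscillatory mode.
#'
#' @param realisations Output of [group_simulation()].
#' @param p MVAR order (default 5).
#' @param freqs Frequency grid for the Fourier/residual band averages
#'   (default 100 points on 0-48 Hz).
#' @param band_lo,band_hi Low/high band edges in Hz (defaults 0-4, 8-12).
#' @param assign_tol_hz Half-width for assigning a selected SSE to a planted
#'   mode (default 4 Hz, the band half-width).
#' @param n_perm,epoch_len_s,alpha_tail Permutation settings (see
#'   [null_distribution()]).
#' @param seed Master seed for the permutation nulls.
#' @return A data frame with one row per (realisation, planted mode):
#'   `realisation`, `mode`, `planted_hz`, `recovered_hz`, `n_assigned`,
#'   `modal_truth_r`, `fourier_truth_r`, and per oscillatory-mode rows
#'   `fourier_residual_r`, `modal_residual_r` (`NA` for the 0 Hz mode).
#' @export
group_network_recovery <- function(realisations, p = 5,
                                   freqs = frequency_grid(48, 100),
                                   band_lo = c(0, 4), band_hi = c(8, 12),
                                   assign_tol_hz = 4,
                                   n_perm = 100, epoch_len_s = 5,
                                   alpha_tail = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  null_seeds <- sample.int(.Machine$integer.max - 1L, length(realisations))
  out <- list()
  for (ri in seq_along(realisations)) {
    r <- realisations[[ri]]
    model <- fit_mvar(r$recording, p)
    decomp <- modal_decomposition(model)
    null <- null_distribution(r$recording, p, n_perm = n_perm,
                              epoch_len_s = epoch_len_s,
                              alpha_tail = alpha_tail,
                              seed = null_seeds[ri])
    sset <- select_modes(extract_sses(decomp), null)
    tab <- sse_table(sset)
    truth <- true_network(r$modes)
    S <- spectral_matrix(transfer_function(model, freqs), model$Sigma)

    sel_raw <- tab$mode[tab$selected]
    sel_all <- unique(c(sel_raw, decomp$conjugate_partner[sel_raw]))
    resid_modes <- setdiff(seq_along(decomp$lambda), sel_all[!is.na(sel_all)])
    S_resid <- spectral_matrix(
      modal_transfer(decomp, freqs, resid_modes, include_partners = FALSE),
      model$Sigma)
    resid_net <- Mod(band_average(S_resid, band_hi[1], band_hi[2]))
    fourier_hi <- Mod(band_average(S, band_hi[1], band_hi[2]))
    fourier_lo <- Mod(band_average(S, band_lo[1], band_lo[2]))

    vec_cor <- function(a, b) stats::cor(as.numeric(a), as.numeric(b))
    for (mi in seq_along(r$modes)) {
      f0 <- r$modes[[mi]]$frequency_hz
      cand <- which(tab$selected & abs(tab$rho_hz - f0) <= assign_tol_hz)
      modal_net <- if (length(cand)) Mod(Reduce(`+`, sset$S_rho[cand]))
      oscillatory <- f0 > 0
      fourier_net <- if (oscillatory) fourier_hi else fourier_lo
      out[[length(out) + 1L]] <- data.frame(
        realisation = ri, mode = mi, planted_hz = f0,
        recovered_hz = if (length(cand))
          tab$rho_hz[cand[which.max(tab$delta_samples[cand])]] else NA_real_,
        n_assigned = length(cand),
        modal_truth_r = if (length(cand))
          vec_cor(modal_net, truth[[mi]]) else NA_real_,
        fourier_truth_r = vec_cor(fourier_net, truth[[mi]]),
        fourier_residual_r = if (oscillatory)
          vec_cor(fourier_hi, resid_net) else NA_real_,
        modal_residual_r = if (oscillatory && length(cand))
          vec_cor(modal_net, resid_net) else NA_real_
      )
    }
  }
  do.call(rbind, out)
}
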