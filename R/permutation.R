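#' Split a recording into non-overlapping epochs
#'
#' Cuts the continuous recording into equal non-overlapping temporal epochs,
#' giving a channels x samples x epochs array. Trailing samples that do not
#' fill a whole epoch are discarded.
#'
#' @param recording An [sse_recording()].
#' @param epoch_len_s Epoch length in seconds.
#' @return An object of class `sse_epochs`: list with `data` (m x n x k
#'   array), `fs`, `channel_labels`.
#' @export
epoch_split <- function(recording, epoch_len_s) {
  stopifnot(inherits(recording, "sse_recording"))
  n_ep <- floor(epoch_len_s * recording$fs)
  if (n_ep < 2) stop("epoch length must cover at least 2 samples")
  T <- ncol(recording$data)
  k <- floor(T / n_ep)
  if (k < 2)
    stop(sprintf("epoch length %g s gives only %d epoch(s); need >= 2",
                 epoch_len_s, k))
  m <- nrow(recording$data)
  data <- array(recording$data[, seq_len(n_ep * k)], dim = c(m, n_ep, k))
  structure(list(data = data, fs = recording$fs,
                 channel_labels = recording$channel_labels),
            class = "sse_epochs")
}

#' Channel-and-epoch shuffled surrogate
#'
#' Pools all (channel, epoch) segments and redistributes them by a single
#' global permutation without replacement, so every lagged relationship
#' between channels is destroyed while the multiset of segments -- and hence
#' the pooled amplitude spectrum -- is preserved exactly. Each surrogate
#' channel is the concatenation of its reassigned epochs.
#'
#' @param epoched An [epoch_split()] object.
#' @param seed Optional integer seed.
#' @param replace Sample segments with replacement instead (default `FALSE`,
#'   the exact-multiset permutation).
#' @return An [sse_recording()] of the same shape as the epoched input.
#' @export
surrogate <- function(epoched, seed = NULL, replace = FALSE) {
  stopifnot(inherits(epoched, "sse_epochs"))
  if (!is.null(seed)) set.seed(seed)
  dm <- dim(epoched$data)
  m <- dm[1]; n_ep <- dm[2]; k <- dm[3]
  # pooled segments: cell (i, e) -> row i + (e-1)*m of the pooled matrix
  pool <- matrix(aperm(epoched$data, c(2, 1, 3)), nrow = n_ep)  # n_ep x (m*k)
  idx <- if (replace) sample.int(m * k, m * k, replace = TRUE)
         else sample.int(m * k)
  shuffled <- pool[, idx, drop = FALSE]
  out <- matrix(0, m, n_ep * k)
  for (i in seq_len(m)) {
    cols <- (seq_len(k) - 1L) * m + i
    out[i, ] <- as.numeric(shuffled[, cols])
  }
  sse_recording(out, fs = epoched$fs, channel_labels = epoched$channel_labels)
}

#' Max-statistic permutation null of damping times
#'
#' Builds the null distribution used to select dynamically important modes:
#' for each permutation a channel/epoch-shuffled surrogate is fitted with an
#' MVAR of the same order, its modal decomposition computed, and the maximum
#' damping time over all modes entered into the null. The selection threshold
#' is the empirical `(1 - alpha_tail)` quantile of this max-statistic null,
#' which controls the family-wise error rate over all `mp` modes. Surrogate
#' fits that come out unstable are retried once with a fresh shuffle and then
#' skipped with a warning.
#'
#' @param recording An [sse_recording()].
#' @param p MVAR model order used for both data and surrogates.
#' @param n_perm Number of permutations (default 200; at least `1/alpha_tail`
#'   are required to resolve the tail).
#' @param epoch_len_s Epoch length in seconds (default 5).
#' @param alpha_tail Tail probability of the threshold (default 0.01).
#' @param seed Optional integer seed; fixes the whole null reproducibly.
#' @return An object of class `sse_null`: list with `null_max_damping`
#'   (samples), `threshold`, `alpha_tail`, `n_perm`, `epoch_len_s`, `seed`.
#' @export
null_distribution <- function(recording, p, n_perm = 200, epoch_len_s = 5,
                              alpha_tail = 0.01, seed = NULL) {
  if (alpha_tail < 0 || alpha_tail >= 1)
    stop("`alpha_tail` must lie in [0, 1)")
  if (alpha_tail > 0 && n_perm < 1 / alpha_tail)
    stop(sprintf("n_perm = %d cannot resolve a %.3g tail; need >= %d",
                 n_perm, alpha_tail, ceiling(1 / alpha_tail)))
  epoched <- epoch_split(recording, epoch_len_s)
  if (!is.null(seed)) set.seed(seed)
  null_max <- rep(NA_real_, n_perm)
  n_skipped <- 0L
  for (b in seq_len(n_perm)) {
    val <- NA_real_
    for (attempt in 1:2) {
      sur <- surrogate(epoched)
      fit <- fit_mvar(sur, p)
      si <- stability_index(fit)
      if (si < 1) {
        val <- -1 / log(si)
        break
      }
    }
    if (is.na(val)) n_skipped <- n_skipped + 1L
    null_max[b] <- val
  }
  if (n_skipped > 0)
    warning(sprintf("%d permutation(s) skipped after unstable surrogate fits",
                    n_skipped))
  null_max <- null_max[!is.na(null_max)]
  threshold <- if (alpha_tail == 0) max(null_max)
               else as.numeric(stats::quantile(null_max, 1 - alpha_tail))
  structure(list(null_max_damping = null_max, threshold = threshold,
                 alpha_tail = alpha_tail, n_perm = n_perm,
                 epoch_len_s = epoch_len_s, seed = seed),
            class = "sse_null")
}

#' @export
print.sse_null <- function(x, ...) {
  cat(sprintf(
    "<sse_null> %d permutations, %.3g tail -> threshold %.2f samples\n",
    length(x$null_max_damping), x$alpha_tail, x$threshold))
  invisible(x)
}

#' Select SSEs against a permutation null
#'
#' Flags as selected every SSE whose damping time (in samples) exceeds the
#' null threshold; all SSEs are retained in the table either way.
#'
#' @param sse_set An [extract_sses()] set.
#' @param null An [null_distribution()] object, or a numeric threshold in
#'   samples.
#' @return The `sse_set` with the `selected` column filled in and the
#'   threshold recorded under `provenance`.
#' @export
select_modes <- function(sse_set, null) {
  stopifnot(inherits(sse_set, "sse_set"))
  threshold <- if (inherits(null, "sse_null")) null$threshold else
    as.numeric(null)
  sse_set$table$selected <- sse_set$table$delta_samples > threshold
  sse_set$provenance$threshold <- threshold
  if (inherits(null, "sse_null")) {
    sse_set$provenance$alpha_tail <- null$alpha_tail
    sse_set$provenance$n_perm <- null$n_perm
    sse_set$provenance$permutation_seed <- null$seed
  }
  sse_set
}
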