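#' Stack in-band mode networks for spatial PCA
#'
#' Collects, across one or many SSE sets, the spectral matrices of modes whose
#' peak frequency lies in the closed band `[f_lo, f_hi]`, vectorises their
#' magnitudes to rows of a `modes x m^2` matrix and removes the column means
#' (the mean network). Band membership depends only on the peak frequency:
#' once a mode is in, its full network enters. When permutation selection has
#' been applied to a set only selected modes are stacked.
#'
#' @param sse_sets One [extract_sses()] set or a list of them (e.g. one per
#'   participant/realisation), all sharing the node count.
#' @param f_lo,f_hi Band edges in Hz (closed interval).
#' @param use_magnitude Stack `|S|` (default); `FALSE` stacks `Re(S)`.
#' @return An object of class `sse_stack`: list with `X` (demeaned rows),
#'   `grand_mean` (column means), `index` (data frame mapping rows to dataset
#'   and mode, with peak frequencies), `m`, `band`.
#' @export
stack_mode_networks <- function(sse_sets, f_lo, f_hi, use_magnitude = TRUE) {
  if (inherits(sse_sets, "sse_set")) sse_sets <- list(sse_sets)
  stopifnot(all(vapply(sse_sets, inherits, TRUE, "sse_set")))
  m <- unique(vapply(sse_sets, function(s) s$m, 1L))
  if (length(m) != 1L) stop("all SSE sets must share the node count")
  rows <- list(); idx <- list()
  for (d in seq_along(sse_sets)) {
    set <- sse_sets[[d]]
    tab <- set$table
    inband <- tab$rho_hz >= f_lo & tab$rho_hz <= f_hi
    if (any(!is.na(tab$selected)))
      inband <- inband & !is.na(tab$selected) & tab$selected
    for (i in which(inband)) {
      Si <- set$S_rho[[i]]
      v <- if (use_magnitude) Mod(Si) else Re(Si)
      rows[[length(rows) + 1L]] <- as.numeric(t(v))  # row-major vectorisation
      idx[[length(idx) + 1L]] <- data.frame(
        dataset = d, mode = tab$mode[i], rho_hz = tab$rho_hz[i],
        delta_samples = tab$delta_samples[i])
    }
  }
  if (!length(rows))
    stop(sprintf("no SSEs with peak frequency in [%g, %g] Hz", f_lo, f_hi))
  X <- do.call(rbind, rows)
  grand_mean <- colMeans(X)
  structure(list(X = sweep(X, 2, grand_mean), grand_mean = grand_mean,
                 index = do.call(rbind, idx), m = m, band = c(f_lo, f_hi)),
            class = "sse_stack")
}

fix_component_signs <- function(components) {
  for (k in seq_len(nrow(components))) {
    j <- which.max(abs(components[k, ]))
    if (components[k, j] < 0) components[k, ] <- -components[k, ]
  }
  components
}

#' Spatial PCA of stacked mode networks
#'
#' Singular value decomposition of the demeaned `modes x m^2` matrix. The
#' components are the principal axes of variation across network connections;
#' the scores say how strongly each mode expresses each axis. Components are
#' sign-fixed so the largest-magnitude weight is positive, making results
#' reproducible across runs and eigensolvers.
#'
#' @param stacked An [stack_mode_networks()] object.
#' @param n_comp Number of components to keep (default: all with non-zero
#'   variance, capped at 10).
#' @return An object of class `sse_pca`: `components` (n_comp x m^2,
#'   orthonormal rows), `scores` (n_modes x n_comp),
#'   `variance_explained_pct`, `grand_mean`, `index`, `m`, `band`.
#' @export
spatial_pca <- function(stacked, n_comp = NULL) {
  stopifnot(inherits(stacked, "sse_stack"))
  X <- stacked$X
  if (nrow(X) < 2) stop("spatial PCA needs at least 2 stacked mode networks")
  sv <- svd(X)
  tot <- sum(sv$d^2)
  nonzero <- sum(sv$d^2 > 1e-12 * max(tot, 1))
  if (nonzero == 0) {
    warning("stacked networks are identical: zero total variance, ",
            "no components returned")
    n_keep <- 0L
  } else {
    n_keep <- if (is.null(n_comp)) min(nonzero, 10L) else min(n_comp, nonzero)
  }
  comps <- t(sv$v[, seq_len(n_keep), drop = FALSE])
  comps <- fix_component_signs(comps)
  scores <- X %*% t(comps)
  structure(list(
    components = comps, scores = scores,
    variance_explained_pct = 100 * sv$d[seq_len(n_keep)]^2 / tot,
    grand_mean = stacked$grand_mean, index = stacked$index,
    m = stacked$m, band = stacked$band
  ), class = "sse_pca")
}

#' @export
print.sse_pca <- function(x, ...) {
  cat(sprintf("<sse_pca> %d components over %d networks (band %g-%g Hz)\n",
              nrow(x$components), nrow(x$scores), x$band[1], x$band[2]))
  cat("  variance explained (%):",
      paste(sprintf("%.1f", utils::head(x$variance_explained_pct, 5)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Split-half reliability of spatial components
#'
#' Randomly splits the in-band mode networks into disjoint halves, computes a
#' PCA on each half independently, and correlates component k of one half
#' with component k of the other (absolute Pearson, after the sign
#' convention). Repeated over `n_splits` random splits; the mean absolute
#' correlation per component measures how reproducible that spatial axis is.
#'
#' @inheritParams stack_mode_networks
#' @param n_splits Number of random splits (default 500).
#' @param n_comp Number of leading components to assess (default 5).
#' @param seed Optional integer seed.
#' @return Numeric vector: mean `|r|` per component.
#' @export
split_half_reliability <- function(sse_sets, f_lo, f_hi, n_splits = 500,
                                   n_comp = 5, seed = NULL,
                                   use_magnitude = TRUE) {
  stacked <- stack_mode_networks(sse_sets, f_lo, f_hi,
                                 use_magnitude = use_magnitude)
  raw <- sweep(stacked$X, 2, stacked$grand_mean, "+")  # un-demeaned rows
  n <- nrow(raw)
  if (n < 4) stop("split-half reliability needs at least 4 in-band SSEs")
  if (!is.null(seed)) set.seed(seed)
  half_pca <- function(rows) {
    Xh <- sweep(rows, 2, colMeans(rows))
    sv <- svd(Xh)
    fix_component_signs(t(sv$v))
  }
  k_max <- 0L
  acc <- matrix(NA_real_, n_splits, n_comp)
  for (s in seq_len(n_splits)) {
    ia <- sample.int(n, floor(n / 2))
    A <- half_pca(raw[ia, , drop = FALSE])
    B <- half_pca(raw[-ia, , drop = FALSE])
    k <- min(nrow(A), nrow(B), n_comp)
    k_max <- max(k_max, k)
    for (j in seq_len(k))
      acc[s, j] <- abs(stats::cor(A[j, ], B[j, ]))
  }
  colMeans(acc[, seq_len(k_max), drop = FALSE], na.rm = TRUE)
}

#' Project score extremes back to network maps
#'
#' Reconstructs the networks implied by the maximum and minimum observed
#' score on one component: `grand_mean + score * component`, reshaped to
#' `m x m`. The two maps differ by `(max - min) * component` exactly.
#'
#' @param pca An [spatial_pca()] result.
#' @param component_idx Component number (1-based).
#' @return List with `max` and `min` (`m x m` matrices) and the two scores.
#' @export
project_score_extremes <- function(pca, component_idx = 1) {
  stopifnot(inherits(pca, "sse_pca"))
  if (component_idx < 1 || component_idx > nrow(pca$components))
    stop("no such component")
  sc <- pca$scores[, component_idx]
  comp <- pca$components[component_idx, ]
  reshape_map <- function(v) matrix(v, pca$m, pca$m, byrow = TRUE)
  list(max = reshape_map(pca$grand_mean + max(sc) * comp),
       min = reshape_map(pca$grand_mean + min(sc) * comp),
       score_max = max(sc), score_min = min(sc))
}

#' Score-frequency association across datasets
#'
#' Quantifies whether a component's score varies with mode peak frequency
#' while allowing each dataset (participant) its own mean: scores are scaled
#' by their standard deviation, score and frequency are centred within
#' dataset, and the slope is estimated by least squares -- the within
#' (fixed-effects) approximation to a random-intercept model. A cluster
#' bootstrap over datasets gives the confidence interval.
#'
#' @param scores Numeric vector of component scores (one per mode).
#' @param frequencies Peak frequencies in Hz.
#' @param dataset_ids Dataset/participant identifier per mode.
#' @param n_boot Bootstrap replicates over datasets (default 500).
#' @param conf_level Interval coverage (default 0.95).
#' @param seed Optional integer seed.
#' @return List with `slope` (score-SD units per Hz), `conf_int`, `n_modes`,
#'   `n_datasets`.
#' @export
score_frequency_regression <- function(scores, frequencies, dataset_ids,
                                       n_boot = 500, conf_level = 0.95,
                                       seed = NULL) {
  if (length(scores) != length(frequencies) ||
      length(scores) != length(dataset_ids))
    stop("`scores`, `frequencies` and `dataset_ids` must have equal length")
  ids <- as.factor(dataset_ids)
  if (nlevels(ids) == 1 && stats::var(frequencies) == 0)
    stop("cannot estimate a slope from a single dataset with constant frequency")
  sc <- scores / stats::sd(scores)
  center_within <- function(v) v - stats::ave(v, ids)
  y <- center_within(sc)
  x <- center_within(frequencies)
  if (sum(x^2) == 0)
    stop("no within-dataset frequency variation; slope not identified")
  slope <- sum(x * y) / sum(x^2)
  if (!is.null(seed)) set.seed(seed)
  lv <- levels(ids)
  boots <- replicate(n_boot, {
    pick <- sample(lv, length(lv), replace = TRUE)
    rows <- unlist(lapply(pick, function(l) which(ids == l)))
    idb <- rep(seq_along(pick), times = vapply(pick, function(l)
      sum(ids == l), 1L))
    yb <- sc[rows] - stats::ave(sc[rows], idb)
    xb <- frequencies[rows] - stats::ave(frequencies[rows], idb)
    if (sum(xb^2) == 0) NA_real_ else sum(xb * yb) / sum(xb^2)
  })
  a <- (1 - conf_level) / 2
  ci <- stats::quantile(boots, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(slope = slope, conf_int = ci, n_modes = length(scores),
       n_datasets = nlevels(ids))
}
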