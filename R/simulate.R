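#' Specify one simulated oscillatory mode
#'
#' A mode is a resonance placed directly in the z-plane: a pole at frequency
#' `frequency_hz` with radius `magnitude`, projected into the network nodes by
#' `weights`. Frequency 0 (or Nyquist) places a single real pole; any other
#' frequency places a complex-conjugate pair so the generated signal is real.
#'
#' @param frequency_hz Pole frequency in Hz, in `[0, fs/2]` for the sampling
#'   rate used at generation time.
#' @param magnitude Pole radius, strictly inside the unit circle (0, 1).
#'   Radii close to 1 give sharp, weakly damped spectral peaks.
#' @param weights Numeric vector giving the relative strength of this mode in
#'   each node; its length fixes the node count.
#' @param amplitude_scale Positive scalar multiplying the unit-variance mode
#'   time course before projection (default 1).
#' @return An object of class `sse_mode_spec`.
#' @export
mode_spec <- function(frequency_hz, magnitude, weights, amplitude_scale = 1) {
  if (!is.numeric(frequency_hz) || length(frequency_hz) != 1L || frequency_hz < 0)
    stop("`frequency_hz` must be a single non-negative number")
  if (!is.numeric(magnitude) || length(magnitude) != 1L ||
      magnitude <= 0 || magnitude >= 1)
    stop("`magnitude` must lie strictly in (0, 1): a pole on or outside the ",
         "unit circle gives an unstable (non-stationary) mode")
  if (!is.numeric(weights) || length(weights) < 1L || !all(is.finite(weights)))
    stop("`weights` must be a finite numeric vector (one entry per node)")
  if (!is.numeric(amplitude_scale) || length(amplitude_scale) != 1L ||
      amplitude_scale <= 0)
    stop("`amplitude_scale` must be a positive scalar")
  structure(list(frequency_hz = frequency_hz, magnitude = magnitude,
                 weights = as.numeric(weights),
                 amplitude_scale = amplitude_scale),
            class = "sse_mode_spec")
}

#' Specify a network simulation
#'
#' Bundles the modes, duration, sampling rate, observation noise and
#' between-realisation jitter for [build_network_recording()] and
#' [group_simulation()].
#'
#' @param modes List of [mode_spec()] objects; all weight vectors must share
#'   one length (the node count).
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param observation_noise_sd Standard deviation of the white observation
#'   noise added to every node, relative to unit-variance mode time courses.
#' @param frequency_jitter_hz Half-width (Hz) of the uniform jitter applied to
#'   each oscillatory mode's frequency across group realisations.
#' @param amplitude_jitter Half-width of the uniform multiplicative amplitude
#'   jitter (e.g. 0.2 scales amplitudes by U(0.8, 1.2)) across realisations.
#' @return An object of class `sse_simulation_spec`.
#' @export
simulation_spec <- function(modes, duration_s, fs,
                            observation_noise_sd = 1,
                            frequency_jitter_hz = 0,
                            amplitude_jitter = 0) {
  if (inherits(modes, "sse_mode_spec")) modes <- list(modes)
  if (!length(modes) || !all(vapply(modes, inherits, TRUE, "sse_mode_spec")))
    stop("`modes` must be a list of mode_spec objects")
  m <- unique(vapply(modes, function(s) length(s$weights), 1L))
  if (length(m) != 1L)
    stop("all modes must have weight vectors of the same length (node count)")
  if (duration_s <= 0 || fs <= 0) stop("`duration_s` and `fs` must be positive")
  if (observation_noise_sd < 0) stop("`observation_noise_sd` must be >= 0")
  if (frequency_jitter_hz < 0 || amplitude_jitter < 0)
    stop("jitter parameters must be >= 0")
  for (s in modes) {
    if (s$frequency_hz > fs / 2)
      stop(sprintf("mode frequency %g Hz exceeds the Nyquist frequency %g Hz",
                   s$frequency_hz, fs / 2))
    if (s$frequency_hz > 0 &&
        (s$frequency_hz + frequency_jitter_hz >= fs / 2 ||
         s$frequency_hz - frequency_jitter_hz <= 0))
      stop("frequency jitter can push a mode outside (0, Nyquist); ",
           "reduce `frequency_jitter_hz`")
  }
  structure(list(modes = modes, n_nodes = m, duration_s = duration_s, fs = fs,
                 observation_noise_sd = observation_noise_sd,
                 frequency_jitter_hz = frequency_jitter_hz,
                 amplitude_jitter = amplitude_jitter),
            class = "sse_simulation_spec")
}

#' Default two-network alpha simulation
#'
#' The stock validation scenario: a 10-node network driven by two subnetworks
#' with different spatial and spectral profiles -- a non-oscillatory 1/f-type
#' mode (real pole at 0 Hz) loaded mainly on the first nodes, and an alpha
#' oscillation (conjugate pole pair, default 10 Hz) loaded mainly on the later
#' nodes, with one middle node carrying both. 300 s at 128 Hz with unit white
#' observation noise; across group realisations the alpha frequency jitters
#' uniformly by +/-2 Hz and its amplitude by +/-20 %.
#'
#' @param n_nodes Node count (default 10). Weight layouts for other counts are
#'   interpolated from the default pattern.
#' @param f_alpha Centre frequency of the oscillatory mode (default 10 Hz).
#' @param r_slow,r_alpha Pole radii of the 0 Hz and oscillatory modes.
#' @param duration_s,fs Duration (s) and sampling rate (Hz).
#' @param observation_noise_sd White observation noise sd (default 1).
#' @param frequency_jitter_hz,amplitude_jitter Group jitter settings.
#' @param weights_slow,weights_alpha Optional explicit weight vectors
#'   overriding the default layout.
#' @return An [simulation_spec()] object.
#' @export
alpha_network_spec <- function(n_nodes = 10, f_alpha = 10,
                               r_slow = 0.90, r_alpha = 0.95,
                               duration_s = 300, fs = 128,
                               observation_noise_sd = 1,
                               frequency_jitter_hz = 2,
                               amplitude_jitter = 0.2,
                               weights_slow = NULL, weights_alpha = NULL) {
  default_slow  <- c(1.0, 0.9, 0.8, 0.6, 0, 0, 0.5, 0, 0, 0)
  default_alpha <- c(0, 0, 0, 0.4, 0.6, 0.8, 0.8, 1.0, 0.9, 0.7)
  stretch <- function(w, m) {
    if (m == length(w)) return(w)
    stats::approx(seq_along(w), w, n = m)$y
  }
  if (is.null(weights_slow)) weights_slow <- stretch(default_slow, n_nodes)
  if (is.null(weights_alpha)) weights_alpha <- stretch(default_alpha, n_nodes)
  simulation_spec(
    modes = list(
      mode_spec(0, r_slow, weights_slow),
      mode_spec(f_alpha, r_alpha, weights_alpha)
    ),
    duration_s = duration_s, fs = fs,
    observation_noise_sd = observation_noise_sd,
    frequency_jitter_hz = frequency_jitter_hz,
    amplitude_jitter = amplitude_jitter
  )
}

#' Convert a placed pole to AR polynomial coefficients
#'
#' Places a pole of radius `magnitude` at `frequency_hz` in the z-plane and
#' expands back to the monic polynomial form used as a recursive filter.
#' Frequency 0 gives a single real pole at `+magnitude` (coefficients
#' `c(1, -magnitude)`); Nyquist gives a real pole at `-magnitude`; any other
#' frequency gives the conjugate pair, i.e. degree-2 coefficients
#' `c(1, -2 r cos(2 pi f / fs), r^2)`.
#'
#' @param frequency_hz Pole frequency in Hz, in `[0, fs/2]`.
#' @param magnitude Pole radius in (0, 1).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of monic polynomial coefficients `c(1, c1, ...)`
#'   such that the AR recursion is `x_t = -c1 x_{t-1} - ... + e_t`.
#' @export
#' @examples
#' poles_to_ar_coefficients(10, 0.95, 128)
poles_to_ar_coefficients <- function(frequency_hz, magnitude, fs) {
  if (frequency_hz < 0 || frequency_hz > fs / 2)
    stop(sprintf("frequency %g Hz is outside [0, Nyquist = %g Hz]",
                 frequency_hz, fs / 2))
  if (magnitude <= 0 || magnitude >= 1)
    stop("`magnitude` must lie strictly in (0, 1); a radius >= 1 is unstable")
  omega <- 2 * pi * frequency_hz / fs
  if (frequency_hz == 0) {
    c(1, -magnitude)
  } else if (frequency_hz == fs / 2) {
    c(1, magnitude)
  } else {
    c(1, -2 * magnitude * cos(omega), magnitude^2)
  }
}

ar_roots <- function(coefficients) {
  # roots in z^{-1}: stable iff all outside unit circle
  if (length(coefficients) == 1L) return(complex(0))
  polyroot(coefficients)
}

is_stable_ar <- function(coefficients) {
  r <- ar_roots(coefficients)
  !length(r) || all(Mod(r) > 1)
}

#' Generate one AR mode time course
#'
#' Filters unit-variance Gaussian white noise through the recursive (all-pole)
#' filter given by monic polynomial `coefficients`, discarding an initial
#' burn-in so the output is (approximately) stationary.
#'
#' @param coefficients Monic AR polynomial, e.g. from
#'   [poles_to_ar_coefficients()]; all roots must lie inside the unit circle.
#' @param n_samples Number of samples to return (after burn-in).
#' @param seed Optional integer seed for a reproducible draw.
#' @param burn_in Samples discarded from the start (default 500).
#' @return Numeric vector of length `n_samples`.
#' @export
generate_mode_timecourse <- function(coefficients, n_samples, seed = NULL,
                                     burn_in = 500) {
  if (!is_stable_ar(coefficients))
    stop("unstable AR coefficients: some pole lies on or outside the unit circle")
  if (n_samples <= 0) stop("`n_samples` must be positive")
  if (!is.null(seed)) set.seed(seed)
  e <- stats::rnorm(n_samples + burn_in)
  if (length(coefficients) == 1L) {
    x <- e
  } else {
    x <- as.numeric(stats::filter(e, filter = -coefficients[-1],
                                  method = "recursive"))
  }
  x[(burn_in + 1):(burn_in + n_samples)]
}

#' Build one simulated network recording
#'
#' Generates each mode's time course by filtering white noise through its
#' placed-pole polynomial, standardises it to unit variance, projects it into
#' the nodes via the mode's weight vector (times its amplitude scale), sums
#' the mode contributions and adds independent white observation noise.
#'
#' @param spec A [simulation_spec()].
#' @param seed Optional integer seed; fixes the recording bit-for-bit.
#' @return An [sse_recording()] of shape `n_nodes x round(duration_s * fs)`.
#' @export
build_network_recording <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sse_simulation_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- round(spec$duration_s * spec$fs)
  m <- spec$n_nodes
  data <- matrix(0, m, n)
  for (s in spec$modes) {
    coefs <- poles_to_ar_coefficients(s$frequency_hz, s$magnitude, spec$fs)
    tc <- generate_mode_timecourse(coefs, n)
    tc <- tc / stats::sd(tc) * s$amplitude_scale
    data <- data + s$weights %o% tc
  }
  if (spec$observation_noise_sd > 0)
    data <- data + matrix(stats::rnorm(m * n, sd = spec$observation_noise_sd),
                          m, n)
  sse_recording(data, fs = spec$fs)
}

#' Simulate a group of jittered realisations
#'
#' Draws `n_realisations` recordings from one network specification. The
#' spatial weights stay fixed across realisations while each oscillatory
#' mode's frequency is drawn uniformly in `f0 +/- frequency_jitter_hz` and its
#' amplitude is scaled by `U(1 - amplitude_jitter, 1 + amplitude_jitter)`,
#' emulating between-participant variability in peak frequency and power.
#'
#' @param spec A [simulation_spec()]; its jitter fields set the draw widths.
#' @param n_realisations Number of independent realisations (>= 1).
#' @param seed Master seed; per-realisation substreams are derived from it so
#'   members are independent yet jointly reproducible.
#' @return A list with one element per realisation, each a list with
#'   `recording` (an [sse_recording()]) and `modes` (the realised
#'   [mode_spec()]s, carrying the jittered frequency/amplitude for
#'   ground-truth scoring).
#' @export
group_simulation <- function(spec, n_realisations, seed = NULL) {
  stopifnot(inherits(spec, "sse_simulation_spec"))
  if (n_realisations < 1) stop("`n_realisations` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_realisations)
  lapply(seq_len(n_realisations), function(i) {
    set.seed(sub_seeds[i])
    modes_i <- lapply(spec$modes, function(s) {
      if (s$frequency_hz > 0 && spec$frequency_jitter_hz > 0) {
        f <- stats::runif(1, s$frequency_hz - spec$frequency_jitter_hz,
                          s$frequency_hz + spec$frequency_jitter_hz)
        if (f <= 0 || f >= spec$fs / 2)
          stop("jittered frequency fell outside (0, Nyquist)")
        s$frequency_hz <- f
      }
      if (spec$amplitude_jitter > 0)
        s$amplitude_scale <- s$amplitude_scale *
          stats::runif(1, 1 - spec$amplitude_jitter, 1 + spec$amplitude_jitter)
      s
    })
    spec_i <- spec
    spec_i$modes <- modes_i
    list(recording = build_network_recording(spec_i, seed = NULL),
         modes = modes_i)
  })
}

#' Ground-truth network matrices of a simulation
#'
#' For each mode, the planted network is the rank-1 outer product of its
#' weight vector with itself, scaled by the squared amplitude: the pattern of
#' node power (diagonal) and connection strength (off-diagonal) that an exact
#' estimator should recover.
#'
#' @param spec A [simulation_spec()], or a list of realised [mode_spec()]s as
#'   returned by [group_simulation()].
#' @return A list of symmetric rank-1 `m x m` matrices, one per mode.
#' @export
true_network <- function(spec) {
  modes <- if (inherits(spec, "sse_simulation_spec")) spec$modes else spec
  lapply(modes, function(s) s$amplitude_scale^2 * (s$weights %o% s$weights))
}
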