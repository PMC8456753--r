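# ssemodes

Spatio-spectral eigenmode (SSE) decomposition of multichannel oscillatory
time series in R.

Electrophysiological recordings (MEG/EEG source parcellations, LFP arrays,
any multichannel oscillatory system) mix several oscillations whose peak
frequencies and spatial topographies vary between recordings. The usual
workflow — band-pass or band-integrate into *a priori* frequency bands, then
map power or connectivity per band — clips spectral peaks that sit near band
edges and mixes overlapping resonances. `ssemodes` instead fits one
multivariate autoregressive (MVAR) model

$$x(t) = \sum_{k=1}^{p} A_k\,x(t-k) + \epsilon(t), \qquad
  \epsilon \sim \mathcal{N}(0, \Sigma)$$

and eigendecomposes its companion matrix. Each eigenvalue
$\lambda_j$ is a pole of the system carrying a peak frequency
$\rho_j = f_s|\arg\lambda_j|/2\pi$, a damping time
$\delta_j = -1/\log|\lambda_j|$, and a rank-1 residue matrix $R_j$ built
from the eigenvectors. The transfer function has an exact partial-fraction
(modal) form

$$H(f) \;=\; \Bigl(I - \sum_k A_k z^{-k}\Bigr)^{-1}
       \;=\; \sum_{j=1}^{mp} R_j\,\frac{z}{z-\lambda_j},
       \qquad z = e^{i2\pi f/f_s},$$

so any single resonance can be pulled out of the superposition. A
**spatio-spectral eigenmode** is the triple
$\{\rho_j,\ \delta_j,\ H_j(\rho_j)\}$; its network matrix
$H_j(\rho_j)\,\Sigma\,H_j^*(\rho_j)$ gives node power (diagonal) and
connection strength (off-diagonal) at the mode's own peak frequency — no
frequency bands or regions of interest need to be fixed in advance.

The package provides:

* `fit_mvar()` + `model_diagnostics()` — least-squares MVAR fitting with
  stability index, Durbin–Watson, variance explained and AIC;
* `transfer_function()`, `spectral_matrix()`, `band_average()` — classical
  Fourier-form spectra and band-integrated networks for comparison;
* `modal_decomposition()`, `extract_sses()`, `modal_transfer()` — the modal
  core;
* `null_distribution()` + `select_modes()` — max-statistic permutation
  testing on damping times (channel/epoch-shuffled surrogates) to separate
  dynamically important modes from the noise floor;
* `stack_mode_networks()`, `spatial_pca()`, `split_half_reliability()`,
  `score_frequency_regression()` — spatial PCA over SSE networks across
  recordings, with reliability and a score–frequency trend estimate;
* `alpha_network_spec()`, `build_network_recording()`, `group_simulation()`
  — a pole-placement simulator generating ground-truth oscillatory networks;
* `run_pipeline()` and a thin CLI (`inst/cli/sse.R`) tying the stages
  together, with TSV/JSON input–output (`read_recording()`,
  `write_recording()`).

## Worked example

Simulate the stock two-network scenario (10 nodes, 300 s at 128 Hz; a
1/f-type mode at 0 Hz and an alpha oscillation at 10 Hz, overlapping on node
7), fit an order-5 MVAR, and let the permutation scheme find the planted
resonances:

```r
library(ssemodes)

spec  <- alpha_network_spec()
rec   <- build_network_recording(spec, seed = 11)
model <- fit_mvar(rec, p = 5)
model
#> <sse_mvar> m = 10 channels, order p = 5, fs = 128 Hz
#>   stability index: 0.9271

sset <- extract_sses(modal_decomposition(model))
null <- null_distribution(rec, p = 5, n_perm = 200, seed = 3)
null
#> <sse_null> 200 permutations, 0.01 tail -> threshold 3.43 samples
sset <- select_modes(sset, null)
subset(sse_table(sset), selected)
#>   mode partner   rho_hz delta_samples   delta_s magnitude is_real_pole selected
#> 1    1       2 9.956464      13.20713 0.1031807 0.9270788        FALSE     TRUE
#> 2    3      NA 0.000000       8.90990 0.0696086 0.8938344         TRUE     TRUE
```

Out of the 50 modes of the order-5 fit, exactly two survive the 1%
max-statistic threshold: a real pole at 0 Hz (the 1/f-type network) and a
conjugate pair at 9.96 Hz — 0.04 Hz from the planted 10 Hz pole — with the
two longest damping times (13.2 and 8.9 samples against a 3.43-sample
threshold). Each selected mode's network matrix is in `sset$S_rho`; its
rank-1 structure reproduces the planted weight pattern, and

```r
individual_alpha_frequency(sset)
#> [1] 9.956464
```

gives the damping-time-weighted alpha peak frequency. Across a simulated
group, `group_simulation()` + `group_network_recovery()` quantify recovery:
modal network estimates correlate above 0.99 with the planted ground truth,
while classical 8–12 Hz band-integrated Fourier networks retain ~0.4
correlation with the residual noise structure (the modal estimate: ~0.2).

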