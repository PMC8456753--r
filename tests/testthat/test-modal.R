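test_that("companion matrix has the exact block layout", {
  m1 <- make_mvar(array(0.7, dim = c(1, 1, 1)))
  expect_equal(companion(m1), matrix(0.7))
  # univariate order 2: companion eigenvalues are the AR polynomial roots
  m2 <- make_mvar(array(c(0.5, 0.3), dim = c(1, 1, 2)))
  lam <- eigen(companion(m2))$values
  roots <- 1 / polyroot(c(1, -0.5, -0.3))
  expect_equal(sort(Re(lam)), sort(Re(roots)), tolerance = 1e-10)
  # m = 2, p = 3 block structure: top row holds A_k, identity sub-blocks
  model <- random_stable_model(2, 3, seed = 41)
  C <- companion(model)
  expect_equal(dim(C), c(6, 6))
  for (k in 1:3) expect_equal(C[1:2, (k - 1) * 2 + 1:2], model$A[, , k])
  expect_equal(C[3:6, 1:4], diag(4))
  expect_true(all(C[3:6, 5:6] == 0))
})

test_that("eigendecomposition reconstructs C with biorthogonal vectors", {
  model <- random_stable_model(4, 3, seed = 42)
  C <- companion(model)
  dec <- modal_decomposition(model)
  expect_length(dec$lambda, 12)
  expect_lt(dec$biorth_residual, 1e-8)
  # modes sorted by descending damping time
  expect_true(all(diff(dec$delta_samples) <= 1e-12))
  # conjugate partners carry conjugate eigenvalues
  for (j in which(!is.na(dec$conjugate_partner))) {
    k <- dec$conjugate_partner[j]
    expect_equal(dec$lambda[k], Conj(dec$lambda[j]), tolerance = 1e-10)
  }
  # V diag(lambda) W reconstructs the companion matrix
  mp <- length(dec$lambda)
  eg <- eigen(C)
  recon <- Re(eg$vectors %*% diag(eg$values) %*% solve(eg$vectors))
  expect_lt(max(abs(recon - C)), 1e-8 * max(abs(C)))
  # diagonal companion: eigenvalues are the diagonal entries
  dm <- make_mvar(array(diag(c(0.9, 0.5, 0.2)), dim = c(3, 3, 1)))
  dd <- modal_decomposition(dm)
  expect_equal(sort(Re(dd$lambda)), c(0.2, 0.5, 0.9), tolerance = 1e-12)
})

test_that("eigenvectors have the Vandermonde delay-embedding structure", {
  model <- random_stable_model(3, 4, seed = 43)
  C <- companion(model)
  eg <- eigen(C)
  m <- 3
  for (j in seq_along(eg$values)) {
    v <- eg$vectors[, j]; lam <- eg$values[j]
    for (b in 2:4) {
      block <- v[(b - 1) * m + 1:m]
      expect_equal(block * lam^(b - 1), v[1:m], tolerance = 1e-8)
    }
  }
})

test_that("peak frequency and damping time follow the pole geometry", {
  expect_equal(peak_frequency(0.9 + 0i, 128), 0)
  expect_equal(peak_frequency(-0.9 + 0i, 128), 64)
  expect_equal(peak_frequency(0.95 * exp(1i * 2 * pi * 10 / 128), 128), 10)
  expect_error(peak_frequency(0 + 0i, 128), "zero")
  expect_equal(damping_time(exp(-1) + 0i, 128)$samples, 1)
  expect_equal(damping_time(0.9 + 0i, 128)$samples, -1 / log(0.9))
  expect_equal(damping_time(0.9 + 0i, 128)$seconds, -1 / log(0.9) / 128)
  # monotone vanishing as |lambda| -> 0
  expect_lt(damping_time(1e-8 + 0i, 128)$samples,
            damping_time(1e-3 + 0i, 128)$samples)
  expect_error(damping_time(1.01 + 0i, 128), "unstable")
})

test_that("residue matrices are rank-1 and conjugate-symmetric in pairs", {
  # scalar AR(1): the single residue is exactly 1 (H = z / (z - a))
  m1 <- make_mvar(array(0.6, dim = c(1, 1, 1)))
  d1 <- modal_decomposition(m1)
  expect_equal(d1$residues[[1]], matrix(1 + 0i))
  model <- random_stable_model(5, 4, seed = 44)
  dec <- modal_decomposition(model)
  for (j in seq_along(dec$lambda)) {
    sv <- svd(dec$residues[[j]])$d
    expect_lt(sv[2], 1e-10 * sv[1])
    k <- dec$conjugate_partner[j]
    if (!is.na(k))
      expect_equal(dec$residues[[k]], Conj(dec$residues[[j]]),
                   tolerance = 1e-8)
  }
})

test_that("the modal transfer function sums to the Fourier form", {
  freqs <- frequency_grid(60, 64)
  model <- random_stable_model(4, 5, fs = 128, seed = 45)
  dec <- modal_decomposition(model)
  Hf <- transfer_function(model, freqs)
  Hm <- modal_transfer(dec, freqs)
  expect_lt(max(Mod(Hm$H - Hf$H)) / max(Mod(Hf$H)), 1e-6)
  # empty subset: zero transfer function
  H0 <- modal_transfer(dec, freqs, integer(0))
  expect_true(all(H0$H == 0))
  # a conjugate-pair subset corresponds to a real impulse response:
  # H evaluated at exp(-i w) equals the conjugate of H at exp(+i w)
  j <- which(!is.na(dec$conjugate_partner))[1]
  pair <- c(j, dec$conjugate_partner[j])
  w <- 2 * pi * 7.3 / model$fs
  eval_pair <- function(z) {
    out <- matrix(0i, 4, 4)
    for (q in pair)
      out <- out + dec$residues[[q]] * z / (z - dec$lambda[q])
    out
  }
  expect_equal(eval_pair(exp(-1i * w)), Conj(eval_pair(exp(1i * w))),
               tolerance = 1e-10)
})

test_that("a single oscillatory mode has a unimodal frequency response", {
  spec <- small_alpha_spec(duration_s = 120)
  rec <- build_network_recording(spec, seed = 46)
  dec <- modal_decomposition(fit_mvar(rec, 5))
  # strongest oscillatory mode (longest damping among complex poles)
  j <- which(!is.na(dec$conjugate_partner))[1]
  freqs <- seq(0.1, 31.9, length.out = 400)
  H <- modal_transfer(dec, freqs, j)
  mag <- apply(Mod(H$H), 1, sum)
  interior_max <- which(diff(sign(diff(mag))) == -2) + 1
  boundary_max <- c(if (mag[1] > mag[2]) 1, if (mag[400] > mag[399]) 400)
  expect_equal(length(interior_max) + length(boundary_max), 1L)
})

test_that("SSE extraction collapses conjugate pairs and counts add up", {
  model <- random_stable_model(6, 4, seed = 47)
  dec <- modal_decomposition(model)
  sset <- extract_sses(dec)
  n_real <- sum(is.na(dec$conjugate_partner))
  n_pairs <- sum(!is.na(dec$conjugate_partner)) / 2
  expect_equal(nrow(sse_table(sset)), n_real + n_pairs)
  expect_equal(length(dec$lambda), 6 * 4)
  expect_true(all(sse_table(sset)$rho_hz >= 0 &
                    sse_table(sset)$rho_hz <= model$fs / 2))
  # each SSE's spectral matrix is Hermitian PSD
  S1 <- sset$S_rho[[1]]
  expect_lt(max(Mod(S1 - Conj(t(S1)))), 1e-10)
  expect_true(all(Re(diag(S1)) >= -1e-12))
})

test_that("subset spectral matrices reduce to the Fourier spectrum", {
  model <- random_stable_model(3, 3, seed = 48)
  dec <- modal_decomposition(model)
  f0 <- 9.7
  S_all <- mode_spectral_matrix(dec, seq_along(dec$lambda),
                                at_frequency = f0)
  S_fourier <- spectral_matrix(
    transfer_function(model, f0)$H[1, , ], model$Sigma)
  expect_equal(S_all, S_fourier, tolerance = 1e-8)
})

test_that("IAF is the damping-weighted mean of in-band peak frequencies", {
  mats <- replicate(3, diag(2), simplify = FALSE)
  one <- make_fake_sse_set(10, 5, mats[1])
  expect_equal(individual_alpha_frequency(one), 10)
  sym <- make_fake_sse_set(c(8, 12), c(3, 3), mats[1:2])
  expect_equal(individual_alpha_frequency(sym), 10)
  wt <- make_fake_sse_set(c(8, 12, 40), c(1, 3, 99), mats)
  expect_equal(individual_alpha_frequency(wt), 11)
  # selection flags restrict the average once present
  sel <- make_fake_sse_set(c(8, 12), c(1, 3), mats[1:2],
                           selected = c(TRUE, FALSE))
  expect_equal(individual_alpha_frequency(sel), 8)
  expect_error(individual_alpha_frequency(
    make_fake_sse_set(30, 5, mats[1])), "no SSEs")
})
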