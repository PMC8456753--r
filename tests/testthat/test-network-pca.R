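random_networks <- function(n, m, pattern = NULL, noise_sd = 0.05,
                            scores = NULL) {
  # symmetric non-negative mode networks: optional planted rank-1 pattern
  lapply(seq_len(n), function(i) {
    base <- matrix(stats::rnorm(m * m, sd = noise_sd), m)
    base <- abs(base + t(base)) / 2
    if (!is.null(pattern)) base <- base + scores[i] * pattern
    base
  })
}

test_that("stacking vectorises in-band networks and removes column means", {
  m <- 4
  mats <- random_networks(6, m)
  set1 <- make_fake_sse_set(c(6.9, 7.0, 9, 11, 13.0, 13.1),
                            rep(5, 6), mats)
  stacked <- stack_mode_networks(set1, 7, 13)
  # closed band: 6.9 out, 7.0 and 13.0 in, 13.1 out
  expect_equal(nrow(stacked$X), 4)
  expect_equal(stacked$index$rho_hz, c(7, 9, 11, 13))
  expect_lt(max(abs(colMeans(stacked$X))), 1e-10)
  # a single in-band SSE demeans to an all-zero row
  single <- stack_mode_networks(
    make_fake_sse_set(10, 5, mats[1]), 7, 13)
  expect_true(all(single$X == 0))
  # selection flags restrict stacking when present
  selset <- make_fake_sse_set(c(9, 10, 11), rep(5, 3), mats[1:3],
                              selected = c(TRUE, FALSE, TRUE))
  expect_equal(nrow(stack_mode_networks(selset, 7, 13)$X), 2)
  expect_error(stack_mode_networks(set1, 40, 45), "no SSEs")
})

test_that("spatial PCA recovers a planted pattern and is self-consistent", {
  set.seed(61)
  m <- 6
  pattern <- abs(outer(stats::rnorm(m), stats::rnorm(m)))
  pattern <- (pattern + t(pattern)) / 2
  # positive loadings keep every network entry non-negative, so the
  # magnitude taken during stacking does not fold the planted variation
  scores <- stats::runif(60, 0.5, 2.5)
  mats <- random_networks(60, m, pattern, noise_sd = 0.02, scores = scores)
  sset <- make_fake_sse_set(stats::runif(60, 8, 12), rep(5, 60), mats)
  stacked <- stack_mode_networks(sset, 7, 13)
  pca <- spatial_pca(stacked)
  expect_gt(abs(stats::cor(pca$components[1, ], as.numeric(t(pattern)))),
            0.99)
  # score signs track the planted scores (up to global sign fixed by PC1)
  expect_gt(abs(stats::cor(pca$scores[, 1], scores)), 0.99)
  # variance percentages are non-increasing and sum to <= 100
  expect_true(all(diff(pca$variance_explained_pct) <= 1e-10))
  expect_lte(sum(pca$variance_explained_pct), 100 + 1e-8)
  # full reconstruction is exact
  recon <- pca_full <- spatial_pca(stacked, n_comp = Inf)
  Xhat <- pca_full$scores %*% pca_full$components
  expect_equal(Xhat, stacked$X, tolerance = 1e-8)
  # identical rows: no variance, no components
  same <- make_fake_sse_set(c(9, 10, 11), rep(5, 3),
                            replicate(3, pattern, simplify = FALSE))
  expect_warning(p0 <- spatial_pca(stack_mode_networks(same, 7, 13)),
                 "zero total variance")
  expect_equal(nrow(p0$components), 0)
})

test_that("split-half reliability separates structure from noise", {
  set.seed(62)
  m <- 5
  pattern <- abs(outer(stats::rnorm(m), stats::rnorm(m)))
  pattern <- (pattern + t(pattern)) / 2
  scores <- stats::runif(80, 0.5, 4.5)
  mats <- random_networks(80, m, pattern, noise_sd = 0.05, scores = scores)
  sset <- make_fake_sse_set(stats::runif(80, 8, 12), rep(5, 80), mats)
  rel <- split_half_reliability(sset, 7, 13, n_splits = 100, n_comp = 3,
                                seed = 1)
  expect_gt(rel[1], 0.9)
  expect_lt(rel[3], rel[1])
  # exactly rank-1 variation: every half recovers the same component
  pure <- lapply(seq(-2, 2, length.out = 8), function(s)
    pmax(pattern * (1 + s), 0))
  psset <- make_fake_sse_set(rep(10, 8), rep(5, 8), pure)
  rel1 <- split_half_reliability(psset, 7, 13, n_splits = 20, n_comp = 1,
                                 seed = 2)
  expect_gt(rel1[1], 0.999)
})

test_that("score-extreme projection is exactly linear in the score", {
  set.seed(63)
  m <- 4
  mats <- random_networks(20, m, noise_sd = 0.3)
  sset <- make_fake_sse_set(stats::runif(20, 8, 12), rep(5, 20), mats)
  stacked <- stack_mode_networks(sset, 7, 13)
  pca <- spatial_pca(stacked)
  ext <- project_score_extremes(pca, 1)
  diff_map <- ext$max - ext$min
  expected <- (ext$score_max - ext$score_min) *
    matrix(pca$components[1, ], m, m, byrow = TRUE)
  expect_equal(diff_map, expected, tolerance = 1e-10)
  # zero score projects to the grand-mean network
  zero_map <- matrix(pca$grand_mean, m, m, byrow = TRUE)
  mid <- ext$max - ext$score_max *
    matrix(pca$components[1, ], m, m, byrow = TRUE)
  expect_equal(mid, zero_map, tolerance = 1e-10)
})

test_that("score-frequency regression recovers planted slopes", {
  simulate_scores <- function(slope, n_per = 50, n_data = 20, seed = 64) {
    set.seed(seed)
    ids <- rep(seq_len(n_data), each = n_per)
    intercepts <- stats::rnorm(n_data, sd = 2)[ids]
    f <- stats::runif(n_per * n_data, 7, 13)
    score <- intercepts + slope * f + stats::rnorm(n_per * n_data, sd = 0.8)
    list(score = score, f = f, ids = ids)
  }
  # null: slope near zero, interval covers zero
  d0 <- simulate_scores(0)
  r0 <- score_frequency_regression(d0$score, d0$f, d0$ids, n_boot = 200,
                                   seed = 1)
  expect_lt(abs(r0$slope), 0.1)
  expect_true(r0$conf_int[1] <= 0 && r0$conf_int[2] >= 0)
  # planted association recovered in score-SD units per Hz
  d1 <- simulate_scores(1.2)
  sd_sc <- stats::sd(d1$score)
  r1 <- score_frequency_regression(d1$score, d1$f, d1$ids, n_boot = 200,
                                   seed = 2)
  expect_lt(abs(r1$slope - 1.2 / sd_sc), 0.1)
  # permuting frequencies destroys the association
  set.seed(3)
  rp <- score_frequency_regression(d1$score, sample(d1$f), d1$ids,
                                   n_boot = 100, seed = 3)
  expect_lt(abs(rp$slope), abs(r1$slope) / 5)
  # agrees with an independent random-intercept fit
  if (requireNamespace("lme4", quietly = TRUE)) {
    df <- data.frame(score = d1$score / sd_sc, f = d1$f,
                     id = factor(d1$ids))
    fit <- lme4::lmer(score ~ f + (1 | id), data = df)
    expect_lt(abs(r1$slope - lme4::fixef(fit)[["f"]]), 0.02)
  }
  expect_error(score_frequency_regression(1:5, rep(3, 5), rep(1, 5)),
               "constant frequency|not identified")
})
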