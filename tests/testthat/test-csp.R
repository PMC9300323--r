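test_that("trace-normalized covariance matches hand-computed cases", {
  expect_equal(normalized_covariance(diag(2)), diag(0.5, 2),
               ignore_attr = TRUE)
  R <- normalized_covariance(rbind(c(1, 2), c(0, 1)))
  expect_equal(R, rbind(c(5/6, 1/3), c(1/3, 1/6)), tolerance = 1e-14)
  expect_equal(normalized_covariance(t(c(3, -1, 2))), matrix(1),
               ignore_attr = TRUE)
  expect_error(normalized_covariance(matrix(0, 2, 8)), "zero-energy")
  expect_error(normalized_covariance(matrix(NA_real_, 2, 8)), "non-finite")
  expect_error(normalized_covariance(matrix(1, 8, 2)), "channels")
})

test_that("average covariance is the elementwise mean with unit trace", {
  t1 <- diag_cov_trial(0.8)
  t2 <- diag_cov_trial(0.6)
  expect_equal(average_covariance(list(t1)), normalized_covariance(t1))
  expect_equal(average_covariance(list(t1, t2)), diag(c(0.7, 0.3)),
               tolerance = 1e-14)
  set.seed(1)
  trials <- replicate(50, matrix(rnorm(4 * 32), 4, 32), simplify = FALSE)
  expect_equal(sum(diag(average_covariance(trials))), 1, tolerance = 1e-12)
  expect_error(average_covariance(list()), "no trials")
})

test_that("the diagonal two-channel case is solved analytically", {
  tr <- array(0, dim = c(2, 2, 4))
  tr[1, , ] <- diag_cov_trial(0.8)     # class 1: variances (0.8, 0.2)
  tr[2, , ] <- diag_cov_trial(0.2)     # class 2: variances (0.2, 0.8)
  ds <- mi_dataset(tr, c(1L, 2L), 100)
  m <- csp_fit(ds, n_pairs = 1L)
  expect_equal(m$eigvals, c(0.8, 0.2), tolerance = 1e-10)
})

test_that("every fit satisfies the whitening identity and eigenvalue complementarity", {
  set.seed(7)
  for (i in 1:10) {
    nch <- sample(3:8, 1)
    ds <- random_dataset(nch, 64L, n_per_class = 6L, seed = i)
    m <- csp_fit(ds, n_pairs = 1L)
    expect_equal(m$W %*% (m$R1_bar + m$R2_bar) %*% t(m$W), diag(nch),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # class-2 whitened eigenvalues complement class 1's
    D2 <- m$W %*% m$R2_bar %*% t(m$W)
    expect_equal(m$eigvals + diag(D2), rep(1, nch), tolerance = 1e-8)
    # both projected class covariances diagonal
    D1 <- m$W %*% m$R1_bar %*% t(m$W)
    expect_lt(max(abs(D1 - diag(diag(D1)))), 1e-8)
    expect_lt(max(abs(D2 - diag(diag(D2)))), 1e-8)
    expect_true(all(diff(m$eigvals) <= 1e-12))
  }
})

test_that("whitening-path filters match an independent generalized-eigenproblem solve", {
  set.seed(101)
  for (i in 1:25) {
    nch <- sample(3:8, 1)
    ds <- random_dataset(nch, 72L, n_per_class = 5L, seed = 1000 + i)
    m <- csp_fit(ds)
    oracle <- generalized_csp_oracle(m$R1_bar, m$R2_bar)
    expect_equal(m$eigvals, oracle$values, tolerance = 1e-8)
    for (k in seq_len(nch))
      expect_gt(abs_cosine(m$W[k, ], oracle$vectors[, k]), 1 - 1e-8)
  }
})

test_that("swapping class labels reverses the eigenvalue spectrum", {
  ds <- random_dataset(5L, 64L, n_per_class = 6L, seed = 33)
  swapped <- mi_dataset(ds$trials, 3L - ds$labels, ds$sampling_rate)
  m1 <- csp_fit(ds)
  m2 <- csp_fit(swapped)
  expect_equal(m2$eigvals, rev(1 - m1$eigvals), tolerance = 1e-8)
})

test_that("channel permutation permutes filters and leaves eigenvalues unchanged", {
  ds <- random_dataset(5L, 64L, n_per_class = 6L, seed = 44)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  dsp <- mi_dataset(ds$trials[, perm, , drop = FALSE], ds$labels,
                    ds$sampling_rate)
  m <- csp_fit(ds)
  mp <- csp_fit(dsp)
  expect_equal(mp$eigvals, m$eigvals, tolerance = 1e-8)
  for (k in 1:5)
    expect_gt(abs_cosine(mp$W[k, ], m$W[k, perm]), 1 - 1e-8)
})

test_that("normalized-variance features follow the variance-share formula", {
  model <- structure(list(W = diag(2), n_pairs = 1L), class = "csp_model")
  set.seed(5)
  trial <- rbind(rnorm(400, sd = sqrt(3)), rnorm(400, sd = 1))
  trial <- trial / sqrt(apply(trial, 1, var) / c(3, 1))  # exact variances 3, 1
  f <- csp_features(model, trial)
  expect_equal(f, c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(csp_features(model, 5 * trial), f, tolerance = 1e-12)

  ds <- random_dataset(6L, 64L, n_per_class = 3L, seed = 8)
  m <- csp_fit(ds, n_pairs = 2L)
  for (i in seq_len(n_trials(ds))) {
    fi <- csp_features(m, get_trial(ds, i))
    expect_length(fi, 4L)
    expect_true(all(fi >= 0))
    expect_equal(sum(fi), 1, tolerance = 1e-12)
  }
  expect_error(csp_features(m, matrix(0, 3, 10)), "channel count")
})

test_that("rank-deficient composite covariance demands shrinkage", {
  tr <- array(0, dim = c(4, 3, 16))
  base <- rbind(sin(seq_len(16)), cos(seq_len(16)))
  for (i in 1:4) tr[i, , ] <- rbind(base, base[1, ] + base[2, ])  # rank 2
  ds <- mi_dataset(tr, c(1L, 1L, 2L, 2L), 32)
  expect_error(csp_fit(ds), "shrinkage")
  m <- csp_fit(ds, shrinkage = 0.1, n_pairs = 1L)
  expect_true(all(is.finite(m$W)))
})

test_that("CSP patterns recover the true mixing columns on planted data", {
  gen <- generate_mi_dataset(
    synth_config(n_trials_per_class = 40L, erd_depth = 0.8,
                 noise_sd = 0.01, seed = 12L))
  filt <- bandpass_filter(gen$dataset, 8, 13)
  m <- csp_fit(filt, n_pairs = 1L)
  pat <- csp_patterns(m)
  A <- gen$forward_model$mixing
  # top filter: largest class-1 variance = the source attenuated in class 2's
  # trials stays strong ... compare both extreme patterns to the mu columns
  cos_top <- max(abs_cosine(pat[, 1], A[, 1]), abs_cosine(pat[, 1], A[, 2]))
  cos_bot <- max(abs_cosine(pat[, 8], A[, 1]), abs_cosine(pat[, 8], A[, 2]))
  expect_gt(cos_top, 0.95)
  expect_gt(cos_bot, 0.95)
})

test_that("CSP models round-trip through the JSON + CSV bundle", {
  ds <- random_dataset(4L, 64L, n_per_class = 4L, seed = 3)
  m <- csp_fit(ds, n_pairs = 2L)
  prefix <- file.path(withr::local_tempdir(), "csp")
  write_csp_model(m, prefix)
  m2 <- read_csp_model(prefix)
  expect_equal(unname(m2$W), unname(m$W), tolerance = 1e-12)
  expect_equal(m2$eigvals, m$eigvals, tolerance = 1e-12)
  expect_equal(m2$n_pairs, m$n_pairs)
  tr <- get_trial(ds, 1)
  expect_equal(csp_features(m2, tr), csp_features(m, tr), tolerance = 1e-10)
})
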