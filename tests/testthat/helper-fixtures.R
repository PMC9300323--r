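# Shared fixtures and independent oracles for the test suite.

abs_cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# Random small dataset with unstructured Gaussian trials (no planted effect).
random_dataset <- function(n_channels = 4L, n_samples = 64L,
                           n_per_class = 5L, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  mi_dataset(array(rnorm(n * n_channels * n_samples),
                   dim = c(n, n_channels, n_samples)),
             rep(1:2, each = n_per_class), 128)
}

# Build a 2-channel, 4-sample trial whose normalized covariance is exactly
# diag(a, 1 - a): orthogonal unit rows scaled by the target variances.
diag_cov_trial <- function(a) {
  u <- c(1, 1, 0, 0) / sqrt(2)
  v <- c(1, -1, 0, 0) / sqrt(2)
  rbind(sqrt(a) * u, sqrt(1 - a) * v)
}

# Independent oracle for the CSP eigenstructure: the generalized eigenproblem
# R1 v = mu (R1 + R2) v, solved through a generic non-symmetric eigensolver
# (a different numerical path than the whitening implementation).
generalized_csp_oracle <- function(R1, R2) {
  M <- solve(R1 + R2, R1)
  e <- eigen(M)
  ord <- order(Re(e$values), decreasing = TRUE)
  list(values = Re(e$values)[ord],
       vectors = Re(e$vectors)[, ord, drop = FALSE])
}

# Brute-force repeated-measures ANOVA: explicit residual computation from
# grand/row/column means, no reuse of the package's formulas.
brute_rm_anova <- function(x) {
  g <- mean(x)
  fit_cells <- outer(rowMeans(x) - g, colMeans(x) - g, `+`) + g
  list(ss_condition = sum((matrix(colMeans(x), nrow(x), ncol(x),
                                  byrow = TRUE) - g)^2),
       ss_subject = sum((matrix(rowMeans(x), nrow(x), ncol(x)) - g)^2),
       ss_error = sum((x - fit_cells)^2),
       F = (sum((matrix(colMeans(x), nrow(x), ncol(x), byrow = TRUE) - g)^2) /
              (ncol(x) - 1)) /
           (sum((x - fit_cells)^2) / ((ncol(x) - 1) * (nrow(x) - 1))))
}

# The 4-point linearly separable LDA fixture.
lda_fixture <- function() {
  list(X = rbind(c(0, 0), c(1, 1), c(2, 1), c(3, 0)),
       y = c(0, 0, 1, 1))
}
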