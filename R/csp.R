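#' Trace-normalized covariance of one trial
#'
#' \code{R = X Xᵀ / tr(X Xᵀ)}: the spatial covariance of a channel x sample
#' trial normalized to unit trace, so every trial contributes equally to the
#' class averages regardless of its overall amplitude.
#'
#' @param trial A channel x sample numeric matrix with at most as many
#'   channels as samples and nonzero energy.
#' @return Symmetric positive semi-definite channel x channel matrix with
#'   trace exactly 1.
#' @export
normalized_covariance <- function(trial) {
  trial <- as.matrix(trial)
  if (!all(is.finite(trial))) stop("trial contains non-finite values")
  if (nrow(trial) > ncol(trial))
    stop("covariance estimation requires no more channels than samples")
  cp <- tcrossprod(trial)
  tr <- sum(diag(cp))
  if (tr <= 0) stop("zero-energy trial: trace of X X^T is 0")
  cp / tr
}

#' Average normalized covariance over trials
#'
#' Arithmetic mean of the per-trial trace-normalized covariances; the mean of
#' unit-trace matrices again has unit trace.
#'
#' @param trials A list of channel x sample matrices.
#' @return Channel x channel matrix with trace 1.
#' @export
average_covariance <- function(trials) {
  if (length(trials) == 0L) stop("no trials supplied")
  covs <- lapply(trials, normalized_covariance)
  nch <- vapply(covs, nrow, integer(1))
  if (length(unique(nch)) != 1L) stop("inconsistent channel counts")
  Reduce(`+`, covs) / length(covs)
}

#' Fit a two-class Common Spatial Patterns model
#'
#' The classical whitening path: per-class average trace-normalized
#' covariances R1, R2; composite R = R1 + R2 eigendecomposed as U diag(l) Uᵀ
#' with eigenvalues descending; whitening P = diag(l)^(-1/2) Uᵀ; the whitened
#' class-1 covariance P R1 Pᵀ eigendecomposed as B D Bᵀ; projection
#' W = Bᵀ P with rows ordered by descending D. Rows of W are spatial
#' filters; columns of W⁻¹ are the corresponding spatial patterns. Because
#' P R1 Pᵀ + P R2 Pᵀ = I, each component's class-1 and class-2 eigenvalues
#' sum to 1: the first filters maximize class-1 variance while minimizing
#' class-2 variance, and the last do the reverse.
#'
#' @param dataset An \code{\link{mi_dataset}} with both classes present.
#' @param n_pairs Number of top/bottom filter pairs retained for features;
#'   default \code{min(3, floor(channels / 2))}.
#' @param shrinkage Fraction g in [0, 1]: each class covariance is shrunk as
#'   \code{(1 - g) R + g * I * tr(R) / N} before composition. Default 0;
#'   needed only for rank-deficient inputs.
#'
#' @return An object of class \code{csp_model}: \code{W} (components x
#'   channels), \code{P} (whitening), \code{eigvals} (class-1 whitened
#'   eigenvalues, descending, in [0, 1]), \code{R1_bar}, \code{R2_bar},
#'   \code{n_pairs}.
#' @export
csp_fit <- function(dataset, n_pairs = NULL, shrinkage = 0) {
  assert_two_classes(dataset)
  d <- dim(dataset$trials)
  if (d[2L] >= d[3L]) stop("need fewer channels than samples per trial")
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must lie in [0, 1]")
  if (is.null(n_pairs)) n_pairs <- min(3L, d[2L] %/% 2L)
  n_pairs <- as.integer(n_pairs)
  if (2L * n_pairs > d[2L]) stop("2 * n_pairs cannot exceed the channel count")

  trl <- function(cls) lapply(which(dataset$labels == cls),
                              function(i) get_trial(dataset, i))
  shrink <- function(R) {
    if (shrinkage == 0) return(R)
    (1 - shrinkage) * R + shrinkage * diag(sum(diag(R)) / nrow(R), nrow(R))
  }
  R1 <- shrink(average_covariance(trl(1L)))
  R2 <- shrink(average_covariance(trl(2L)))
  R <- R1 + R2

  e <- eigen(R, symmetric = TRUE)         # eigenvalues already descending
  if (min(e$values) < max(e$values) * 1e-10)
    stop("composite covariance is rank-deficient; refit with shrinkage > 0")
  P <- diag(1 / sqrt(e$values)) %*% t(e$vectors)

  S1 <- P %*% R1 %*% t(P)
  S1 <- (S1 + t(S1)) / 2
  eb <- eigen(S1, symmetric = TRUE)       # descending class-1 eigenvalues
  W <- t(eb$vectors) %*% P
  # sign convention: largest-magnitude entry of each filter positive
  for (i in seq_len(nrow(W))) {
    j <- which.max(abs(W[i, ]))
    if (W[i, j] < 0) W[i, ] <- -W[i, ]
  }

  structure(list(W = W, P = P, eigvals = eb$values,
                 R1_bar = R1, R2_bar = R2, n_pairs = n_pairs,
                 channel_names = dataset$channel_names),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat("<csp_model> ", nrow(x$W), " filters, n_pairs = ", x$n_pairs,
      "\n  class-1 eigenvalues: ",
      paste(signif(x$eigvals, 3), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Normalized-variance CSP features for one trial
#'
#' Projects a trial through the retained filters (first and last
#' \code{n_pairs} rows of W) and returns each component's share of the total
#' projected variance: \code{f_i = var(Z_i) / sum_j var(Z_j)}. Features are
#' nonnegative and sum to 1; they are invariant to any positive rescaling of
#' the trial. A log-variance variant (\code{log(f)}) is available.
#'
#' @param model A \code{csp_model}.
#' @param trial Channel x sample matrix matching the model's channel count.
#' @param log_variance If TRUE, return \code{log(f)} instead of \code{f}.
#' @return Numeric feature vector of length \code{2 * n_pairs}.
#' @export
csp_features <- function(model, trial, log_variance = FALSE) {
  trial <- as.matrix(trial)
  if (nrow(trial) != ncol(model$W))
    stop("trial channel count does not match the model")
  m <- model$n_pairs
  nr <- nrow(model$W)
  sel <- c(seq_len(m), seq(nr - m + 1L, nr))
  Z <- model$W[sel, , drop = FALSE] %*% trial
  v <- apply(Z, 1L, stats::var)
  tot <- sum(v)
  if (tot <= 0) stop("zero total variance in projected trial")
  f <- v / tot
  if (log_variance) log(f) else f
}

#' Feature matrix for every trial in a dataset
#' @param model A \code{csp_model}.
#' @param dataset An \code{\link{mi_dataset}}.
#' @param log_variance Passed to \code{\link{csp_features}}.
#' @return trials x (2 n_pairs) numeric matrix.
#' @export
csp_transform <- function(model, dataset, log_variance = FALSE) {
  t(vapply(seq_len(n_trials(dataset)),
           function(i) csp_features(model, get_trial(dataset, i), log_variance),
           numeric(2L * model$n_pairs)))
}

#' Spatial patterns of a CSP model
#'
#' Patterns (interpretable scalp topographies) are the columns of W⁻¹,
#' the forward images of the unit-variance CSP components.
#'
#' @param model A \code{csp_model}.
#' @return channels x components matrix; column i corresponds to filter i.
#' @export
csp_patterns <- function(model) solve(model$W)

#' Serialize a CSP model to a JSON + CSV bundle
#'
#' Writes \code{<prefix>.json} (eigenvalues, n_pairs, channel names) and
#' matrix CSVs \code{<prefix>_W.csv}, \code{<prefix>_P.csv} so a fit is
#' inspectable and reloadable without binary formats.
#'
#' @param model A \code{csp_model}.
#' @param prefix Output path prefix.
#' @return Invisibly, the JSON path.
#' @export
write_csp_model <- function(model, prefix) {
  utils::write.csv(model$W, paste0(prefix, "_W.csv"), row.names = FALSE)
  utils::write.csv(model$P, paste0(prefix, "_P.csv"), row.names = FALSE)
  utils::write.csv(model$R1_bar, paste0(prefix, "_R1.csv"), row.names = FALSE)
  utils::write.csv(model$R2_bar, paste0(prefix, "_R2.csv"), row.names = FALSE)
  meta <- list(eigvals = model$eigvals, n_pairs = model$n_pairs,
               channel_names = model$channel_names)
  path <- paste0(prefix, ".json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a CSP model written by \code{\link{write_csp_model}}
#' @param prefix Path prefix used when writing.
#' @return A \code{csp_model}.
#' @export
read_csp_model <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(list(
    W = as.matrix(utils::read.csv(paste0(prefix, "_W.csv"))),
    P = as.matrix(utils::read.csv(paste0(prefix, "_P.csv"))),
    eigvals = meta$eigvals,
    R1_bar = as.matrix(utils::read.csv(paste0(prefix, "_R1.csv"))),
    R2_bar = as.matrix(utils::read.csv(paste0(prefix, "_R2.csv"))),
    n_pairs = as.integer(meta$n_pairs),
    channel_names = meta$channel_names), class = "csp_model")
}
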