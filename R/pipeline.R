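#' Pipeline configuration
#'
#' Settings for the end-to-end decoding evaluation: band choice, CSP /
#' LDA knobs, and the cross-validation layout.
#'
#' @param band Either a length-2 numeric (Hz band edges) or "auto" to select
#'   the band per training fold from the r-squared spectrum.
#' @param n_pairs CSP filter pairs retained (NULL = model default).
#' @param cv_folds Stratified folds (>= 2).
#' @param cv_repeats Independent repetitions of the CV split.
#' @param seed Integer seed controlling fold assignment.
#' @param log_variance Use log-variance CSP features.
#' @param ridge LDA ridge (NULL = numerical-safety default).
#' @param shrinkage CSP covariance shrinkage in [0, 1].
#' @param band_search Length-2 Hz range searched when \code{band = "auto"}.
#' @param band_widths Length-2 Hz (min, max) window widths for auto selection.
#'
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(band = "auto", n_pairs = NULL, cv_folds = 5L,
                            cv_repeats = 5L, seed = 1L, log_variance = FALSE,
                            ridge = NULL, shrinkage = 0,
                            band_search = c(4, 40), band_widths = c(4, 12)) {
  if (!(identical(band, "auto") || (is.numeric(band) && length(band) == 2L)))
    stop("band must be 'auto' or a length-2 numeric (Hz)")
  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  structure(list(band = band, n_pairs = n_pairs, cv_folds = cv_folds,
                 cv_repeats = as.integer(cv_repeats), seed = as.integer(seed),
                 log_variance = isTRUE(log_variance), ridge = ridge,
                 shrinkage = shrinkage, band_search = band_search,
                 band_widths = band_widths),
            class = "pipeline_config")
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin to folds, so fold sizes per class differ by at most one.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# One train/test pass: band selection (train only), filtering, CSP fit
# (train only), LDA fit (train only), prediction on the held-out trials.
fit_and_score <- function(train, test, config) {
  if (identical(config$band, "auto")) {
    spec <- compute_r2_spectrum(train)
    bs <- select_band(spec, min_width = config$band_widths[1L],
                      max_width = config$band_widths[2L],
                      search_range = config$band_search)
    band <- c(bs$low, bs$high)
  } else band <- config$band
  nyq <- train$sampling_rate / 2
  band <- c(max(band[1L], 0.5), min(band[2L], nyq - 0.5))

  train_f <- bandpass_filter(train, band[1L], band[2L])
  test_f <- bandpass_filter(test, band[1L], band[2L])
  model <- csp_fit(train_f, n_pairs = config$n_pairs,
                   shrinkage = config$shrinkage)
  feats_tr <- csp_transform(model, train_f, config$log_variance)
  feats_te <- csp_transform(model, test_f, config$log_variance)
  lda <- lda_fit(feats_tr, train_f$labels, ridge = config$ridge)
  pred <- lda_predict(lda, feats_te)
  list(pred = as.integer(pred), truth = test$labels, band = band)
}

#' Cross-validated evaluation of the full decoding pipeline
#'
#' Runs stratified k-fold cross-validation, repeated \code{cv_repeats}
#' times. Every data-dependent fitting step — r-squared band selection (when
#' \code{band = "auto"}), the CSP spatial filters, and the LDA weights — is
#' estimated on the training trials of each fold only, so reported accuracy
#' is leakage-free. Deterministic given the config seed.
#'
#' @param dataset An \code{\link{mi_dataset}} with both classes present.
#' @param config A \code{\link{pipeline_config}}.
#'
#' @return An object of class \code{evaluation_result}: \code{accuracy_mean}
#'   (percent), \code{accuracy_per_fold} (percent, one per fold x repeat),
#'   \code{confusion} (2 x 2 counts, rows = truth), \code{band_used} (Hz
#'   range per fold), \code{config_echo}.
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  assert_two_classes(dataset)
  n_per_class <- min(table(dataset$labels))
  if (n_per_class < config$cv_folds)
    stop("cv_folds exceeds the trials available in the smaller class")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  acc <- numeric(0)
  bands <- list()
  confusion <- matrix(0L, 2L, 2L,
                      dimnames = list(truth = c("1", "2"), pred = c("1", "2")))
  for (rep_i in seq_len(config$cv_repeats)) {
    fold <- stratified_folds(dataset$labels, config$cv_folds)
    for (k in seq_len(config$cv_folds)) {
      train <- subset_trials(dataset, which(fold != k))
      test <- subset_trials(dataset, which(fold == k))
      res <- fit_and_score(train, test, config)
      acc <- c(acc, 100 * mean(res$pred == res$truth))
      bands[[length(bands) + 1L]] <- res$band
      for (i in seq_along(res$truth))
        confusion[res$truth[i], res$pred[i]] <-
          confusion[res$truth[i], res$pred[i]] + 1L
    }
  }
  structure(list(accuracy_mean = mean(acc),
                 accuracy_per_fold = acc,
                 confusion = confusion,
                 band_used = do.call(rbind, bands),
                 config_echo = config),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result> mean accuracy ",
      sprintf("%.2f%%", x$accuracy_mean), " over ",
      length(x$accuracy_per_fold), " folds (",
      x$config_echo$cv_folds, "-fold x ", x$config_echo$cv_repeats,
      " repeats)\n", sep = "")
  cat("  band(s) used: ", paste(unique(apply(x$band_used, 1L, function(b)
    sprintf("%g-%g Hz", b[1L], b[2L]))), collapse = ", "), "\n", sep = "")
  cat("  confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation result to JSON
#' @param result An \code{evaluation_result}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_evaluation <- function(result, path) {
  cfg <- result$config_echo
  jsonlite::write_json(
    list(schema = "midecode/evaluation/v1",
         accuracy_mean = result$accuracy_mean,
         accuracy_per_fold = result$accuracy_per_fold,
         confusion = result$confusion,
         band_used = result$band_used,
         config = list(band = cfg$band, cv_folds = cfg$cv_folds,
                       cv_repeats = cfg$cv_repeats, seed = cfg$seed,
                       log_variance = cfg$log_variance,
                       shrinkage = cfg$shrinkage)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys match \code{\link{pipeline_config}}
#'   arguments (unknown keys rejected).
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(y$band) && !identical(y$band, "auto"))
    y$band <- as.numeric(y$band)
  do.call(pipeline_config, y)
}

#' Load a synthetic-generator configuration from YAML
#' @param path YAML file whose keys match \code{\link{synth_config}} arguments.
#' @return A \code{synth_config}.
#' @export
read_synth_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(synth_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(synth_config, y)
}
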