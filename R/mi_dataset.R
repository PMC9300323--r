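#' Epoched two-class motor-imagery EEG dataset
#'
#' The container every pipeline stage consumes: a trial x channel x sample
#' array of epoched EEG with one binary class label per trial (1 = left-hand
#' imagery, 2 = right-hand imagery), the sampling rate, and channel names.
#'
#' @param trials Numeric array of dimension trial x channel x sample (values
#'   in microvolt-scale arbitrary units). All trials share the same channel
#'   and sample counts by construction.
#' @param labels Integer vector of per-trial class labels in \{1, 2\}, one per
#'   trial.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_names Character vector of channel names; defaults to
#'   "C1".."Cn".
#' @param provenance Free-text description of where the data came from
#'   (synthetic configuration or source file).
#'
#' @return An object of class \code{mi_dataset}.
#' @export
mi_dataset <- function(trials, labels, sampling_rate,
                       channel_names = NULL, provenance = "") {
  if (length(dim(trials)) != 3L)
    stop("'trials' must be a 3-d array (trial x channel x sample)")
  if (!all(is.finite(trials)))
    stop("'trials' contains non-finite values")
  n_trials <- dim(trials)[1L]
  n_channels <- dim(trials)[2L]
  labels <- as.integer(labels)
  if (length(labels) != n_trials)
    stop("length(labels) [", length(labels), "] != number of trials [",
         n_trials, "]")
  if (!all(labels %in% c(1L, 2L)))
    stop("labels must be 1 or 2")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("'sampling_rate' must be a positive scalar (Hz)")
  if (is.null(channel_names))
    channel_names <- paste0("C", seq_len(n_channels))
  if (length(channel_names) != n_channels)
    stop("channel_names length must match channel count")
  structure(
    list(trials = trials, labels = labels,
         sampling_rate = as.numeric(sampling_rate),
         channel_names = as.character(channel_names),
         provenance = as.character(provenance)[1L]),
    class = "mi_dataset")
}

#' @export
print.mi_dataset <- function(x, ...) {
  d <- dim(x$trials)
  cat("<mi_dataset> ", d[1L], " trials x ", d[2L], " channels x ", d[3L],
      " samples @ ", x$sampling_rate, " Hz\n", sep = "")
  cat("  labels: ", sum(x$labels == 1L), " class-1, ",
      sum(x$labels == 2L), " class-2\n", sep = "")
  if (nzchar(x$provenance))
    cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
dim.mi_dataset <- function(x) dim(x$trials)

#' Number of trials in a dataset
#' @param dataset An \code{mi_dataset}.
#' @return Integer trial count.
#' @export
n_trials <- function(dataset) dim(dataset$trials)[1L]

# Extract trial i as a channel x sample matrix.
#' Extract one trial
#' @param dataset An \code{mi_dataset}.
#' @param i Trial index.
#' @return A channel x sample numeric matrix.
#' @export
get_trial <- function(dataset, i) {
  m <- dataset$trials[i, , , drop = FALSE]
  dim(m) <- dim(dataset$trials)[2:3]
  m
}

#' Subset a dataset by trial indices
#' @param dataset An \code{mi_dataset}.
#' @param idx Integer vector of trial indices.
#' @return An \code{mi_dataset} with those trials, labels preserved.
#' @export
subset_trials <- function(dataset, idx) {
  mi_dataset(dataset$trials[idx, , , drop = FALSE],
             dataset$labels[idx],
             dataset$sampling_rate,
             dataset$channel_names,
             dataset$provenance)
}

# Internal: check that both classes are present before any fitting step.
assert_two_classes <- function(dataset) {
  if (length(unique(dataset$labels)) < 2L)
    stop("both classes must be present for fitting")
  invisible(TRUE)
}
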