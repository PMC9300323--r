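#' Zero-phase band-pass filter an epoched dataset
#'
#' Applies an order-4 Butterworth band-pass forward and backward
#' (\code{signal::filtfilt}) to every channel of every trial, giving a
#' zero-phase response so no group delay is introduced between channels.
#'
#' @param dataset An \code{\link{mi_dataset}}.
#' @param low,high Band edges in Hz; \code{0 < low < high < Nyquist}.
#' @param order Butterworth order (per pass); default 4.
#'
#' @return A filtered copy of the dataset, same shape and labels.
#' @export
bandpass_filter <- function(dataset, low, high, order = 4L) {
  nyq <- dataset$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("invalid band: need 0 < low < high < Nyquist (", nyq, " Hz)")
  nt <- dim(dataset$trials)[3L]
  # filtfilt padding needs trials comfortably longer than the filter edge
  if (nt < 6L * (order + 1L))
    stop("trial too short for the filter warm-up length")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- dataset$trials
  for (i in seq_len(dim(out)[1L]))
    for (ch in seq_len(dim(out)[2L]))
      out[i, ch, ] <- signal::filtfilt(bf, dataset$trials[i, ch, ])
  mi_dataset(out, dataset$labels, dataset$sampling_rate,
             dataset$channel_names,
             paste0(dataset$provenance, sprintf(" | bandpass %g-%g Hz", low, high)))
}

# Hann-windowed periodogram of one channel: power per FFT bin (one-sided).
periodogram_power <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  xw <- (x - mean(x)) * w
  p <- Mod(stats::fft(xw))^2 / sum(w^2)
  nb <- floor(n / 2) + 1L
  list(freq = (seq_len(nb) - 1L) * fs / n, power = p[seq_len(nb)])
}

# Per-trial, per-channel band power on the bin grid:
# trials x channels x bins array.
trial_band_powers <- function(dataset, freq_grid, channels) {
  d <- dim(dataset$trials)
  fs <- dataset$sampling_rate
  half <- if (length(freq_grid) > 1L) diff(freq_grid)[1L] / 2 else 0.5
  pow <- array(0, dim = c(d[1L], length(channels), length(freq_grid)))
  # bin membership is the same for every trial/channel: precompute
  pg0 <- periodogram_power(dataset$trials[1L, 1L, ], fs)
  bin_sel <- lapply(freq_grid, function(f)
    which(pg0$freq >= f - half & pg0$freq < f + half))
  for (i in seq_len(d[1L])) {
    for (ci in seq_along(channels)) {
      pg <- periodogram_power(dataset$trials[i, channels[ci], ], fs)
      pow[i, ci, ] <- vapply(bin_sel, function(s) sum(pg$power[s]), numeric(1))
    }
  }
  pow
}

# The discriminability statistic: squared point-biserial correlation written
# in its BCI form, sqrt(N1*N2)/(N1+N2) * (mean P1 - mean P2) / sd_pop(P1 u P2),
# then squared. Population (divide-by-n) SD of the pooled sample makes this
# exactly the squared Pearson correlation between power and class label.
r2_statistic <- function(p1, p2) {
  n1 <- length(p1); n2 <- length(p2)
  pooled <- c(p1, p2)
  sd_pop <- sqrt(mean((pooled - mean(pooled))^2))
  if (sd_pop == 0) {
    warning("zero pooled variance; r^2 defined as 0")
    return(0)
  }
  r <- sqrt(n1 * n2) / (n1 + n2) * (mean(p1) - mean(p2)) / sd_pop
  r^2
}

#' Per-frequency class-discriminability (r-squared) spectrum
#'
#' For each frequency bin, computes per-trial band power (Hann periodogram,
#' summed over the bin) and the squared point-biserial correlation between
#' band power and class label — the signed-r-squared statistic standard in
#' sensorimotor BCI, with the population-SD convention for the pooled sample.
#'
#' Channel handling: with \code{channel_agg = "max"} (default) r-squared is
#' computed per channel and the best channel's value is kept per bin — the
#' convention of channel-wise r-squared maps, and the only aggregation that
#' detects bilateral ERD whose left- and right-channel power changes cancel
#' in the channel mean. \code{"mean"} averages band power over channels
#' before the statistic; \code{"single"} uses one channel.
#'
#' @param dataset An \code{\link{mi_dataset}} with both classes present.
#' @param channel_agg "max" (default), "mean", or "single".
#' @param freq_grid Bin centre frequencies in Hz; default 1-Hz bins 4-40 Hz.
#' @param channel Channel index when \code{channel_agg = "single"}.
#'
#' @return An object of class \code{r2_spectrum}: list with \code{freqs},
#'   \code{r2} (one value in [0,1] per bin), and the class trial counts
#'   \code{n1}, \code{n2}.
#' @export
compute_r2_spectrum <- function(dataset,
                                channel_agg = c("max", "mean", "single"),
                                freq_grid = NULL,
                                channel = 1L) {
  channel_agg <- match.arg(channel_agg)
  assert_two_classes(dataset)
  n1 <- sum(dataset$labels == 1L); n2 <- sum(dataset$labels == 2L)
  if (n1 < 2L || n2 < 2L)
    stop("each class needs at least 2 trials to estimate r^2")
  nyq <- dataset$sampling_rate / 2
  if (is.null(freq_grid))
    freq_grid <- seq(4, min(40, floor(nyq) - 1), by = 1)
  if (any(diff(freq_grid) <= 0)) stop("freq_grid must be strictly increasing")
  chans <- if (channel_agg == "single") as.integer(channel)
           else seq_len(dim(dataset$trials)[2L])
  pow <- trial_band_powers(dataset, freq_grid, chans)
  i1 <- dataset$labels == 1L
  r2 <- vapply(seq_along(freq_grid), function(k) {
    if (channel_agg == "mean") {
      p <- apply(pow[, , k, drop = FALSE], 1L, mean)
      r2_statistic(p[i1], p[!i1])
    } else {
      max(vapply(seq_along(chans), function(ci)
        r2_statistic(pow[i1, ci, k], pow[!i1, ci, k]), numeric(1)))
    }
  }, numeric(1))
  structure(list(freqs = freq_grid, r2 = r2, n1 = n1, n2 = n2),
            class = "r2_spectrum")
}

#' @export
print.r2_spectrum <- function(x, ...) {
  best <- which.max(x$r2)
  cat("<r2_spectrum> ", length(x$freqs), " bins ",
      min(x$freqs), "-", max(x$freqs), " Hz; peak r^2 = ",
      signif(x$r2[best], 3), " at ", x$freqs[best], " Hz (n1=", x$n1,
      ", n2=", x$n2, ")\n", sep = "")
  invisible(x)
}

#' Select the most discriminative contiguous frequency band
#'
#' Sweeps every contiguous window on the spectrum's bin grid with width
#' between \code{min_width} and \code{max_width} Hz and returns the one
#' maximizing mean r-squared. Ties break toward lower frequency, then toward
#' narrower width.
#'
#' @param spec An \code{r2_spectrum} from \code{\link{compute_r2_spectrum}}.
#' @param min_width,max_width Window width bounds in Hz.
#' @param search_range Length-2 Hz range restricting the search; default the
#'   full spectrum support.
#'
#' @return List with \code{low}, \code{high} (Hz) and \code{score} (mean
#'   r-squared over the chosen window).
#' @export
select_band <- function(spec, min_width = 4, max_width = 12,
                        search_range = NULL) {
  freqs <- spec$freqs
  if (!is.null(search_range)) {
    keep <- freqs >= search_range[1L] & freqs <= search_range[2L]
    if (!any(keep)) stop("empty search range")
    freqs <- freqs[keep]
    r2 <- spec$r2[keep]
  } else r2 <- spec$r2
  step <- if (length(freqs) > 1L) diff(freqs)[1L] else 1
  half <- step / 2
  best <- NULL
  for (nb in seq(max(1L, round(min_width / step)),
                 max(1L, round(max_width / step)))) {
    if (nb > length(freqs)) break
    for (s in seq_len(length(freqs) - nb + 1L)) {
      sc <- mean(r2[s:(s + nb - 1L)])
      cand <- list(low = freqs[s] - half, high = freqs[s + nb - 1L] + half,
                   score = sc, width = nb)
      # ties: lower frequency first, then narrower width
      if (is.null(best) || sc > best$score ||
          (sc == best$score && (cand$low < best$low ||
            (cand$low == best$low && nb < best$width))))
        best <- cand
    }
  }
  best[c("low", "high", "score")]
}
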