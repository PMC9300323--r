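#' Configuration for the synthetic motor-imagery EEG generator
#'
#' Bundles the generator parameters with validation. Defaults describe a
#' small sensorimotor montage: 8 channels, 2-second epochs at 250 Hz, a mu
#' rhythm centred at 10 Hz, and a moderate planted ERD effect.
#'
#' @param n_channels Number of EEG channels (must be smaller than
#'   \code{n_samples_per_trial} so per-trial covariances are estimable).
#' @param n_samples_per_trial Samples per epoch.
#' @param sampling_rate Sampling rate in Hz; must exceed the Nyquist
#'   requirement \code{2 * (mu_freq + mu_bandwidth)}.
#' @param n_trials_per_class Trials generated for each of the two classes.
#' @param mu_freq Centre frequency of the mu sources in Hz.
#' @param mu_bandwidth Spectral half-width of the mu sources in Hz, realized
#'   through random amplitude modulation.
#' @param erd_depth Fraction in [0, 1]: relative attenuation of the active
#'   class's mu source power (event-related desynchronization). 0 plants no
#'   effect; 1 silences the source completely during its class's trials.
#' @param noise_sd Standard deviation of the additive white sensor noise, in
#'   the same amplitude units as the unit-RMS sources.
#' @param n_common_sources Number of band-limited noise sources shared by
#'   both classes.
#' @param seed Integer seed; the single source of all randomness in a
#'   generated dataset.
#'
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n_channels = 8L,
                         n_samples_per_trial = 500L,
                         sampling_rate = 250,
                         n_trials_per_class = 50L,
                         mu_freq = 10,
                         mu_bandwidth = 2,
                         erd_depth = 0.5,
                         noise_sd = 0.2,
                         n_common_sources = 2L,
                         seed = 1L) {
  cfg <- list(n_channels = as.integer(n_channels),
              n_samples_per_trial = as.integer(n_samples_per_trial),
              sampling_rate = as.numeric(sampling_rate),
              n_trials_per_class = as.integer(n_trials_per_class),
              mu_freq = as.numeric(mu_freq),
              mu_bandwidth = as.numeric(mu_bandwidth),
              erd_depth = as.numeric(erd_depth),
              noise_sd = as.numeric(noise_sd),
              n_common_sources = as.integer(n_common_sources),
              seed = as.integer(seed))
  if (cfg$n_channels >= cfg$n_samples_per_trial)
    stop("n_channels must be less than n_samples_per_trial ",
         "(covariance estimation requires N < T)")
  if (cfg$n_trials_per_class < 1L)
    stop("n_trials_per_class must be >= 1")
  if (cfg$erd_depth < 0 || cfg$erd_depth > 1)
    stop("erd_depth must lie in [0, 1]")
  if (cfg$sampling_rate <= 2 * (cfg$mu_freq + cfg$mu_bandwidth))
    stop("sampling_rate must exceed 2 * (mu_freq + mu_bandwidth) (Nyquist)")
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative")
  # one mu source per class plus the common sources must fit in the montage
  if (2L + cfg$n_common_sources > cfg$n_channels)
    stop("n_channels must be >= 2 + n_common_sources")
  class(cfg) <- "synth_config"
  cfg
}

# Unit-RMS amplitude-modulated sinusoid: centre frequency f, random phase,
# slow random AM whose rate is bounded by the requested bandwidth.
am_sinusoid <- function(n, fs, f, bandwidth) {
  t <- (seq_len(n) - 1L) / fs
  phase <- stats::runif(1L, 0, 2 * pi)
  am_rate <- stats::runif(1L, 0.2, max(0.25, bandwidth / 2))
  am_phase <- stats::runif(1L, 0, 2 * pi)
  env <- 1 + 0.5 * sin(2 * pi * am_rate * t + am_phase)
  s <- env * sin(2 * pi * f * t + phase)
  s / sqrt(mean(s^2))
}

# Unit-RMS band-limited Gaussian noise via FFT masking (passband in Hz).
bandlimited_noise <- function(n, fs, low = 2, high = 30) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1L) * fs / n
  freqs <- pmin(freqs, fs - freqs)          # two-sided symmetric axis
  X[freqs < low | freqs > high] <- 0 + 0i
  s <- Re(stats::fft(X, inverse = TRUE)) / n
  s / sqrt(mean(s^2))
}

#' Generate a synthetic two-class motor-imagery EEG dataset
#'
#' Realizes a linear source-mixing forward model with a planted ERD effect.
#' Each class has one dedicated mu-band source (an amplitude-modulated
#' sinusoid at \code{mu_freq}); during a class's own trials that source's
#' amplitude is scaled by \code{sqrt(1 - erd_depth)}, i.e. its band power is
#' attenuated by \code{erd_depth}, while the opposite class's source stays at
#' baseline. Band-limited common sources and white sensor noise are
#' identically distributed across classes, so the class difference lives
#' entirely in the mu sources' variance — the structure CSP is designed to
#' recover. The mixing matrix is drawn once per dataset (Gaussian entries,
#' QR-orthonormalized columns) and returned so recovery can be tested.
#'
#' @param config A \code{\link{synth_config}}.
#' @param return_sources If TRUE, also return the latent source signals
#'   (trial x source x sample array) for recovery tests.
#'
#' @return A list with elements \code{dataset} (an \code{\link{mi_dataset}};
#'   trials of class 1 first) and \code{forward_model} (a list with the
#'   channels x sources \code{mixing} matrix, source counts, and the column
#'   indices of the two class-specific mu sources); plus \code{sources} when
#'   requested.
#' @export
#' @examples
#' gen <- generate_mi_dataset(synth_config(n_trials_per_class = 5, seed = 42))
#' gen$dataset
generate_mi_dataset <- function(config, return_sources = FALSE) {
  if (!inherits(config, "synth_config"))
    config <- do.call(synth_config, as.list(config))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n_src <- 2L + config$n_common_sources
  nc <- config$n_channels
  nt <- config$n_samples_per_trial
  fs <- config$sampling_rate

  # Mixing: Gaussian draw, QR-orthogonalized columns (orthogonal directions,
  # column norms kept from the draw) -> full column rank, identifiable
  # patterns, and unequal source gains as lateralized sources have on a real
  # montage. Equal-norm columns would make channel-averaged band power
  # blind to the planted effect (the two classes' attenuations cancel).
  qrd <- qr(matrix(stats::rnorm(nc * n_src), nc, n_src))
  A <- qr.Q(qrd) %*% diag(abs(diag(qr.R(qrd))), n_src)

  total <- 2L * config$n_trials_per_class
  labels <- rep(c(1L, 2L), each = config$n_trials_per_class)
  trials <- array(0, dim = c(total, nc, nt))
  sources <- if (return_sources) array(0, dim = c(total, n_src, nt)) else NULL
  atten <- sqrt(1 - config$erd_depth)

  for (i in seq_len(total)) {
    S <- matrix(0, n_src, nt)
    S[1L, ] <- am_sinusoid(nt, fs, config$mu_freq, config$mu_bandwidth)
    S[2L, ] <- am_sinusoid(nt, fs, config$mu_freq, config$mu_bandwidth)
    if (labels[i] == 1L) S[1L, ] <- S[1L, ] * atten else S[2L, ] <- S[2L, ] * atten
    for (k in seq_len(config$n_common_sources))
      S[2L + k, ] <- bandlimited_noise(nt, fs)
    X <- A %*% S
    if (config$noise_sd > 0)
      X <- X + matrix(stats::rnorm(nc * nt, sd = config$noise_sd), nc, nt)
    trials[i, , ] <- X
    if (return_sources) sources[i, , ] <- S
  }

  ds <- mi_dataset(trials, labels, fs,
                   provenance = sprintf(
                     "synthetic: erd_depth=%g noise_sd=%g seed=%d",
                     config$erd_depth, config$noise_sd, config$seed))
  fm <- list(mixing = A,
             n_class_sources_1 = 1L,
             n_class_sources_2 = 1L,
             n_common_sources = config$n_common_sources,
             class1_cols = 1L,
             class2_cols = 2L)
  class(fm) <- "forward_model"
  out <- list(dataset = ds, forward_model = fm)
  if (return_sources) out$sources <- sources
  out
}
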