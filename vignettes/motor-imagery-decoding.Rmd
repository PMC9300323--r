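---
title: "Decoding two-class motor imagery: band selection, CSP, and Fisher LDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding two-class motor imagery: band selection, CSP, and Fisher LDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midecode)
```

## The decoding problem

Imagining a left- or right-hand movement attenuates the mu rhythm (a
sensorimotor oscillation around 10 Hz) over the contralateral motor cortex —
event-related desynchronization (ERD). A motor-imagery brain–computer
interface turns this lateralized power change into a binary decision. The
pipeline implemented here is the classical one:

1. **Band selection** — find the subject-specific frequency band in which the
   two classes differ most, using the r² (squared point-biserial)
   discriminability spectrum;
2. **Band-pass filtering** — isolate that band with a zero-phase filter;
3. **CSP spatial filtering** — learn channel combinations whose variance is
   maximal for one class and minimal for the other, and summarize each trial
   by normalized component variances;
4. **Fisher LDA** — classify the feature vectors with a closed-form linear
   discriminant.

A separate study-statistics stage analyses a subjects × conditions accuracy
table (per-condition summaries, one-way repeated-measures ANOVA, exploratory
paired comparisons).

## The r² discriminability spectrum

For a frequency bin, let $P_1$ and $P_2$ be the per-trial band powers of the
$N_1$ left- and $N_2$ right-imagery trials. The statistic is

$$r^2 = \left[\frac{\sqrt{N_1 N_2}}{N_1+N_2}\,
  \frac{\overline{P_1}-\overline{P_2}}{\mathrm{sd}(P_1 \cup P_2)}\right]^2,$$

with the **population** (divide-by-$n$) standard deviation of the pooled
sample. Under that convention $r^2$ is exactly the squared Pearson
correlation between band power and a 0/1 class label (the squared
point-biserial correlation), which the test suite verifies on random data to
$10^{-10}$. It is invariant to shifting or positively rescaling all powers
and to swapping the class labels.

Band power is computed per trial from a Hann-windowed periodogram, summed
over 1 Hz bins on a 4–40 Hz grid by default. **Channel handling**: the
default (`channel_agg = "max"`) computes r² per channel and keeps the best
channel per bin, the convention of channel-wise r² maps. We deliberately do
not default to averaging band power over channels: ERD is bilateral and
complementary (left-hand imagery suppresses right-hemisphere mu and vice
versa), so the left- and right-channel power changes cancel in a channel
mean and the pooled-power statistic can be blind to a strong effect. The
mean and single-channel variants remain available.

`select_band()` sweeps every contiguous window between `min_width` and
`max_width` (default 4–12 Hz) and returns the window maximizing mean r²;
ties break toward lower frequency, then narrower width, so the selection is
deterministic.

## CSP: the whitening path

Each trial $X$ (channels × samples, with fewer channels than samples) gives
a trace-normalized covariance $R = XX^\top/\mathrm{tr}(XX^\top)$, so every
trial contributes equally regardless of amplitude. With class averages
$\bar R_1, \bar R_2$, the composite $R = \bar R_1 + \bar R_2$ is
eigendecomposed $R = U\lambda U^\top$, whitened by
$P = \lambda^{-1/2}U^\top$, and the whitened class-1 covariance
$P\bar R_1 P^\top = BDB^\top$ yields the projection $W = B^\top P$ with rows
ordered by descending $D$. Because $P\bar R_1P^\top + P\bar R_2P^\top = I$,
the class-2 eigenvalue of each component is one minus the class-1
eigenvalue: the first rows of $W$ maximize class-1 variance while minimizing
class-2 variance, the last rows the reverse. Rows of $W$ are spatial
*filters*; columns of $W^{-1}$ are the corresponding spatial *patterns*
(scalp topographies, the objects compared to the true mixing in recovery
tests).

Features for a trial are the normalized variances of the projections through
the top and bottom `n_pairs` filters, $f_i = \mathrm{var}(Z_i)/\sum_j
\mathrm{var}(Z_j)$ — the variance-share form, not the more common
log-variance (available via `log_variance = TRUE` but off by default, for
fidelity to the variance-share formulation). Features are nonnegative, sum
to one, and are invariant to rescaling the trial.

Numerical choices: eigenvector signs are fixed by making each filter's
largest-magnitude entry positive; equal eigenvalues keep the
eigendecomposition's output order (documented as arbitrary); a composite
covariance whose condition exceeds $10^{10}$ raises an error naming the
`shrinkage` remedy, which replaces each class covariance by
$(1-\gamma)\bar R_k + \gamma\,\mathrm{tr}(\bar R_k)I/N$ (default
$\gamma = 0$). The test suite checks the whitening path against an
independent generalized-eigenproblem solve of
$\bar R_1 v = \mu(\bar R_1+\bar R_2)v$ on random instances.

## Fisher LDA in closed form

With class means $\mu_0, \mu_1$ and *un-normalized* scatter matrices
$\Sigma_j = \sum_{x \in X_j}(x-\mu_j)(x-\mu_j)^\top$, the discriminant
maximizes $(w^\top(\mu_0-\mu_1))^2 / (w^\top\Sigma_0 w + w^\top\Sigma_1 w)$,
whose maximizer is $w \propto (\Sigma_0+\Sigma_1)^{-1}(\mu_0-\mu_1)$. Using
scatter rather than covariance changes only $w$'s scale, which is normalized
away. The formulation supplies no intercept; we use the equal-prior midpoint
threshold $w^\top(\mu_0+\mu_1)/2$, appropriate for the balanced designs this
pipeline targets, with ties going to class 0. A small default ridge
($10^{-10}$ × the scatter's trace scale) guards the solve; `ridge = 0`
recovers the exact solution for oracle comparisons.

## The synthetic ERD generator

No public recordings accompany the study this package's statistics stage
analyses, so every decoding stage is validated on synthetic data with a
known ground truth. The generator realizes the linear forward model
$X = AS + \varepsilon$:

* one mu source per class: unit-RMS amplitude-modulated sinusoids at
  `mu_freq` (default 10 Hz) with random phase per trial and AM rate bounded
  by `mu_bandwidth` (default 2 Hz);
* `n_common_sources` (default 2) band-limited (2–30 Hz) Gaussian noise
  sources shared by both classes;
* white sensor noise of standard deviation `noise_sd` (default 0.2, i.e.
  one fifth of a source's RMS);
* a mixing matrix drawn once per dataset from a standard Gaussian and
  QR-orthogonalized — orthogonal columns, but column norms kept from the
  draw. Exactly orthonormal columns would give every source the same total
  gain, making channel-averaged band power identical across classes in
  expectation (the two complementary attenuations cancel); unequal gains
  reproduce the asymmetry that lateralized sources have on a real montage.

ERD is planted as variance attenuation: during a class's own trials, that
class's mu source amplitude is scaled by $\sqrt{1-\texttt{erd\_depth}}$, so
its band power drops by `erd_depth` while the other class's source stays at
baseline. This is the minimal model exhibiting ERD as a class-dependent
variance change — which is precisely the structure CSP exploits. Defaults (8
channels, 500 samples at 250 Hz, 50 trials per class, `erd_depth` 0.5) were
chosen once as a plausible small montage; the epoch length and channel count
of the original recordings were never published, so these are declared,
not inferred.

What the generator does **not** emulate: volume conduction and realistic
10–20 geometry, 1/f background spectra, eye/muscle artifacts, non-stationary
rhythms, inter-subject variability. Passing tests therefore demonstrate
algorithmic correctness (planted effects are recovered, oracles agree), not
expected performance on real EEG.

## Cross-validated evaluation

How the study computed its accuracies (split, folds, online/offline) was
never stated; `run_pipeline()` is a declared **reconstruction**: stratified
5-fold cross-validation repeated 5 times, reporting mean held-out accuracy
in percent. All data-dependent fitting — band selection included — happens
inside each training fold, which a leakage test enforces (reordering
held-out trials can never change a fold's accuracy). A single seed makes the
whole evaluation reproducible.

## The study-statistics stage

The embedded 9 × 4 table (percent accuracies of nine subjects under
pre-stimulation, pseudo-stimulation, tACS, and tDCS conditions) is analysed
with:

* **Column summaries** — means and sample ($n-1$) SDs, the convention that
  reproduces the published summary row. One published cell deserves note:
  the recomputed tDCS mean is 88.7156, which rounds to 88.72; the published
  88.71 is evidently a truncation, so reproduction checks give that cell one
  unit in the last printed digit (±0.01) where the rounded cells get ±0.005.
* **Repeated-measures ANOVA** — the two-way decomposition without
  replication: $SS_{total} = SS_{condition} + SS_{subject} + SS_{error}$,
  $F = MS_{condition}/MS_{error}$ on $(c-1, (c-1)(s-1))$ degrees of freedom.
  The published integer degrees of freedom (3, 24) imply no sphericity
  correction, so none is applied by default; a Greenhouse–Geisser option
  exists. The implementation is checked against a brute-force residual
  computation and against `stats::aov` with a subject error stratum.
  A table with zero condition SS reports $F = 0$ even when the error SS is
  also degenerate.
* **Pairwise comparisons** — paired two-sided t-tests, unadjusted. The study
  reports four pairwise p-values without naming the test or an unambiguous
  pair-to-value mapping, so this output is labeled an exploratory
  reconstruction and only the direction (tDCS vs pre-stimulation is
  significant; tACS vs pre-stimulation is not) is asserted.

## Worked example

```{r example, eval = FALSE}
gen <- generate_mi_dataset(
  synth_config(n_trials_per_class = 50, erd_depth = 0.8,
               noise_sd = 0.1, seed = 7))
spec <- compute_r2_spectrum(gen$dataset)
select_band(spec)                     # picks a window around 10 Hz
res <- run_pipeline(gen$dataset, pipeline_config(seed = 1))
res                                   # near-perfect accuracy at this depth

rm_anova(load_table3())               # F(3, 24) = 10.436
```

## Problem sizes and runtime

The shipped tests and the acceptance script run on deliberately small
problems — 8-channel montages, 100–200 trials, 2-second epochs, 5-fold
cross-validation — chosen so the full validation executes in about a minute
while leaving the planted effects far above their detection thresholds.

## Known limitations

* Two classes only, by construction (both CSP and this LDA are two-class).
* The EDF writer/reader covers the subset of the format the package emits
  (uniform sample rate, one data record per trial, labels in a CSV sidecar);
  it is not a general-purpose EDF library.
* `erd_depth` near 0 with few trials gives chance-level decoding, as it
  must; the monotonicity of accuracy in `erd_depth` is a statistical, not
  per-seed, guarantee.
* The pairwise-comparison p-values are not comparable to the published ones
  beyond their direction, for the reasons above.
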