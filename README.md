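# midecode

Two-class motor-imagery EEG decoding in R: subject-specific frequency-band
selection with the r² (squared point-biserial) discriminability spectrum,
zero-phase band-pass filtering, Common Spatial Patterns (CSP) with
normalized-variance features, and closed-form Fisher LDA, evaluated with
leakage-free stratified cross-validation. The package also ships a synthetic
ERD/ERS generator with a known linear forward model (so every stage is
testable against ground truth) and a study-statistics stage for a
subjects × conditions accuracy table (summaries, one-way repeated-measures
ANOVA, exploratory paired comparisons).

## Who this is for

Researchers in sensorimotor BCI / neural signal processing who need a small,
fully tested reference implementation of the classical mu-rhythm decoding
chain, and anyone who wants to re-derive the statistics of a
9-subject × 4-condition (pre-stimulation, pseudo-stimulation, tACS, tDCS)
accuracy table from its printed values.

## The methods in brief

**Band discriminability.** For each frequency bin, with per-trial band
powers P₁ (N₁ left-imagery trials) and P₂ (N₂ right-imagery trials),

    r² = [ √(N₁N₂)/(N₁+N₂) · (mean P₁ − mean P₂) / sd_pop(P₁ ∪ P₂) ]²

with the population-SD convention, making r² the squared point-biserial
correlation between band power and class label. The band maximizing
windowed mean r² is selected per training fold.

**CSP.** Trace-normalized trial covariances R = XXᵀ/tr(XXᵀ) are averaged per
class; the composite R̄₁+R̄₂ = UλUᵀ gives the whitening P = λ^(−1/2)Uᵀ;
eigendecomposing PR̄₁Pᵀ = BDBᵀ gives the projection W = BᵀP whose first/last
rows maximize one class's variance while minimizing the other's
(eigenvalues of the two classes sum to 1 per component). Trial features are
variance shares fᵢ = var(Zᵢ)/Σⱼvar(Zⱼ) over the retained top/bottom filter
pairs.

**LDA.** w ∝ (Σ₀+Σ₁)⁻¹(μ₀−μ₁) with un-normalized class scatters, midpoint
threshold wᵀ(μ₀+μ₁)/2.

**Repeated-measures ANOVA.** SS_total = SS_condition + SS_subject +
SS_error; F = MS_condition/MS_error on (c−1, (c−1)(s−1)) degrees of
freedom, no sphericity correction by default.

## Worked example

```r
library(midecode)

gen <- generate_mi_dataset(
  synth_config(n_trials_per_class = 50, erd_depth = 0.8,
               noise_sd = 0.1, seed = 7))
spec <- compute_r2_spectrum(gen$dataset)
spec
#> <r2_spectrum> 37 bins 4-40 Hz; peak r^2 = 0.661 at 10 Hz (n1=50, n2=50)
select_band(spec)
#> $low  [1] 8.5
#> $high [1] 12.5
#> $score [1] 0.34

res <- run_pipeline(gen$dataset, pipeline_config(seed = 1))
res
#> <evaluation_result> mean accuracy 100.00% over 25 folds (5-fold x 5 repeats)
#>   band(s) used: 8.5-12.5 Hz, 7.5-11.5 Hz
#>   confusion (rows = truth):
#>      pred
#> truth   1   2
#>     1 250   0
#>     2   0 250
```

The planted mu-band ERD (80% power attenuation at 10 Hz) is found by the r²
spectrum, the auto-selected band brackets 10 Hz, and cross-validated
accuracy is perfect at this effect size. With `erd_depth = 0` the same
pipeline sits at chance (~50%).

The study-statistics stage recomputes the published table summaries:

```r
column_summary(load_table3())
#>            condition     mean       sd
#> 1    pre-stimulation 82.06889 5.672150
#> 2 pseudo-stimulation 82.66333 7.252005
#> 3               tACS 87.06667 7.634093
#> 4               tDCS 88.71556 6.880351
rm_anova(load_table3())
#> Repeated-measures ANOVA: F(3, 24) = 10.436, p = 0.000139
#>   SS condition 288.556 | SS subject 1301.874 | SS error 221.193
```

A mean accuracy of ~82% before stimulation rising to ~89% after tDCS, with
F(3, 24) = 10.436 (p < 0.001), indicates a significant condition effect on
motor-imagery classification accuracy.

## Command line

A thin CLI over the same functions lives at `inst/cli/midecode`:

```sh
Rscript inst/cli/midecode simulate --config cfg.yaml --out data/run1
Rscript inst/cli/midecode r2-spectrum --in data/run1 --out spectrum.csv
Rscript inst/cli/midecode evaluate --in data/run1 --out result.json
Rscript inst/cli/midecode reproduce-stats --out report.json
```

Datasets serialize to a flat CSV bundle (lossless) or EDF (16-bit
quantized), each with a labels CSV sidecar.

## Package layout

- `R/synthetic_eeg.R` — forward-model ERD generator
- `R/preprocessing.R` — filtering, r² spectrum, band selection
- `R/csp.R` — covariances, whitening path, features, patterns
- `R/lda.R` — closed-form Fisher discriminant
- `R/pipeline.R` — cross-validated evaluation, configs
- `R/io.R` — EDF and CSV-bundle readers/writers
- `R/study_stats.R` — accuracy-table statistics
- `vignettes/motor-imagery-decoding.Rmd` — methods and design rationale
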