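---
title: "Models and methods behind the sulfostress pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the sulfostress pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulfostress)
```

## The experimental design being modelled

`sulfostress` analyses batch-culture stress experiments with
*Saccharolobus islandicus* REY15A under three conditions — an optimal
control (pH 3.4, 76 °C), acid stress (pH 2.4, 76 °C) and cold stress
(pH 3.4, 66 °C) — each harvested at mid-log and early stationary phase in
biological triplicate. `design_samples()` enumerates the 18 samples and
`design_contrasts()` the four stress-versus-optimal contrasts (each stress
compared to the control at the same phase). All tables are plain TSV with
a header row and `NA` as the only missing-value token; one dialect
everywhere avoids parser drift, and sample identifiers
(`acid_ML_r1`, ...) are deterministic so fixtures are diffable.

## Growth kinetics

Cultures start at OD600 = 0.02 and are monitored to saturation. The
package estimates the specific growth rate per replicate in one of two
ways.

The default fits the three-parameter logistic
$\mathrm{OD}(t) = K\,\mathrm{OD}_0 e^{\mu t} / (K + \mathrm{OD}_0(e^{\mu t}-1))$
by nonlinear least squares (`stats::nls` with the self-starting `SSlogis`
parametrization, `scaleOffset = 1` so that noise-free data converge).
Batch curves monitored into stationary phase identify all three
parameters; the fit is unbiased and recovers noiseless doubling times to
numerical precision.

The alternative (`method = "window"`, also exported as
`fit_exponential_window()`) is the classical log-linear sliding window:
ordinary least squares of $\ln \mathrm{OD}$ against time over the
contiguous window of at least 4 readings maximizing $r^2$, restricted to
an OD band (default 0.04 to half the observed maximum) that trims the
noise-dominated start and the plateau. Ties go to the earlier, then the
longer, window. This estimator is appropriate for series truncated within
the exponential phase, but on full logistic curves the $r^2$ criterion
prefers long windows whose span reaches the half-maximum bound, where the
local slope of $\ln \mathrm{OD}$ has already fallen to $\mu/2$; in
simulation this inflates doubling times by tens of percent. That measured
bias is why the model-based fit is the default and the window fit is kept
as a documented alternative for truncated data.

Doubling time is $T_d = \ln 2 / \mu$; condition summaries report the mean
and standard error ($\mathrm{sd}/\sqrt{n}$ — the `±` convention used for
every summary in the package) across replicates. Maximum densities are
per-replicate maxima of the observed series, compared across conditions
by one-way ANOVA with Tukey HSD post-hoc tests at p < 0.05. Degenerate
zero-variance input (identical replicates everywhere) reports p = 1
rather than NaN so synthetic edge cases cannot crash a run.

## GDGT lipid profiling

Core GDGTs carry 0–8 cyclopentane rings; late-eluting chromatographic
isomers of GDGT-3, -4 and -5 (written `GDGT-3p` etc. for TSV-safe column
names) are summed into their major components before anything else —
`merge_isomers()` conserves total area exactly. Relative abundances
$f_n$ are peak areas over the per-sample total, and the ring index is the
abundance-weighted mean ring number

$$\mathrm{RI} = \frac{\sum_{n=1}^{8} n\, f_n}{\sum_{n=0}^{8} f_n},$$

which is 0 exactly when all mass is GDGT-0 and at most 8. GDGT-8 is
carried through every code path even though the organism is not observed
to produce it, because the definition includes it. Stress-versus-optimal
comparisons of RI and of each $f_n$ use Welch's t-test by default (the
pooled-variance test is available via `pooled = TRUE`); Welch is the
safer default because stress conditions visibly change replicate
variance. Zero-variance groups with equal means give p = 1; with
different means, p = 0 with a warning.

## Transcript accounting

Replicate QC computes Pearson correlations between libraries on raw
counts (an option for log-CPM exists upstream of the rule): a library
passes when its best within-group correlation exceeds 0.9; below that it
is retained with a warning unless some library outside its group
correlates better by more than 0.05, in which case it is excluded. The
retention rule generalizes a decision originally made ad hoc for a single
borderline library; the generalized form is what the package implements.

The DE engine is deliberately a labelled stand-in: per-gene Welch t-tests
on $\log_2(\mathrm{CPM} + 0.5)$ with Benjamini–Hochberg adjustment, so
that synthetic counts can flow through the downstream accounting end to
end. It is not a count-model DE method; for real data an externally
produced result table feeds `call_degs()` directly. Genes whose mean raw
count across the contrast's six libraries falls below 5 are reported with
`NA` p-values and can never be called — the analogue of independent
filtering.

Sign convention (prominent because it inverts the common default):
transcript log2FC is mean(optimal) − mean(stress), so **negative means
increased expression under stress**. A DEG needs |log2FC| ≥ 1 and
adjusted p < 0.05; direction is `up_in_stress` for log2FC ≤ −1. The Venn
partition keys responses by (gene, direction) per phase and splits them
into acid-unique, cold-unique and common; `unique + common = total` per
stress and direction is asserted on every call.

## The protein Z procedure

Per condition and phase, a protein quantified in $\ge 2$ replicates gets
a mean log2 abundance $m$, the SD of those replicate values
$\mathrm{sd}_{between}$, the mean reported within-replicate spectral SE
$\bar{s}_{within}$, and a total uncertainty combining the two layers in
quadrature, $u = \sqrt{\mathrm{sd}_{between}^2 + \bar{s}_{within}^2}$.
"Root-square sum of A plus B" admits an additive reading $A + B$; both
are implemented (`combine = "additive"`), quadrature is the default
because that is what a root-square sum most plausibly means. The test
statistic is

$$Z = \frac{m_{stress} - m_{optimal}}{u_{stress} + u_{optimal}}$$

with a **plain sum** in the denominator, kept exactly as specified even
though quadrature would be conventional. Two features make the procedure
deliberately conservative: $u$ carries the full between-replicate SD
rather than the SE of the mean, and the two uncertainties add linearly.
Z-scores are referred to a standard normal (two-sided by default; the
sidedness is a documented choice, one-sided available), adjusted by
Benjamini–Hochberg within each contrast, and calls require adjusted
p < 0.1 **and** |log2FC| ≥ 1. Protein log2FC is
$m_{stress} - m_{optimal}$: **positive = increased under stress**,
opposite to the transcript convention; the concordance step reconciles
the two on direction of change. Proteins missing a condition are carried
with `NA` statistics, never dropped. The BH step-up is implemented in the
package (`bh_adjust()`, NA-safe) and is cross-checked in the tests
against both a brute-force oracle and `stats::p.adjust`.

## The synthetic-data generator

The generator is first-class, tested code: every pipeline input can be
produced with known ground truth (`gen_truth()`), so each estimator is
validated by parameter recovery. Every stage derives its own RNG stream
from the global seed plus a fixed stage offset, making stages
individually reproducible.

* **Growth** — logistic trajectories per condition with rates set by the
  observed doubling times (6.8, 9.8, 14.0 h), carrying capacities by the
  observed maximum densities (1.48, 0.75, 1.69), OD0 = 0.02, sampled
  every 2 h over 200 h (the slowest condition needs ~180 h to plateau,
  and the design requires every culture to reach early stationary phase),
  plus additive Gaussian reading noise (sd 0.01 OD, a typical
  bench-spectrophotometer precision) truncated at zero. The logistic
  form itself is a modelling choice — the simplest shape with an
  exponential phase and a plateau.
* **Lipids** — the true composition per condition and phase is a binomial
  profile over rings 0–6 whose mean equals the target ring index (3.65 /
  1.59 / 2.83 at mid-log, 3.93 / 2.08 / 3.67 at early stationary for
  optimal / acid / cold), so targets hold exactly by construction and
  rings 7–8 carry no mass. Samples are Dirichlet draws around the truth
  (concentration 500, giving replicate scatter comparable to the
  observed SEs); a uniform share of GDGT-3/4/5 area — up to 10 % under
  acid stress, up to 2 % otherwise — is split into isomer columns,
  conserving total area.
* **Counts** — negative-binomial (dispersion 0.05, typical of bulk
  RNA-seq; below 1e-8 the sampler switches to Poisson) around log-normal
  gene baselines with ±30 % library-size factors. A DE gene's stress-cell
  mean is scaled by $2^{-\mathrm{log2FC}}$ so the transcript sign
  convention is reproduced end to end; genes shared between stresses
  carry identical effects so planted "common" responses are recoverable
  by the Venn partition.
* **Proteins** — per protein and sample, a shifted-Poisson number of
  spectra (mean 5, ≥ 1), a replicate offset $\sim N(0, 0.25)$, a reported
  value equal to the mean of spectrum-level ratios $\sim N(\cdot, 0.5)$,
  and a within-sample SE whose SD estimate is drawn from the exact
  chi distribution of a sample SD (with a single spectrum, the
  instrument-level SD stands in). The 0.5 / 0.25 log2-unit defaults
  place the Z procedure in a regime where both uncertainty layers
  matter.

What the generator does **not** emulate: raw reads or spectra, gene
length or sequence content, count outliers and batch effects, missing
protein quantifications (missingness must be introduced explicitly, as
the tests do), or correlated lipid measurement error. Passing recovery
tests therefore demonstrates correctness of the estimators under the
stated noise model, not robustness to everything real data can do.

## Calibration results encoded in the test suite

The test suite (and `scripts/acceptance.R`) recomputes, among others:
exactness of `ring_index()` and `bh_adjust()` against brute-force oracles
(1000 random cases each, 1e-12); doubling-time recovery (noiseless < 1 %
relative error; at default noise the median relative error over 100 seeds
is well under 10 %, and the recovered ordering is cold > acid > optimal);
null calibration of both the DEG stand-in and the protein Z procedure
(zero planted effects give essentially zero calls — the Z denominator's
conservatism pushes the realized false-positive rate far below the
nominal level); and protein power.

One power result deserves emphasis because it is easy to misread: the
probability that a protein with a true twofold shift is flagged depends
strongly on how many other true signals share its BH family. Under the
default noise model a twofold shift yields $Z \approx 2.5$; when the
tested contrast's family is essentially all shifted, over 90 % are
flagged, but at 5 % prevalence the BH rank penalty drops per-protein
power to around 10 %. The packaged power experiment therefore plants the
shift in every protein of one stress cell and measures the flagged
fraction there, and users should expect the procedure to be conservative
for rare signals — consistent with it flagging only tens of proteins in
the real design.

## Numerical and degenerate-input choices

* Welch statistics with zero pooled variance: p = 1 when means agree,
  p = 0 with a warning otherwise.
* $Z$ with zero denominator: 0 (warning) when the numerator is zero,
  signed infinity mapped to p = 0 otherwise.
* Window fit on constant series: slope 0 with $r^2$ defined as 1 (the
  flat line is an exact fit).
* BH with `NA` p-values: `NA`s are excluded from the family size and
  returned as `NA`.
* All summary `±` values are standard errors, $\mathrm{sd}/\sqrt{n}$;
  with a single replicate the SE is `NA`, never 0.
* Report JSON segregates its timestamp into a dedicated field so reruns
  with the same seed are content-identical.

## Known limitations

The DE stand-in has no dispersion shrinkage and will be underpowered on
real counts relative to a dedicated count-model tool; the concordance
step matches exact locus tags only; the growth module does not model lag
phase; and the lipid module starts from integrated peak areas —
chromatogram processing, calditol-linked GDGTs and environmental proxy
indices are out of scope.
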