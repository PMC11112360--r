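---
title: "Transcriptomic points of departure: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptomic points of departure: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A point of departure (POD) is the dose marking the onset of adverse effect;
risk assessments traditionally derive it from apical endpoints such as organ
histopathology. A transcriptomic POD (tPOD) instead summarizes genome-wide
dose-response expression into a single dose below which no concerted
transcriptional change is expected. `tpodkit` implements the full chain from
a normalized log2 expression matrix with per-sample doses to a tPOD, by two
routes:

* **gene set-based**: per-probeset benchmark doses (BMDs) are averaged to
  genes, genes are mapped into gene sets (ontologies, pathways,
  co-expression modules), sets are screened by minimum-enrichment criteria,
  and the tPOD is the lowest median gene BMD among passing sets;
* **distribution-based**: the tPOD is read directly off the list of
  probeset BMDs — its 5th or 10th percentile, its 25th-smallest value, the
  first mode of its kernel density on the log10 axis, or the knee of its
  accumulation curve.

The package also implements the two perturbation experiments used to compare
the routes (structure-preserving gene-set randomization and transcriptome
down-sampling) and the concordance metrics (absolute fold change, proportion
of molecules within k-fold, RMSD on the log10 scale, method sensitivity).

# Dose-response models and the benchmark dose

Each dose-responsive probeset is fit by maximum likelihood, assuming normal
errors with constant variance, to eight continuous model families in their
standard continuous benchmark-dose forms:

| family | mean function | mean parameters |
|---|---|---|
| linear | $\beta_0 + \beta_1 d$ | 2 |
| poly2 | $\beta_0 + \beta_1 d + \beta_2 d^2$ | 3 |
| power | $\gamma + \beta d^\delta$, $\delta \ge 1$ | 3 |
| hill | $\gamma + v\, d^n / (k^n + d^n)$ | 4 |
| exp2 | $a e^{s b d}$ | 2 |
| exp3 | $a e^{s (b d)^p}$ | 3 |
| exp4 | $a\,(c - (c-1) e^{-b d})$ | 3 |
| exp5 | $a\,(c - (c-1) e^{-(b d)^p})$ | 4 |

$s = \pm 1$ is the adverse direction, fixed from the observed top-dose
departure before fitting the exponential families; for exp4/exp5 the
direction instead constrains $c$ ($c > 1$ rising, $c < 1$ falling). Because
the variance is constant, the ML fit minimizes the residual sum of squares;
the optimizer is a bounded quasi-Newton capped at 250 iterations, started
from at least five deterministic initializations (method-of-moments guesses
plus fixed perturbations) — a single start under a hard iteration cap is
fragile for the saturating families. The linear and quadratic models are
solved exactly by least squares.

**Selection.** Within the polynomial family the quadratic replaces the
linear model only when the nested likelihood-ratio test has p < 0.05. Hill
fits with half-max dose $k$ below one third of the lowest positive dose are
flagged as extrapolating below the design; the best model is the lowest-AIC
eligible fit (AIC counts the mean parameters plus one for $\sigma$), and a
flagged Hill winner is replaced by the next-lowest-AIC model whose
goodness-of-fit p-value exceeds 0.05. The goodness-of-fit p-value is a
likelihood-ratio test against the saturated group-means model; models with
as many mean parameters as dose groups have no residual degrees of freedom,
their p-value is undefined (NA) and they are treated as not failing the
fit screen. AIC ties break toward fewer parameters, then a fixed model
order — determinism throughout.

**BMD.** The benchmark response (BMR) is one standard deviation of the
control mean; following the constant-variance convention of BMD software,
the default "standard deviation" is the selected fit's modeled $\sigma$
(`control_sd = "modeled"`), with the empirical control-group SD available as
a switch. The BMD solves $|\mu(d) - \mu(0)| = \sigma$ and is found by a
log-spaced grid scan refined by root bisection, so non-monotone quadratics
return their first crossing; curves that never depart from control by one
BMR at or below the top dose return an infinite-BMD sentinel and are
dropped.

**Confidence limits.** BMDL and BMDU are profile-likelihood limits. Every
family has one amplitude-like parameter that the BMR constraint determines
in closed form given the BMD, $\sigma$ and the other parameters, so the
profile at a fixed BMD is a bounded optimization over the remaining
parameters with $\sigma$ profiled jointly (the 1-SD BMR ties amplitude to
the current $\sigma$, so conditioning on $\hat\sigma$ would be
inconsistent). Each one-sided 95% bound uses the $\chi^2_1$ cutoff 2.706;
the search walks geometrically from the BMD with warm starts and bisects
the crossing. Records with BMD above the highest tested dose or with
BMDU/BMDL > 40 are removed.

# The prefilter

Probesets enter BMD modeling only if they pass, conjunctively, a Williams
trend test (p < 0.05) and an absolute fold-change screen (> 1.5 on the
linear scale, i.e. > 0.585 log2 units between some treated group mean and
control). The Williams statistic compares the isotonic (pool-adjacent-
violators) amalgamated mean of the highest dose group against control; the
amalgamated top-group mean equals the maximum over suffix-weighted means of
the treated groups, which makes the statistic cheap and exactly
vectorizable. Two-sidedness takes the larger of the increasing- and
decreasing-direction statistics. P-values are Monte-Carlo permutation tail
probabilities with the +1 correction — permutation handles unbalanced
designs, matches practice in genomic dose-response software, and is
testable against exhaustive enumeration on small designs. Zero-variance
probesets (possible in noiseless fixtures) raise a classed condition; the
prefilter treats them as passing when the group means differ and failing
otherwise. No multiple-testing correction is applied at this stage, by
design.

# Distribution-based estimators

All five operate on the probeset BMD list of one molecule and return
nothing when fewer than 25 BMD values are available (the published minimum
for these methods; Rank25 additionally cannot exist below 25 values).

* **Perc05 / Perc10** — interpolated percentiles, using the linear
  interpolation convention of mainstream statistical environments (R type
  7). The convention is pinned by oracle tests.
* **Rank25** — the 25th-smallest BMD, duplicates counted.
* **FirstMode** — Gaussian KDE of log10(BMD) with bandwidth
  max(Sheather–Jones, 0.015 log10 mg/kg/d), evaluated on a 512-point grid
  spanning the data range plus three bandwidths; modes are local maxima
  with density at least 0.055, and the tPOD is the lowest-dose qualifying
  mode. The 0.055 threshold is interpreted as an absolute height on the
  log10-dose axis (densities integrate to 1 there); a relative-to-peak
  variant is selectable because the published description does not resolve
  the ambiguity. Sheather–Jones failures (near-constant data) fall back to
  the minimum bandwidth.
* **PODAcc** — the accumulation curve (sorted log10 BMDs versus cumulative
  fraction) is min-max normalized on both axes, interpolated onto a uniform
  512-point grid, lightly smoothed (moving average, window = grid/64 —
  without smoothing, sampling noise in the empirical curve fires spurious
  early knees), and scanned by the Kneedle rule: local maxima of the
  difference between the curve and the diagonal, accepted when the
  difference later drops by more than sensitivity × grid spacing. The
  orientation is adaptive — whichever side of the diagonal the curve
  departs farthest toward carries the knee — so flat-then-steep and
  steep-then-flat shapes both resolve to the dominant bend. A near-straight
  curve (maximum departure below sensitivity × spacing) has no knee; all
  BMDs equal returns the common value. Sensitivity defaults to 1, the value
  of the published algorithm.

All five are equivariant under rescaling doses by a positive constant;
FirstMode only up to its density-grid quantization.

# Gene set-based tPOD

Probesets mapping to more than one gene are excluded; the remaining
probesets' BMDs are averaged per gene (arithmetic mean, linear scale). A
gene set's size is the number of its genes exposed by the platform's probe
map — so the percentage criterion's denominator shrinks on reduced
platforms. A set passes filter F = (min genes, min %) when at least
`min_genes_with_bmd` of its platform genes have a BMD and those genes are at
least `min_pct_with_bmd` percent of its platform genes. The tPOD is the
lowest per-set median (default; mean selectable) of gene BMDs among passing
sets. The shipped stringency ladder F1–F11 fixes F3 at the recommended
(3 genes, 5%) and fills the other rungs with defaults that increase in both
fields — published sources print only F3, so the remaining rungs are
package defaults, user-overridable, preserving the monotone-stringency
sweep (passing sets under a stricter rung are always a subset).

# Perturbation experiments

**Randomized gene sets.** `randomize_structure()` replicates a structure
exactly — set count and per-set sizes — with random membership. In overlap
mode each set is drawn independently (a gene can join several sets, as in
ontology structures); no-overlap mode draws without replacement so each
gene occurs at most once (for co-expression-module structures). The
sampling universe defaults to the union of genes in the original structure,
which preserves its coverage statistics; the full platform is selectable
since the published description leaves the universe open.
`run_randomization_study()` repeats the enrichment step over randomized
structures, reports a molecule only when at least half the simulations
return a tPOD, aggregates by the median over successful simulations, and
reports the fold change original/median.

**Down-sampling.** `downsample_probesets()` retains a random fraction
(scenarios at 60% and 11.3%) or a fixed keep-list (e.g., ~3k sentinel-gene
probesets). Reduction restricts the existing per-probeset BMD records
rather than refitting: per-probeset statistics are independent across
probesets, so restriction is exactly equivalent to rerunning the trend test
and BMD modeling on the reduced matrix, at a fraction of the cost. The
gene-set route also shrinks the platform denominator to the retained
probesets ("keep only the probesets and, consequently, genes present in the
down-sampled set"). Keep-list scenarios are deterministic and run once.
Seeds: one master seed spawns per-simulation child seeds.

# The synthetic-data generator

`simulate_study()` emulates a multi-dose toxicogenomics study: a control
group plus treated dose levels, a minority-to-majority mix of responsive
and flat probesets, Gaussian log2-scale noise, baselines uniform on 6–12
log2 units. Responsive mean curves are drawn from the same eight model
families the pipeline fits, so model selection is exercised against
in-family truth, and each curve is calibrated so it crosses the 1-SD
benchmark response (with the configured `noise_sd` as that SD) exactly at
the probeset's true BMD:

* six families (hill, power, linear, poly2, exp4, exp5) separate baseline
  from amplitude; their curve is baseline + effect × f(d) with f the unit
  shape, and the shape parameter is solved so f(true BMD)/f(top dose) =
  noise_sd/effect;
* exp2 and exp3 couple amplitude to baseline ($\mu(0) = a$), so exp2's
  effect size is implied by (baseline, BMD) and exp3 solves its exponent
  for the requested effect — draws a family cannot realize are redrawn,
  trimming only a vanishing sliver off the log-uniform BMD distribution.

True BMDs are sampled log-uniformly within `true_bmd_range`, directions
50/50 up/down, top-dose effect sizes uniform within `effect_size_range`
(default 1–2.5 log2 units).

**Default design.** The default dose grid is a seven-level half-log series
(0, 3, 10, 30, 100, 300, 1000 mg/kg/d) with five replicates and noise SD
0.1. Grid density is the binding constraint on BMD recovery: with only two
or three treated levels spaced a decade apart, the 1-SD crossing falls
between doses and no estimator — not even one fitting the true generating
family with known form — can locate it to better than about two-fold. The
half-log design makes the crossing identifiable, and is the standard
recommendation for benchmark-dose estimation studies. The reference
("standard") study for parameter-recovery checks uses 500 probesets, 300
responsive, seed-fixed.

What the generator does **not** emulate: probe-level microarray artifacts,
normalization effects, batch structure, correlated noise across probesets,
or the clustering of real molecules' BMDs around a characteristic potency
(true BMDs are log-uniform by design). Passing tests therefore demonstrate
algorithmic correctness and statistical calibration under idealized noise,
not robustness to array artifacts. One practical consequence: a flat
log-uniform BMD distribution has no pronounced mode or knee, so FirstMode
and PODAcc estimates on it carry more sampling variability than on real
molecules; aggregated comparisons (original versus the median over
simulations) are the stable quantity, and they are what the reduction and
randomization studies report.

`simulate_structure()` and `simulate_probe_map()` generate gene-set
structures with configurable set count, set-size distribution,
overlap/disjoint membership, and a controllable share of ambiguous
(multi-gene) probesets.

# Numerical and design notes

* Doses are exact design values; group membership is exact equality after
  parsing, with no tolerance clustering.
* Gene and probeset identifiers are opaque strings; no identifier-namespace
  validation is attempted.
* Fold-change thresholds are strict inequalities (`> 1.5`, `abs fc < k`);
  ties at exactly k can be counted as within via a documented toggle, since
  printed proportions cannot disambiguate the convention.
* Concordance metrics are computed only over molecules where both methods
  report; sensitivity counts every molecule. `n_common` is reported with
  every metric.
* The molecule-count bins used for grouped comparisons are <150, 150–300
  (left-closed), and ≥300 probesets with a BMD.
* Scaled-down defaults: the test suite and the acceptance script run
  100-replicate perturbation studies and studies of 500–1200 probesets;
  the 1,000-replicate protocol of full runs is the function default
  (`n_sims = 1000`).
* The location families (linear, poly2, power, hill) are invariant to
  adding a constant to all responses; the exponential families are
  multiplicative in the response and are not — an intrinsic property of
  their functional forms, reflected in the tests.

# Known limitations

* Non-constant variance, model averaging and Bayesian BMD estimation are
  out of scope.
* The Williams permutation p-value has Monte-Carlo granularity
  1/(n_permutations + 1); counts reproduced against tabulated-critical-value
  implementations may shift slightly near the threshold.
* Profile-likelihood bounds assume a unimodal profile; pathological
  multimodal profiles would be bracketed conservatively.
* The exact parameter values of enrichment filters other than F3, and the
  exact randomization universe, are package choices exposed as arguments.
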