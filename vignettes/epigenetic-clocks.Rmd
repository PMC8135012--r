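---
title: "Epigenetic clocks and the aging EWAS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epigenetic clocks and the aging EWAS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiclock)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design decisions taken where the design was genuinely open.

## The clock model

A methylation clock is a sparse linear predictor of age from CpG beta
values. `train_clock()` fits

$$ T(\mathrm{age}_i) = \beta_0 + \sum_j \beta_j x_{ij} + \varepsilon_i $$

with the elastic-net penalty $\lambda\,[\alpha\|\beta\|_1 +
(1-\alpha)\|\beta\|_2^2/2]$ via `glmnet`. Assumptions worth keeping in
mind:

* **Linearity on the transformed-age scale.** Methylation change is modeled
  as linear in $T(\mathrm{age})$. Real trajectories are often logistic-like
  near the beta bounds; over the within-study age ranges linearity is the
  standard working approximation, and the clock literature's near-perfect
  in-range correlations show it is a serviceable one.
* **Completeness.** Beta matrices must be complete. How missing betas should
  be handled is an open question in general; this package takes the
  position that imputation belongs upstream and refuses missing cells
  rather than guessing.
* **Sparsity.** Elastic net with $\alpha = 0.5$ (the convention for
  methylation clocks: enough L1 for sparsity, enough L2 to keep groups of
  correlated CpGs) yields tens of active probes out of thousands.

Penalty strength is chosen by internal 10-fold cross-validation at the
**minimum** mean squared error, not the 1-SE rule: the goal of a clock is
predictive accuracy, not a minimal probe set. Both $\alpha$ and the fold
count are arguments. Predictors are standardized internally by `glmnet`;
coefficients are reported on the original beta scale so a stored clock is a
plain linear formula.

### Age transforms

Three transforms link chronological age to the regression response
(`age_transform()`):

* **identity** — response in years; the default for within-species clocks.
* **relative** — age divided by the species' maximum lifespan (cattle 38 y,
  human 122.5 y), a value in (0, 1]. Two species with very different
  lifespans share one regression only if the response means the same thing
  in both; relative age is that common currency, and it is why a joint
  cattle–human clock can be accurate in each species while a years-trained
  joint clock is systematically biased in the shorter-lived one.
* **loglinear** — $\log(\mathrm{age} + \mathrm{offset})$ below a maturity
  knot, continued linearly with matched value and slope above it.
  Juvenile methylomes change fastest, and a compressive transform for young
  ages is common in the clock literature. The exact form used elsewhere
  varies and is often unpublished; the implementation here (offset and knot
  as explicit parameters, default offset 1 y, knot 5 y) is a documented
  choice, **off by default**, provided for users who want the option rather
  than as a claim about any particular published clock.

All transforms are strictly increasing and invert exactly (checked to
1e-10 in the tests). Back-transformed predictions are **not clipped** to
[0, lifespan]: an impossible DNAm age is a calibration signal the user
should see, so it is reported as-is with a warning.

### Cross-validation and its fine print

`loo_estimates()` reruns the *entire* training procedure — including
penalty selection — without each sample. Whether published LOO clock
curves re-selected the penalty inside the loop is usually unstated; always
re-selecting is the conservative choice (no information about the held-out
sample leaks through $\lambda$) and is what this package does.

`kfold_estimates()` stratifies folds by species × tissue and balances fold
sizes to within one sample; `group_by_donor = TRUE` keeps isogenic samples
in one fold, which is mandatory when donors contribute to both tissues.
Internal CV folds are drawn in canonical (sorted sample id) order so
results do not depend on the column order of the input matrix.

One artifact deserves a note because it surprises people: under a
**permutation null** (ages shuffled), a correctly shrunk clock collapses
toward the intercept, i.e. each leave-one-out prediction approaches the
mean age of the *training* fold — which is exactly anti-correlated with the
held-out age. LOO r under the null is therefore biased toward −1, not 0.
The meaningful null check, used in the tests, is the absence of *positive*
out-of-sample correlation together with uninformative error magnitudes.

### Age acceleration

`age_acceleration()` defines acceleration as the residual of
cross-validated DNAm age regressed (OLS) on chronological age **within
tissue**, not as DNAm age minus age. Clocks are differently calibrated per
tissue (slope and intercept), and the raw difference confounds calibration
with biology; the residual is orthogonal to age by construction, making the
blood-vs-oocyte comparison in `acceleration_correlation()` a comparison of
deviations, not calibrations. Resubstitution estimates must never be used
here: they shrink residuals toward zero and fake concordance.

## The EWAS block

`correlation_screen()` computes, per probe within one tissue, Pearson r
against age in years, $t = r\sqrt{n-2}/\sqrt{1-r^2}$, the two-sided
Student p, and the signed normal equivalent
$Z = \mathrm{sign}(r)\,\Phi^{-1}(1-p/2)$ — the screening convention of the
WGCNA tradition. The screen uses **untransformed age** within a tissue:
within one species the transform is monotone-linear and the screening
question is association with chronological age.

Numerical choices: p-values are floored at 1e-300, capping |Z| near 37.04
(`qnorm(5e-301, lower.tail = FALSE)`) so machine-precision correlations do
not produce infinite Z; constant probes get `NA` statistics, a reported
count, and exclusion from selection; the selection tie-break at equal |Z|
is lexicographic in probe id, so selections are bit-reproducible.

`stouffer_meta()` combines tissues as $(w_1 Z_1 + w_2 Z_2)/\sqrt{w_1^2 +
w_2^2}$. Weights default to **equal**: with two tissues of similar
information content the symmetric $(Z_1+Z_2)/\sqrt2$ form is the natural
default, and $\sqrt{n}$ weighting is available by argument for unbalanced
designs. Selection uses the fixed p < 10⁻⁴ threshold with at most 500
probes per direction of change ranked by |Z|; no multiple-testing
correction beyond that fixed threshold is applied to selection (a BH-FDR
column can be added by the user from the p column; faithfulness to the
fixed-threshold screening convention comes first).

`feature_enrichment()` keeps the 2×2 machinery fully general: the caller
chooses the selected set, the background and the feature. The default
background in the pipeline is *all probes with defined statistics in the
tissue*; published enrichment figures rarely state their background, and
rather than guess, the package makes the choice explicit and configurable.
The hypergeometric p is exact (upper tail, `phyper`), never a normal
approximation; a degenerate table with $bc = 0$ reports an infinite odds
ratio with a flag rather than failing.

Divergence classification (`classify_divergent()`) requires per-tissue
significance (p < 10⁻⁴ in *both* tissues) with opposite Z signs. Whether a
meta-analysis threshold or per-tissue thresholds define divergence is a
genuinely open choice; per-tissue thresholds are used because divergence is
a statement about each tissue individually, and a meta statistic of two
opposed effects is biased toward zero precisely for the probes of interest.

## The synthetic-data generator

`simulate_methylation()` draws
$\beta = \mathrm{baseline}_{\mathrm{tissue}} + \mathrm{slope}_{\mathrm{tissue}}
\cdot T(\mathrm{age}) + \varepsilon$, $\varepsilon \sim N(0, \sigma)$,
clipped to [0, 1]. It emulates, by construction:

* **disjoint age-related CpG sets** per tissue (`blood_up`, `blood_down`,
  `oocyte_up`, `oocyte_down`), plus small `shared` and `divergent` classes
  so the transfer-failure and divergence analyses have something to find;
* **lower non-island baseline methylation in oocytes** than blood
  (defaults: non-island baselines uniform on [0.25, 0.6] vs [0.5, 0.85];
  islands uniform on [0.05, 0.25] in both tissues);
* a **second species** (human blood) sharing the aging signal on the
  relative-age scale, which is exactly the condition a relative-age clock
  exploits;
* a promoter-enriched `blood_up` class (60% promoter vs 15% background) so
  region enrichment is exercisable, on a toy genome layout (5 chromosomes,
  genes in blocks of 8 probes) that is internally consistent with the
  −10 kb..+1 kb promoter window.

Default sizes are desk-scale: 2,000 probes, 60 cattle blood + 40 cattle
oocyte samples aged uniformly on 0.5–13.3 y, optionally 60 human blood
samples aged 1–100 y — mirroring the 277/80/852 composition of the
motivating cohorts at roughly 1/18 scale. Noise is additive Gaussian with
$\sigma = 0.02$ on the beta scale; a logit-scale option exists for users
who want bound-respecting noise. Slope magnitudes default to 0.01–0.03
beta/year (identity scale) or 0.25–0.75 beta per relative-age unit; these
effect sizes are **chosen for testability, not estimated from any
dataset** — published EWAS report statistics, not effect-size
distributions. Baselines are shifted (never the slopes) to keep noiseless
trajectories inside [0.02, 0.98], so clipping affects well under 1% of
entries under defaults and the per-probe OLS slope recovers the truth slope
exactly when $\sigma = 0$.

`simulate_isogenic_pairs()` adds a latent per-donor age-acceleration offset
(SD 1.5 y) to the age that *drives the signal* but not to the recorded age,
with configurable cross-tissue correlation ρ. This is the minimal mechanism
that makes the acceleration-correlation question testable: at ρ = 0 the
paired test's p-values are uniform (checked by Monte Carlo), at ρ = 0.9 it
detects the correlation with power ≥ 0.9 at 40 donors.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real arrays: probe-level measurement error that
depends on intensity, cell-composition heterogeneity within a tissue,
batch and chip effects, spatial correlation of probes along the genome,
non-linear (saturating) age trajectories, and realistic genome annotation.
Tests against this generator establish that the *statistical machinery* is
correct and calibrated, not that any particular biological effect size will
be observed in real data.

A `truth` table can be passed back into the generator to redraw samples on
a **fixed array** (same probe classes, slopes, baselines, annotation) —
the natural way to simulate independent cohorts measured on one platform,
and what the Monte-Carlo calibration tests do.

## Reproducibility and problem sizes

Every stochastic entry point takes a seed, and fixed seeds give
bit-identical simulations, folds and clock files. Clock files are a JSON
header plus a probe/weight TSV at full double precision; serialization
round-trips preserve predictions to 1e-12.

The test-suite and acceptance-script problem sizes — 2,000 probes with
up to 160 samples for clock recovery, 100,000 probes × 60 samples for null
calibration, 200 + 100 Monte-Carlo repeats for acceleration calibration and
power — were chosen as the smallest sizes at which the assessed properties
(correlation bounds, binomial calibration intervals, power) are stable
across seeds; they run in a few minutes on one CPU.

## Known limitations

* The package consumes beta matrices as given: no normalization, no IDAT
  parsing, no probe QC, no detection p-values.
* Clocks are linear in betas; no interactions or tissue-specific slopes are
  fitted (a dual-tissue clock relies on probes informative in both
  tissues).
* The EWAS screen is a marginal correlation per probe; no covariates
  (sex, batch, cell composition) are adjusted for.
* Gene-neighborhood queries reconstruct a TSS from the annotation's signed
  distances and assume one TSS per gene symbol.
* With two tissues, Stouffer combination is the whole meta-analysis; no
  heterogeneity statistic is computed.
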