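# epiclock

Epigenetic clocks and an aging EWAS for cross-tissue and cross-species DNA
methylation data.

DNA methylation at a modest number of CpG sites predicts chronological age
with remarkable accuracy in essentially every mammalian tissue examined.
`epiclock` is for researchers who work with methylation-array beta values
(CpG × sample matrices of methylation fractions in [0, 1]) and want to

* train **epigenetic clocks** — sparse elastic-net predictors of age —
  for a single tissue, for several tissues jointly, or for two species
  jointly on the **relative-age** scale;
* obtain honest **cross-validated DNAm-age estimates** (leave-one-sample-out
  or stratified k-fold) and **age acceleration**, and compare acceleration
  between isogenic tissues (e.g. blood and oocytes from the same animal);
* run a per-CpG **aging EWAS** per tissue, combine tissues by **Stouffer
  meta-analysis**, select and classify top CpGs (including divergent CpGs
  that age in opposite directions in two tissues), and test annotation
  enrichment (promoters, CpG islands) with exact hypergeometric statistics.

Because consortium-scale mammalian-array data are not freely downloadable,
the package includes a **synthetic-data generator** that emulates the
relevant structure — two tissues with disjoint and divergent age-related CpG
sets, lower non-island baseline methylation in oocytes than blood, and a
second species sharing signal on the relative-age scale — together with a
ground-truth table, so every stage of the analysis is testable end to end.

## The model

A clock is a penalized linear model of transformed age on probe betas
x ∈ [0,1]^p:

    T(age) ≈ β₀ + Σⱼ βⱼ xⱼ ,   with penalty  λ [ α‖β‖₁ + (1−α)‖β‖₂²/2 ]

fitted by `glmnet` with α = 0.5 by default and λ chosen by internal 10-fold
cross-validation at minimum squared error. The age transform `T` is the
identity (years) for within-species clocks or **relative age**
`T(age) = age / max_lifespan` (cattle 38 y, human 122.5 y) for dual-species
clocks; predictions are back-transformed to years.

The EWAS screen computes, per probe and tissue, the Pearson correlation `r`
with age, `t = r√(n−2)/√(1−r²)`, its two-sided p-value, and the signed
normal-equivalent `Z = sign(r)·Φ⁻¹(1−p/2)`. Tissues are combined as
`Z_meta = (Z₁+Z₂)/√2` (Stouffer, equal weights; √n weighting optional).
Top CpGs are those with p < 10⁻⁴, capped at 500 per direction of change by
|Z|. Enrichment of a selected set against its background for a binary
annotation feature uses the 2×2 odds ratio `ad/bc` and the upper-tail
hypergeometric probability.

Age acceleration is the residual of cross-validated DNAm age regressed on
chronological age within tissue, which removes tissue-specific calibration
and makes accelerations comparable across tissues.

## Worked example

```r
library(epiclock)
cfg <- sim_config(seed = 42)   # 2,000 probes; 60 cattle blood + 40 oocytes
d <- simulate_methylation(cfg)

clock <- train_clock(d$betas, d$samples, seed = 42)
clock
#> Epigenetic clock (elastic net, alpha = 0.5 )
#>   transform: identity
#>   probes with nonzero weight: 36
#>   penalty lambda: 0.07736
#>   trained on 100 samples (blood/oocyte; cattle)

est <- kfold_estimates(d$betas, d$samples, k = 10, seed = 42)
evaluate_clock(est, by = "tissue")
#>    group  n pearson_r       mae
#> 1  blood 60 0.9985289 0.1537851
#> 2 oocyte 40 0.9971296 0.1711306
```

The clock used 36 of 2,000 probes and, on 10-fold cross-validated
estimates, predicts age with r ≈ 0.998 and a median absolute error of
about 0.15–0.17 years in both tissues — the synthetic aging signal is
strong and the penalty selection recovers it almost perfectly.

```r
ewb <- correlation_screen(d$betas, d$samples, tissue = "blood")
ewo <- correlation_screen(d$betas, d$samples, tissue = "oocyte")
sel <- select_top_cpgs(ewb)
length(sel$hyper); length(sel$hypo)
#> [1] 128
#> [1] 132
cross_tissue_z_correlation(ewb, ewo)
#> [1] 0.085

bg <- ewb$probe_id[!is.na(ewb$r)]
prom <- d$annotation$probe_id[d$annotation$region_class == "promoter"]
feature_enrichment(intersect(sel$hyper, bg), bg, prom)
#> 2x2 enrichment: a = 67  b = 61  c = 327  d = 1545
#> odds ratio = 5.19 ; hypergeometric p = 1.1e-17
```

The blood screen finds 128 hyper- and 132 hypomethylating CpGs at
p < 10⁻⁴; the near-zero correlation of blood and oocyte Z statistics
reflects the largely disjoint aging CpG sets of the two tissues, and the
hypermethylating blood CpGs are strongly enriched in promoters (odds ratio
5.2), both structures the generator builds in and the analysis recovers.

`run_pipeline(pipeline_config())` chains all stages — simulation, the clock
panel with cross-validation, the isogenic acceleration comparison, and the
EWAS/meta/enrichment block — and returns (optionally writes) a
machine-readable summary.

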