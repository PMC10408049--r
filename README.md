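# cismr

Two-sample *cis*-Mendelian randomization with correlated genetic
instruments.

`cismr` is for analysts who want to estimate the causal effect of a
molecular exposure on disease outcomes using instruments drawn from one
or two gene regions — the drug-target MR setting. Its motivating
application is plasma caffeine, instrumented by variants around
*CYP1A2* and *AHR* (the genes governing caffeine clearance), with
binary neuropsychiatric outcomes from large case-control GWAS cohorts.
Because cis instruments are few and correlated through linkage
disequilibrium (LD), the package centres on the estimators and
diagnostics that remain valid under correlation.

## The method

For variant *j*, let γ̂ⱼ (SE σ_Xj) be its association with the exposure
(SD units) and Γ̂ⱼ (SE σ_Yj) its log-odds association with the outcome.
Each variant gives a Wald ratio θ̂ⱼ = Γ̂ⱼ/γ̂ⱼ with first-order SE
σ_Yj/|γ̂ⱼ|. With signed LD correlations r and
Ω = diag(σ_Y) · r · diag(σ_Y), the pooled slope is the GLS regression
through the origin

    β̂  = (γ̂ᵀ Ω⁻¹ γ̂)⁻¹ γ̂ᵀ Ω⁻¹ Γ̂
    se  = sqrt( φ · (γ̂ᵀ Ω⁻¹ γ̂)⁻¹ ),   φ = max(1, Q/(J−1))

where Q is the residual heterogeneity of the J instruments — a
multiplicative random-effects inflation that can widen but never
narrow the interval. exp(β̂) is the odds ratio per SD of exposure.

Around that core the package provides the complete pipeline:

- gene-region instrument selection (`select_region_snps`, default
  threshold 5×10⁻⁵ ≈ a Bonferroni correction for ~10³ region variants),
  greedy LD clumping (`clump`, default r² = 0.3), and FIQT
  winner's-curse correction (`fiqt_adjust`);
- allele harmonization with palindrome handling and an exclusion log
  (`harmonize`);
- per-variant fixed-effect meta-analysis across outcome cohorts
  (`fixed_effect_meta`), Cochran's Q / I² (`cochran_q`), and
  DerSimonian–Laird pooling of cohort-level estimates
  (`random_effects_meta`);
- the correlated-variant IVW estimator (`correlated_ivw`) with
  leave-one-out, per-gene, and lead-variant sensitivity analyses;
- Benjamini–Hochberg FDR control across outcomes, odds-ratio
  conversion, and deterministic TSV/JSON serialization
  (`run_pipeline`, `write_results`);
- a seeded synthetic summary-statistics generator with known truth and
  a calibration harness (`simulate_region`, `recovery_experiment`), so
  every stage is testable offline.

## Worked example

Simulate a caffeine-style study (two cis regions, 25 variants each,
seven causal signals, exposure n = 10,000, one outcome cohort of
300,000 with a true slope of 0.1 log-odds per SD) and run the full
pipeline:

```r
library(cismr)

cfg <- sim_config()                       # reference study conditions
sim <- simulate_region(cfg, seed = 42)
bundle <- run_pipeline(sim$exposure, sim$outcomes, sim$ld,
                       regions = cfg$regions, seed = 42)
print(bundle)
#> cis-MR result bundle: 1 outcome(s), 7 instrument(s), mean F = 55.9
#> disorder: OR per SD = 1.067 [0.969, 1.174], p = 0.187, p_FDR = 0.187 (7 variants)

print(bundle$strength)
#> Instrument strength (decorrelated): mean F = 55.9 over 7 variants
#>   approximate relative weak-instrument bias: 1.8%

print(bundle$outcomes$disorder$per_gene$het)
#> Cochran's Q = 0.367 on 1 df (p = 0.545), I^2 = 0%
```

Selection retained 7 quasi-independent instruments across the two
regions. The odds ratio 1.067 per SD is this replicate's estimate of
the true exp(0.1) ≈ 1.105; its 95% interval [0.969, 1.174] covers the
truth (a single replicate at these sample sizes has limited power —
`recovery_experiment()` quantifies this over many replicates). The
decorrelated mean F of 56 indicates strong instruments (≈ 2% expected
weak-instrument bias), and the between-gene I² of 0% shows the two
regions imply concordant slopes, as they must here since the generator
used a single causal slope.

`write_results(bundle, "results/")` serializes the estimates,
leave-one-out series, heterogeneity table, instrument table, exclusion
log, and run metadata as stable TSV/JSON files.

For a real-data run, fill in the file paths in the config template at
`inst/extdata/full_run_config.yaml` (exposure and outcome summary
statistics plus a reference-panel LD matrix over the instrument
variants) and call
`run_pipeline_file("full_run_config.yaml", out_dir = "results")`,
or use the CLI wrapper `inst/cli/cismr.R` (subcommands `select`, `mr`,
`simulate`, `report`).

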