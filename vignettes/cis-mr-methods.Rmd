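---
title: "Cis-Mendelian randomization with correlated instruments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cis-Mendelian randomization with correlated instruments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismr)
```

## The scientific problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to probe whether an exposure causally affects an outcome.
`cismr` implements the *cis* (drug-target style) flavour of two-sample
MR: instruments are restricted to variants in or near one or two genes
with an established biological link to the exposure. The motivating
application is plasma caffeine, instrumented by variants around
*CYP1A2* (the enzyme responsible for most caffeine clearance) and *AHR*
(its transcriptional regulator), with binary neuropsychiatric outcomes
measured in large case-control GWAS cohorts. Restricting instruments to
a known metabolic pathway reduces the risk of pleiotropy, but the price
is that the instruments are few and mutually correlated through linkage
disequilibrium (LD), which changes the estimator, the diagnostics, and
which sensitivity analyses are even well defined.

The package covers the full chain: summary-statistics input and allele
harmonization, gene-region selection, LD clumping, winner's-curse
correction, cross-cohort meta-analysis, the correlated-variant IVW
estimator with multiplicative overdispersion, heterogeneity and
leave-one-out sensitivity analyses, FDR control, and a synthetic-data
generator that makes the whole chain testable without any external
download.

## Model and estimator

For variant $j$, let $\hat\gamma_j$ (SE $\sigma_{X j}$) be its
association with the exposure in SD units, and $\hat\Gamma_j$ (SE
$\sigma_{Y j}$) its log-odds association with the outcome. Under the
instrumental-variable assumptions every valid instrument satisfies
$\Gamma_j = \beta\,\gamma_j$ for a single causal slope $\beta$
(log-odds per SD). The single-variant estimate is the Wald ratio
$\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order standard
error $\sigma_{Y j}/|\hat\gamma_j|$.

With correlated instruments the Wald ratios are pooled by generalized
least squares regression of $\hat\Gamma$ on $\hat\gamma$ through the
origin. Let $r_{jk}$ be the signed LD correlation and
$\Omega_{jk} = \sigma_{Y j}\sigma_{Y k} r_{jk}$. Then

$$\hat\beta = \left(\hat\gamma^\top \Omega^{-1} \hat\gamma\right)^{-1}
  \hat\gamma^\top \Omega^{-1} \hat\Gamma,
\qquad
\operatorname{se}(\hat\beta) = \sqrt{\phi\,
  \left(\hat\gamma^\top \Omega^{-1} \hat\gamma\right)^{-1}},$$

where the multiplicative random-effects factor
$\phi = \max\!\left(1, Q/(J-1)\right)$ with residual heterogeneity
$Q = (\hat\Gamma - \hat\beta\hat\gamma)^\top \Omega^{-1}
(\hat\Gamma - \hat\beta\hat\gamma)$ absorbs residual dispersion across
instruments: it can widen, never narrow, the interval and leaves the
point estimate untouched. With $J = 1$ the estimator reduces exactly to
the Wald ratio, and with $r = I$ to the standard first-order IVW.
Intervals and p-values use the normal reference distribution. Key
assumptions: first-order weights (exposure uncertainty enters the
F-statistic diagnostics, not the weighting), a signed LD matrix aligned
to the harmonized effect alleles, and instruments acting through the
exposure only.

Standard pleiotropy-robust estimators (MR-Egger, weighted
median/mode) presuppose independent instruments and are deliberately
absent. The sensitivity analyses that do survive correlation are
implemented instead: leave-one-out re-estimation, separate per-gene
estimates with Cochran's Q across regions, between-cohort heterogeneity
with a DerSimonian–Laird random-effects pool, and a lead-variant-only
analysis (one variant per gene, essentially uncorrelated across
chromosomes).

## The selection stage

*Region filter.* Variants are kept when they lie within a flanked gene
region (1-based inclusive bounds, GRCh37; defaults are the *CYP1A2* and
*AHR* coordinates with 100 kb flanks) and pass the association
threshold `p_threshold`. The default `5e-5` corresponds to a
region-wide Bonferroni correction: with on the order of a thousand
variants measured across the two regions, $0.05/955 \approx 5.2\times
10^{-5}$ (`bonferroni_threshold(955)`).

*Clumping.* Greedy by ascending p-value (rsid as a deterministic
tie-break): the most significant remaining variant is kept and every
remaining variant with $r^2 >$ `clump_r2` (default 0.3) within
`clump_window_kb` (default 10,000 kb) of it is removed. The algorithm
is the field's de facto standard; the thresholds are the tunable part.
Variants on different chromosomes never exclude one another.

*Winner's curse.* Effects of variants selected for significance are
biased away from zero. The FDR inverse quantile transformation (FIQT)
shrinks them: Benjamini–Hochberg-adjust the two-sided p-values using
`m_total` tests (defaulting to the count of region variants before
thresholding, the natural family), then map back,
$z^{adj} = \operatorname{sign}(z)\,\Phi^{-1}(1 - p^{adj}/2)$ and
$\beta^{adj} = z^{adj}\sigma$. This is a shrinkage by construction
($|\beta^{adj}| \le |\beta|$); when $p^{adj} \ge 1$ the adjusted effect
is set to 0 with a warning. Numerically the inverse normal is evaluated
in its upper-tail form, which stays accurate where $1 - p/2$ would
round to 1 in double precision.

*Instrument strength.* The mean F statistic is computed as the
decorrelated mean chi-square $(z^\top r^{-1} z)/J$; with independent
instruments this is the plain mean of $z_j^2$, which is also available
(`method = "plain"`) since the LD-adjusted convention is not
standardized across the literature. $1/\bar F$ approximates the
relative weak-instrument bias of the IVW estimate — $\bar F$ between 25
and 50 corresponds to roughly 2–4% bias.

## Harmonization and meta-analysis

Outcome records are aligned to the exposure's effect allele: identical
orientation passes through, swapped alleles flip the outcome beta and
complement its frequency, and any other pair is excluded as an allele
mismatch. Palindromic variants (A/T, C/G) are indistinguishable from a
strand flip by alleles alone, so they are retained only when both
effect-allele frequencies are informative — outside $0.5 \pm$
`eaf_band` — and concordant after alignment. The band defaults to
0.08, a deliberately conservative common-practice value; it is a
parameter because no single convention exists. A palindromic variant
with a missing frequency is excluded. Every input variant is either
retained or logged with a reason, and harmonization is idempotent.

When an outcome is measured in two cohorts (e.g. a consortium GWAS and
an independent biobank), the per-variant associations are combined by
fixed-effect inverse-variance meta-analysis before estimation; a
variant covered by only one cohort passes through unpooled, so cohorts
with different variant coverage are handled naturally. Cohort-level
*MR estimates* are additionally compared by Cochran's Q / $I^2$ and
pooled by DerSimonian–Laird additive random effects, the appropriate
level at which to allow between-source heterogeneity.

Across the outcomes of one run, primary p-values are
Benjamini–Hochberg-adjusted; the FDR family is the set of primary
outcome analyses only — sensitivity analyses are never part of the
family. Estimates are reported on both the log-odds and odds-ratio (per
SD of exposure) scales; TSVs round OR columns to 3 decimals, while
`run.json` keeps full precision.

## The synthetic-data generator

`simulate_region()` draws summary statistics directly at the summary
level — no individual genotypes — which matches exactly the two-sample
summary-data regime the estimators assume and keeps a replicate cheap.
Within each region the signed LD is AR(1), $r_{jk} = \rho^{|j-k|}$;
regions are uncorrelated blocks. A sparse vector of causal effects
$\gamma_c$ (SD per allele) is propagated into the marginal effects a
GWAS measures as $\gamma = R\,\gamma_c$, so selection and clumping see
realistic LD-smeared association signals. Sampling noise is
multivariate normal with covariance $D\,R\,D$, where $D$ carries the
standard GWAS standard errors $1/\sqrt{2 n f_j (1-f_j)}$ for the
continuous exposure and the effective-sample-size approximation
$1/\sqrt{2 n \varphi(1-\varphi) f_j (1-f_j)}$ (case fraction
$\varphi$) for binary outcomes — an approximation that is adequate for
calibration purposes and documented as such. Outcome signals follow
$\Gamma = \beta\,\gamma + \text{pleiotropy}$ per cohort.

The defaults are the package's reference study conditions, chosen once
to emulate the caffeine setting: two regions of 25 variants
($\rho = 0.9$, 8 kb spacing inside the flanked *CYP1A2*/*AHR*
coordinates), seven causal signals with effects 0.072–0.088 SD, minor
allele frequencies uniform on (0.1, 0.5), exposure $n = 10{,}000$, one
binary cohort of 300,000 with 10% cases, and causal slope 0.1 log-odds
per SD. Under these conditions selection at $p < 5\times10^{-5}$
followed by clumping at $r^2 = 0.3$ retains about 7 instruments (one
per causal signal) with a decorrelated mean F of a few tens — the same
order as real caffeine instruments. Allele pairs are drawn from the
non-palindromic combinations so that the generator exercises allele
matching rather than frequency-based palindrome resolution, which is
tested separately on handwritten fixtures.

One seed drives everything through deterministic stream splitting:
sub-seeds for the structure draw, the exposure noise, and each
outcome-cohort noise are taken up-front from the master seed in a fixed
order, so adding an outcome to a configuration does not perturb the
exposure draws, and the same seed reproduces a dataset bit for bit.

What the generator does *not* emulate: realistic human LD (block
structure, long-range haplotypes), allele-frequency-dependent effect
sizes, population stratification, sample overlap between exposure and
outcome studies, and strand ambiguity. Passing calibration on this
generator therefore validates the estimator chain under its own
assumptions; it does not certify robustness to those real-data
complications.

## Calibration experiments

`recovery_experiment()` repeats simulate → select → clump → FIQT →
harmonize → meta → correlated IVW, estimating each replicate twice
(with and without the winner's-curse correction on identical data) and
reporting mean bias, empirical vs model-based SE, 95% CI coverage,
rejection rate at $\alpha = 0.05$, and the raw-vs-FIQT bias of the
selected exposure betas. At the reference conditions with 1,000
replicates the slope is recovered with bias within Monte-Carlo error of
zero, coverage near 0.95, and null rejection near 0.05 (the test suite
asserts coverage in [0.93, 0.97] and null rejection in [0.03, 0.07]).
With a deliberately modest exposure sample ($n = 3{,}000$), selection
bites near the threshold and the winner's curse becomes visible: raw
selected betas overshoot away from zero while FIQT-corrected ones do
not, and the downstream slope estimate is correspondingly less biased.
Problem sizes in the shipped tests (1,000 calibration replicates, 500
winner's-curse replicates, 50-variant regions) were chosen as the
smallest sizes at which these rates are stable to a few parts in a
hundred.

## Numerical and degenerate-input conventions

- LD matrices are symmetrized as $(M + M^\top)/2$, the diagonal forced
  to 1; if the smallest eigenvalue is below $-10^{-8}$, negative
  eigenvalues are clipped to $10^{-10}$, the matrix reconstructed and
  its diagonal rescaled — flagged on the object. Submatrices for
  leave-one-out reuse the repaired full matrix without re-repair, for
  determinism.
- Ties in clumping are broken by rsid lexicographic order, making the
  pipeline fully deterministic.
- A single-variant analysis returns the exact Wald ratio (no linear
  solve), $\phi = 1$.
- Zero exposure betas are an error in ratio/GLS estimation (the Wald
  ratio is undefined); $p^{adj} \ge 1$ in FIQT yields an adjusted beta
  of 0 with a warning.
- Row validation on input drops (and logs) records with nonpositive
  SEs, identical alleles, out-of-range p-values or frequencies; a
  warn-only check flags p-values grossly inconsistent with
  $|\beta/\sigma|$.

## Limitations

Estimates are average lifetime effects of the genetically proxied
exposure; time-varying effects are out of scope. The estimator assumes
the supplied LD matrix matches the ancestry of the association data —
a mismatched reference panel biases both the estimate and its
heterogeneity statistics. With two gene regions the between-gene
heterogeneity test has a single degree of freedom and little power.
The effective-sample-size standard error for binary outcomes is an
approximation that degrades for very unbalanced case-control ratios
combined with rare variants.
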