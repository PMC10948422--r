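---
title: "Methods: two-sample MR, sensitivity diagnostics, and colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, sensitivity diagnostics, and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcoloc)
```

## The causal model and its assumptions

Two-sample Mendelian randomization treats genetic variants as
instrumental variables for an exposure. A variant is a valid instrument
if it (i) is robustly associated with the exposure, (ii) shares no
common cause with the outcome, and (iii) affects the outcome only
through the exposure (no horizontal pleiotropy). Under these
assumptions, with summary associations $(\hat\beta_{Xj}, \sigma_{Xj})$
and $(\hat\beta_{Yj}, \sigma_{Yj})$ from two non-overlapping samples,
each Wald ratio $r_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the
causal effect $\theta$, and the IVW estimator is their inverse-variance
weighted mean — equivalently, weighted regression of outcome on exposure
effects through the origin.

No real instrument set satisfies (iii) exactly, which is why the
package treats the robust estimators and the diagnostic suite as part of
the method, not an afterthought: the weighted median tolerates up to
half invalid weight; the mode-based estimator tolerates any minority of
invalid instruments that do not form the largest cluster; MR-Egger
tolerates directional pleiotropy provided instrument strength is
independent of the direct effects (InSIDE), at the cost of low
precision; MR-PRESSO removes individual gross violators.

## Estimator conventions

* **IVW** defaults to multiplicative random effects: the fixed-effect
  standard error is inflated by $\sqrt{Q/(k-1)}$ only when Cochran's
  $Q$ exceeds its degrees of freedom, so homogeneous sets are not
  deflated. Fixed effects are available by flag. p-values are normal.
* **MR-Egger** is fitted by weighted least squares with weights
  $1/\sigma_{Yj}^2$ after orienting every pair so $\hat\beta_{Xj} \ge 0$
  (the intercept is only interpretable as average directional pleiotropy
  in that orientation). Standard errors are the WLS ones — scaled by the
  residual dispersion, i.e. multiplicative random effects without a
  lower floor on the dispersion — and inference uses the t distribution
  with $k-2$ degrees of freedom. $I^2_{GX}$ is computed from the
  oriented exposure effects; values below 0.9 set a `nome_warning`
  because the slope is then likely attenuated toward the null.
* **Median estimators** interpolate the ratio at centred cumulative
  weight 0.5 (cumulative weights $\mathrm{cum}(w_j) - w_j/2$). Standard
  errors come from a parametric bootstrap that resamples each ratio from
  $N(r_j, se(r_j))$ with fixed weights; the seed is mandatory, making
  every bootstrap bit-reproducible. Default 1000 replicates.
* **Weighted mode** maximizes a weighted Gaussian KDE over the ratios.
  The bandwidth is $\phi \times 0.9\,\min(\mathrm{sd},
  \mathrm{mad})\,k^{-1/5}$ with $\phi = 1$ by default (the conventional
  modified Silverman rule); the maximizer is located on a 512-point grid
  and refined by golden-section search to $10^{-10}$. When the ratios
  are exactly equal the common value is returned directly. The bootstrap
  recomputes the bandwidth within each replicate.

## Instrument selection parameters

| parameter | forward preset | reverse preset | why |
|---|---|---|---|
| significance threshold | $5\times10^{-6}$ | $5\times10^{-8}$ | the forward exposures (regional brain measures) yield few genome-wide hits; the relaxed threshold is the accepted trade-off, while the disease GWAS supports the strict one |
| clumping $r^2$ | 0.001 | 0.001 | near-independence of instruments |
| clumping window | 10 Mb | 250 kb | distance from the index variant, inclusive |
| MAF floor | 0.01 | 0.01 | bi-allelic common variants only |
| outcome association | drop if $p < 0.05$ | same | guards exclusion restriction |
| F floor | 10 | 10 | weak-instrument convention |

Clumping is greedy: candidates sorted by ascending p (ties broken
lexicographically by variant ID for reproducibility), the best remaining
kept, and all same-chromosome candidates within the window at
$r^2$ above threshold discarded. Per-variant $R^2$ uses
$z^2/(z^2+n-2)$, which needs only fields already in the summary table;
the allele-frequency form $2f(1-f)\beta^2$ (standardized traits) is
available by configuration. The single-SNP F then reduces to exactly
$z^2$ for large $n$, so the F ≥ 10 filter is approximately a $|z| \ge
3.16$ screen. The F-statistic is also computed jointly over the
selected set; filtering is per-SNP.

Harmonization matches variants by ID (the convention of summary-file
lineages; positional disagreements warn but do not fail), flips swapped
alleles (negating $\hat\beta_Y$, complementing the frequency), and drops
palindromic (A/T, G/C) variants outright. A frequency-concordance rescue
for palindromic variants exists behind a flag but is off by default —
the stricter convention is the reproducible one. Variants missing from
the outcome are dropped and recorded, not proxied.

## Sensitivity suite

MR-PRESSO is implemented as a seeded parametric test: observed
$RSS = \sum_j w_j(\hat\beta_{Yj} - \hat b^{(-j)}\hat\beta_{Xj})^2$ with
leave-one-out IVW slopes $\hat b^{(-j)}$ and $w_j = 1/\sigma^2_{Yj}$
(the residual lives in the outcome space, so that weight puts each term
on its sampling scale); the null distribution re-draws
$\hat\beta^*_{Yj} \sim N(\hat b^{(-j)}\hat\beta_{Xj}, \sigma_{Yj})$ and
recomputes everything including the leave-one-out slopes. The global p
is the continuity-corrected exceedance fraction $(1 + \#\{RSS^* \ge
RSS\})/(n_{sim}+1)$, never exactly zero. Per-variant outlier p-values
are Bonferroni-corrected by $k$ and flagged below 0.05; defaults
$n_{sim} = 1000$. The 50%-valid applicability assumption surfaces as a
warning when more than half the instruments are flagged. The distortion
test is deliberately out of scope. Under a true null (500 replicates,
$n_{sim} = 200$) the global test rejects at 0.05 between 2% and 9% of
the time — the calibration the test suite asserts.

## Multiple testing and tiers

BH step-up adjustment supports a family size $m$ larger than the number
of supplied p-values, because a phenotype family's top-ranked results
are often all that is published: $a_{(i)} = m\,p_{(i)}/i$, monotonized
downward from the largest rank, capped at 1. With $m = 34$ (one test
per cortical region within a measure class) the three top published
adjusted values are reproduced to four decimals, which is what pins the
family definition down. Tiers: *significant* iff $P_{FDR} < 0.1$;
*nominal* iff raw $p < 0.05$ and $P_{FDR} \ge 0.1$; else *null*. Note
that one BH adjustment is not idempotent in general (re-adjusting
already-adjusted values can change them); the package therefore never
re-adjusts.

## Colocalization

Posteriors come from exhaustive enumeration of single-causal-variant
configurations weighted by per-variant priors ($p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$) and Wakefield approximate Bayes factors. All five
hypothesis sums are computed in log space with log-sum-exp — at region
scale the joint ABFs overflow double precision otherwise — and the H3
term uses $\log(L_1 L_2 - L_{12})$ via a stable log-difference. Effect
prior standard deviations default to 0.15 for quantitative traits and
0.2 (log-OR scale) for case-control traits, the reference framework's
documented defaults, both exposed as arguments. Regions are intersected
by variant ID; posteriors depend on betas only through $z^2$, so allele
orientation does not affect them, but harmonizing first keeps reported
signs coherent. Classification: PPH4 ≥ 0.75 strong (boundary
inclusive), 0.5 < PPH4 < 0.75 moderate, else none. Lead-variant choice
for a region is the analyst's; the package accepts any lead and extracts
±500 kb with inclusive bounds.

## What the synthetic generator emulates — and what it does not

`simulate_gwas_pair()` draws, per variant: allele frequency uniform on
(0.05, 0.45); a spike-and-slab true exposure effect (30% causal by
default, slab sd 0.1 on a standardized trait); observed effects with
$se = 1/\sqrt{2f(1-f)N}$, the standardized-trait approximation, with the
case-control factor $1/\sqrt{\phi(1-\phi)}$ for binary outcomes on the
log-OR scale; and a direct effect per pleiotropy mode. Sample-size
defaults (23,909 exposure; 80,610 outcome with case fraction 0.258)
match the study sizes this pipeline is designed around. Directional
pleiotropy is oriented with respect to the exposure-increasing allele —
on an arbitrary allele coding a fixed-sign direct effect would cancel
under Egger's orientation, which is a property of the real phenomenon,
not a generator artifact. Allele orientation of the emitted outcome
table is randomly swapped per variant so harmonization is always
exercised.

The generator does **not** emulate: realistic human LD maps (LD is
exchangeable within synthetic blocks), sample overlap between studies,
winner's-curse selection into the published exposure GWAS, allele-
frequency differences between studies, population stratification, or
trait-specific genetic architectures. Passing tests therefore certify
the estimators and pipeline plumbing under their own model — type-I
error 3–8% at the null, recovery bias below 0.02 at $\theta = 0.2$,
Egger intercept detection of mean-0.05 directional pleiotropy in the
majority of replicates — not performance on real GWAS data.

Estimator-level simulations use fully relevant instrument panels
(`pi_causal = 1`): "50 instruments" means 50 valid instruments feeding
the estimator, with the spike-and-slab default reserved for pipeline
runs where the selection stage is part of what is being tested.

`simulate_coloc_region()` propagates a causal z-score through
exchangeable LD ($z_j = r_{j,c}\,z_c + \varepsilon$, $\varepsilon \sim
N(0, R)$) and reconstructs betas from z and n. Shared regions use one
causal index for both traits; distinct regions two; null regions none.

## Numerical and degenerate-input choices

* Wald ratios are undefined at $\hat\beta_X = 0$ (explicit error); a
  single instrument degrades IVW to the Wald ratio with a message.
* Empirical p-values are continuity-corrected, so never zero; normal
  tail p-values are floored at the smallest positive double.
* Seeds are mandatory wherever randomness exists (bootstrap, PRESSO,
  generators). Pipeline sub-seeds derive from the master seed and the
  phenotype *label* (not list position), so run output is invariant to
  exposure ordering; derived seeds stay below $2^{31}$.
* The run manifest carries a config digest (MD5 of the deparsed
  configuration), per-stage seeds, version, timestamp, and per-stage
  record counts; two runs with equal configuration produce
  byte-identical result tables.
* `bh_adjust` rejects p-values outside (0, 1]; `coloc_priors` enforces
  $p_{12} \le p_1, p_2$ and total prior mass below 1.

## Problem sizes in the shipped tests

The test suite simulates at desk scale, chosen to keep the full run
within a few minutes on one CPU while leaving binomial tolerances
meaningful: 500 replicates for type-I error, 200 for recovery bias and
Egger power, 100 region pairs per coloc scenario, 500 × 200 simulations
for PRESSO null calibration, and 50 pipeline replicates for end-to-end
detection. The same conditions are recomputed from scratch by
`scripts/acceptance.R` under a caller-supplied seed.

## Known limitations

* No multivariable MR, MR-RAPS, or Steiger filtering; no proxy-variant
  lookup; no liftover; no VCF/PLINK parsing.
* The confounder screen is a static blocklist, standing in for a live
  variant-phenotype lookup service; its completeness is the analyst's
  responsibility.
* Published-table consistency checking treats the printed p's decimal
  count as its tolerance; odds ratios printed with few decimals near 1
  can flag as inconsistent purely through rounding of the CI bounds.
* Colocalization assumes at most one causal variant per trait per
  region; fine-mapped multi-signal colocalization is out of scope.
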