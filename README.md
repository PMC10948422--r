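# mrcoloc

Bidirectional two-sample Mendelian randomization (MR) and Bayesian
colocalization for GWAS summary statistics, with a seeded synthetic
generator so every stage of the pipeline is verifiable at desk scale.

The package is aimed at genetic epidemiologists asking whether a
heritable trait (for example an MRI-derived brain-structure phenotype
such as regional cortical thickness or surface area) causally influences
a disease outcome (for example amyotrophic lateral sclerosis), using only
published per-variant association summaries from two non-overlapping
GWAS.

## The model

A genetic variant *j* with exposure association β̂_Xj (se σ_Xj) and
outcome association β̂_Yj (se σ_Yj), harmonized to a common effect
allele, yields the Wald ratio estimate of the causal effect θ:

    r_j = β̂_Yj / β̂_Xj,   se(r_j) = |σ_Yj / β̂_Xj|

The **inverse-variance weighted (IVW)** estimate pools the ratios with
weights w_j = 1/se(r_j)²:

    θ̂_IVW = Σ w_j r_j / Σ w_j

with multiplicative random-effects inflation of the standard error by
√(Q/(k−1)) when Cochran's Q exceeds its k−1 degrees of freedom. Four
robust estimators are reported alongside: **MR-Egger** (weighted
regression of β̂_Y on β̂_X with a free intercept; the intercept estimates
average directional pleiotropy, the I²_GX statistic flags NOME-violation
attenuation below 0.9), the **weighted and simple median** (interpolated
median of the ratios at centred cumulative weight 0.5, bootstrap
standard errors), and the **weighted mode** (maximizer of an
inverse-variance-weighted Gaussian kernel density over the ratios). For
binary outcomes β is a log odds ratio and estimates are reported as
OR = exp(β) with 95% CI exp(β ± 1.96 se).

Instrument selection follows the convention for this analysis family:
significance threshold (5×10⁻⁶ forward / 5×10⁻⁸ reverse), greedy LD
clumping (r² ≤ 0.001 within 10 Mb / 250 kb), MAF > 0.01, removal of
palindromic and allele-incompatible variants, of variants associated
with the outcome (p < 0.05), of variants on a confounder blocklist, and
of weak instruments by the F-statistic

    F = R²(N − 1 − k) / ((1 − R²)k),   F < 10 removed,

with per-variant R² = z²/(z² + n − 2). Diagnostics include Cochran's Q,
the Egger intercept test, MR-PRESSO (simulation-based residual-sum test
with outlier removal and re-estimation), and leave-one-out. IVW p-values
are adjusted across a phenotype family by Benjamini–Hochberg FDR;
results with P_FDR < 0.1 are tiered *significant*, with raw p < 0.05 but
P_FDR ≥ 0.1 *nominal*.

**Colocalization** of two traits in a ±500 kb region enumerates the five
single-causal-variant hypotheses (H0 none, H1/H2 one trait only, H3 two
distinct variants, H4 one shared variant) with per-variant Wakefield
approximate Bayes factors,

    log ABF = ½ log(V/(V+W)) + ½ z² W/(V+W),   V = se², W = prior_sd²,

priors p1 = p2 = 10⁻⁴, p12 = 10⁻⁵, and all sums in log space. PPH4 ≥
0.75 is classified a strong, 0.5 < PPH4 < 0.75 a moderate indication of
a shared causal variant.

## Worked example

Simulate a 30-instrument exposure with true causal effect θ = 0.2 on a
case-control outcome, harmonize, and fit:

```r
library(mrcoloc)
sim <- simulate_gwas_pair(sim_config(n_snps = 30, theta = 0.2,
                                     pi_causal = 1, seed = 7))
h   <- harmonize(sim$exposure, sim$outcome, "cortical thickness", "ALS")
fit <- mr_fit(h, seed = 11, n_boot = 1000)
print(fit)
```

```
Two-sample MR fit: cortical thickness -> ALS (30 instruments)
          method n_snps     beta       se    pvalue    or or_lci95 or_uci95
             ivw     30 0.253681 0.030942 2.432e-16 1.289    1.213    1.369
     egger_slope     30 0.230934 0.046035 2.651e-05 1.260    1.151    1.379
 weighted_median     30 0.262890 0.043869 2.064e-09 1.301    1.194    1.417
   simple_median     30 0.303374 0.055992 6.022e-08 1.354    1.214    1.512
   weighted_mode     30 0.264853 0.042881 6.555e-10 1.303    1.198    1.418
 egger_intercept     30 0.002328 0.003786 5.437e-01    NA       NA       NA
```

All five estimators agree on a positive causal effect; the IVW 95% CI
for β, (0.193, 0.314), covers the generating θ = 0.2, and the Egger
intercept is indistinguishable from zero (no directional pleiotropy, as
simulated). The diagnostics concur:

```r
print(sensitivity_report(h, n_sim = 1000, seed = 12))
```

```
Sensitivity report (30 instruments)
  Cochran's Q = 22.23 on 29 df, p = 0.81
  Egger intercept = 0.002328 (p = 0.544), I2_GX = 0.949
  MR-PRESSO global p = 0.8062, 0 outlier(s)
```

A region with one shared causal variant (z = 8 in both traits)
colocalizes decisively:

```r
reg <- simulate_coloc_region("shared", n_variants = 50, ld_rho = 0.3,
                             effect_z = 8, seed = 3)
coloc_abf(reg$region1, reg$region2)
```

```
Colocalization over 50 shared variant(s) (window +/- 500 kb)
  PPH0 = 0.0000  PPH1 = 0.0000  PPH2 = 0.0000  PPH3 = 0.0000  PPH4 = 1.0000
  classification: strong (lead rs5)
```

`run_bidirectional()` wires the stages (selection → harmonization →
exclusions → MR-PRESSO purge → estimation → sensitivity → family FDR)
over many exposures and returns a tiered result table with a run
manifest; `run_from_config()` drives the same from a YAML file, and
`inst/scripts/run-analysis.R` exposes it from a shell.

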