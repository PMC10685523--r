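---
title: "Methods: two-sample Mendelian randomization in aminoMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in aminoMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aminoMR)
```

## The problem and the model

aminoMR implements a complete two-sample Mendelian randomization (MR)
workflow for GWAS summary statistics. The motivating application is the
question of whether genetically predicted circulating amino acid levels
causally affect the risk of metabolic dysfunction-associated fatty liver
disease (MAFLD): amino acid associations come from a large metabolite GWAS
meta-analysis, disease associations from independent MAFLD case–control
GWASs, and the analysis is repeated against an MRI-derived liver-fat
fraction (PDFF) as a continuous validation outcome. Everything in the
package, however, is generic two-sample MR: any exposure/outcome pair of
summary-statistic tables in the supported format can be analysed.

Two-sample MR treats genetic variants as instrumental variables. For
variant $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its association
with the exposure in one sample and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$)
its association with the outcome in a non-overlapping sample. Under the
instrumental-variable assumptions (relevance, independence of confounders,
exclusion restriction), each variant provides a Wald ratio estimate
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ of the causal effect
$\theta$, with first-order standard error
$\sigma_{Yj}/|\hat\beta_{Xj}|$.

### Effect-size recovery from z-scores

Metabolite GWAS results are often distributed as z-scores. For a
standardized (unit-variance) trait the per-allele effect and its SE are
recovered as
$$\hat b = \frac{z}{\sqrt{2p(1-p)(n+z^2)}}, \qquad
  \mathrm{SE} = \frac{1}{\sqrt{2p(1-p)(n+z^2)}},$$
with $p$ the allele frequency and $n$ the sample size
(`zscoreToBeta()`). The conversion preserves $\hat b/\mathrm{SE} = z$,
so downstream significance filtering is unaffected by it. The same
sampling model gives the per-instrument variance explained,
$2p(1-p)\hat b^2$, and the single-instrument strength statistic
$F = (\hat b/\mathrm{SE})^2$. We use the $(\hat b/\mathrm{SE})^2$
approximation rather than $R^2(n-2)/(1-R^2)$: the two agree to $O(1/n)$
at GWAS sample sizes and the conventional $F>10$ rule is insensitive to
the difference.

### Instrument selection

Candidate instruments pass a multiplicity-adjusted significance threshold
(`significanceThreshold()`; the default $5\times10^{-8}/102 =
4.9\times10^{-10}$ adjusts genome-wide significance for 102 tested
metabolites). Correlated candidates are pruned by greedy p-value-ordered
LD clumping (`ldClump()`), the PLINK convention: visit candidates in
ascending p-value order and keep a variant only if its $r^2$ with every
previously kept same-chromosome variant within the window (default
$r^2 < 0.01$, 10 Mb) is below threshold. Ties in p-value break by
(chromosome, position, id), making the output independent of input row
order. The greedy output is the maximal p-ordered independent set; the
test suite verifies this against a brute-force subset-enumeration oracle
on hundreds of random instances. LD pairs absent from a sparse table are
taken as $r^2 = 0$ with a logged warning rather than an error, because
real LD tables never enumerate all pairs.

Instruments missing from an outcome GWAS are replaced by the
highest-$r^2$ proxy above $r^2 > 0.8$ within a window (`findProxy()`),
with ties broken by positional distance and then id; when no proxy
qualifies the instrument is dropped for that outcome with a recorded
reason. The proxy-search window default is the printed 500 Mb; we suspect
the intended value was 500 kb, so the window is an explicit parameter and
both values work unchanged. Proxy outcome effects are oriented to the
original instrument's effect allele using the sign of the dosage
correlation when the LD table carries one (as tables built by
`r2FromDosages()` do); otherwise the pair is used as-is and flagged
`proxy_orientation_unverified` in the action log.

### Harmonization

`harmonizeData()` aligns outcome to exposure effect alleles: direct
match, allele swap (negate $\hat\beta_Y$, complement the frequency),
strand complement, and complement-plus-swap are attempted in that order;
anything else drops as `allele_mismatch`. Palindromic variants (A/T, C/G)
cannot be resolved from alleles alone. The default policy `drop_all`
removes them — matching the analysed study, which removed both its
palindromic instruments — while `frequency_inference` aligns them by
comparing allele frequencies and drops only variants inside the ambiguity
band (minor-allele frequency above 0.42) or lacking an outcome frequency.
Outcome tables without frequencies are fully supported; they simply force
the `drop_all` behaviour for palindromes. Every decision is recorded in a
per-variant `action_log`, and pairs plus drops always partition the
instruments attempted.

### Estimators

All estimator algebra runs on the log odds-ratio scale for binary
outcomes (SD scale for continuous ones); odds ratios appear only in
reporting output. Writing $w_j = (\hat\beta_{Xj}/\sigma_{Yj})^2$ for the
first-order inverse variance of the ratio $\hat\theta_j$:

* **IVW** (`mrIVW()`): $\hat\theta = \sum w_j\hat\theta_j / \sum w_j$,
  equivalent to weighted regression through the origin. Fixed-effect SE
  $1/\sqrt{\sum w_j}$; the multiplicative random-effects variant
  multiplies it by $\max(1, \sqrt{Q/(k-1)})$, where $Q$ is Cochran's
  heterogeneity statistic about the pooled estimate. We chose
  multiplicative rather than additive random effects as it is the
  convention of the TwoSampleMR ecosystem this workflow mirrors; the
  choice is recorded in the estimate's metadata. At $k=1$ the fixed
  IVW reduces to the Wald ratio exactly (special-cased so the identity
  holds bit-for-bit, not merely to rounding).
* **MR-Egger** (`mrEgger()`): weighted least squares of
  $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ *with* an intercept, weights
  $1/\sigma_{Yj}^2$, after orienting exposure effects non-negative. The
  slope is consistent for $\theta$ under InSIDE even with invalid
  instruments; the intercept estimates mean directional pleiotropy. SEs
  carry the $\max(1,\hat\sigma)$ multiplicative overdispersion factor
  and p-values use $t_{k-2}$ — small-$k$ regression inference.
* **Weighted median** (`mrWeightedMedian()`): the ratio estimates are
  ordered and interpolated at cumulative normalized weight 0.5
  ($s_j = \sum_{i\le j} w'_i - w'_j/2$); consistent when valid
  instruments carry more than half the weight.
* **Weighted mode** (`mrWeightedMode()`): the argmax of a weighted
  Gaussian kernel density over the ratios, bandwidth
  $0.9\,\mathrm{mad}(\hat\theta)/k^{1/5}$ times a user factor (default
  1, reported in the output metadata). Exact symmetric bimodal ties
  resolve deterministically to the smaller mode, because the density is
  evaluated on an ascending grid and the first maximum wins.

Weighted median and mode SEs come from a parametric bootstrap (both
betas perturbed by their SEs; default 5000 resamples) and require an
explicit seed in the pipeline configuration, which is what makes full
runs byte-reproducible. Wald-ratio SEs use the first-order delta method
(outcome noise only), standard two-sample practice.

Confidence limits are $\hat\theta \pm 1.96\,\mathrm{SE}$ with 1.96
exactly (not 1.959964) everywhere, including the reconstruction of
log-scale estimates from printed ORs (`seFromCI()`): the difference is
far below reporting precision, and a single convention keeps printed
two-decimal CIs reconstructable.

### Method selection and the analysis stages

`selectMainMethod()` encodes the main-analysis rules: Wald ratio for one
instrument, fixed-effect IVW for two or three, multiplicative
random-effects IVW for four or more, with weighted median and MR-Egger
sensitivity analyses attached only when $k \ge 4$. The same rules apply
to binary and continuous outcomes.

The pipeline functions compose the stages: `runForwardMR()` (selection →
harmonization → estimation → fixed-effect meta-analysis of discovery and
replication via `fixedEffectMeta()`), `runConfounderExclusion()` (same
run minus a supplied list of confounder-associated variants, with flags
when an exposure's instrument count falls below a method threshold),
`runConservative()` (prioritized-instrument subsets, Wald or fixed IVW
only; exposures with no prioritized instruments are reported as not
assessable), `runReverseMR()` (disease as exposure with fixed IVW,
weighted median and weighted mode), and `runContinuousOutcome()`
(SD-per-SD estimates, no OR columns). Meta-analysed p-values below
$0.05/n_\text{exposures}$ (default denominator 20, configurable) are
labelled *strong*, between that and 0.05 *suggestive*. Per-exposure
failures never abort a run; they become structured log records, since
dropped instruments and unassessable exposures are an expected part of
this kind of analysis. Between-cohort heterogeneity of causal estimates
is available through `betweenGroupQ()` applied to per-cohort runs.

## The synthetic-data generator

`simulateTwoSample()` generates matched exposure/outcome summary tables
with known ground truth: $p_j \sim U$, true exposure effects with random
sign and $|b_j| \sim U$, direct (pleiotropic) outcome effects $\alpha_j$
added relative to the exposure-increasing allele (allele coding is
arbitrary, so "directional" pleiotropy is only meaningful in that
orientation), true outcome effect $\theta b_j + \mathrm{sign}(b_j)\,
\alpha_j$, and independent Gaussian sampling noise with the
standardized-trait SE $1/\sqrt{2p_j(1-p_j)n}$ in each sample. z-scores
and p-values are emitted so the selection stage can run on simulated
data, and `noiseScale` can shrink the noise to machine precision — a
noise-free study pushed through the whole pipeline must return
$\theta$ to at least six significant digits with every estimator, which
the tests assert.

Defaults were chosen once to echo the motivating study's conditions:
exposure sample size 85,000 (the metabolite GWAS meta-analysed up to
~86,500 participants), outcome sample size 10,000 so that outcome noise
dominates at desk scale, allele frequencies in (0.10, 0.50) and effect
magnitudes in (0.05, 0.30) SD, which give single-instrument F-statistics
of roughly 40–4000, matching the reported strong-instrument range
(38.7–7504.1). Binary outcomes are simulated directly on the log-OR
scale (observed log-OR = truth + normal noise) rather than through
individual-level logistic sampling: that is sufficient for estimator
algebra, calibration and robustness studies, and keeps thousands of
replicates cheap. What the generator does *not* emulate: realistic
allele-frequency spectra, case–control ascertainment and the
non-collapsibility of odds ratios, sample overlap, population
stratification, or genome-wide LD beyond simple equicorrelated blocks
(`simulateLDBlocks()`, which maps latent Gaussians to dosage-like values
in [0, 2] with the latent correlation pre-corrected so the transformed
variables hit the target $r^2$). Passing calibration tests on this
generator therefore demonstrates correctness of the estimator algebra
and selection logic, not robustness to those real-data complications.

## Numerical and design choices

* Duplicate variant ids in an input table keep the smallest p-value and
  warn; input delimiters (tab, comma, whitespace) are auto-detected from
  the mandatory header line; `#`-prefixed lines are metadata.
* Underflowing p-values are floored at the smallest positive double so
  the $(0,1]$ invariant survives extreme z-scores.
* Degenerate inputs fail loudly and specifically: zero exposure effects
  name the offending variant, constant dosage columns name the column,
  collinear Egger designs are rejected, and estimators state their
  minimum instrument counts ($k \ge 2$ for Q, $\ge 3$ for
  Egger/median/mode).
* Simulation scenario sizes used by the tests and the acceptance script
  (2000 replicates for calibration at $k=10$; 1000 replicates at
  $k=150$ with directional pleiotropy N(0.15, 0.02) on 30% of
  instruments) were fixed in advance by power analysis so that expected
  pass margins exceed three binomial standard errors on one CPU in a few
  minutes.
* Per-exposure bootstrap seeds are derived deterministically from the
  run seed (`seed + 7919 i` modulo a prime below $2^{31}$), so results
  are reproducible yet exposures do not share RNG streams.

## Known limitations

The package deliberately omits MR-PRESSO, multivariable MR and
contamination-mixture/CAUSE estimators (out of scope for this workflow),
genome-build liftover, VCF parsing, and LD computation from binary
reference panels. Proxy substitution uses a single best proxy, not LD
imputation. The weighted-mode bandwidth rule is a pragmatic MAD-based
convention; mode estimates are bandwidth-sensitive, which is why the
factor is surfaced in the output metadata rather than hidden.

## A worked example

```{r example}
set.seed(1)
study <- simulateTwoSample(simulationConfig(
  nSnps = 10, causalTheta = 0.35, seed = 42))
hd <- harmonizeStudy(study)
mrIVW(hd, "multiplicative_random")
mrEgger(hd)$intercept
```

The IVW estimate targets the generating $\theta = 0.35$ and the Egger
intercept targets zero (no pleiotropy was simulated); both are computed
fresh each time the vignette runs.
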