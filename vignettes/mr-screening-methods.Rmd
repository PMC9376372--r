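---
title: "Methods: two-sample MR screening with mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The model and its assumptions

Two-sample Mendelian randomization treats genetic variants as instruments
for an exposure: if SNP j shifts the exposure by $\gamma_j$ (in SD units)
and the exposure causally shifts the log-odds of a binary disease by
$\beta$ per SD, then the SNP's marginal log-OR on the disease is
$\beta\gamma_j + \alpha_j$, where $\alpha_j$ is any direct (horizontally
pleiotropic) effect. With exposure and outcome association estimates
taken from two non-overlapping GWAS, each SNP yields a ratio estimate
$\hat\beta_j = \hat\beta_{yj}/\hat\beta_{xj}$, and the estimators in this
package differ only in how they pool the $\hat\beta_j$ and in which
instruments they tolerate being invalid ($\alpha_j \ne 0$).

The three usual instrumental-variable assumptions — relevance,
independence from confounders, and exclusion restriction — motivate the
package's structure: relevance is enforced quantitatively (the
F-statistic filter), exclusion violations are probed by the sensitivity
suite, and directionality (exposure causes outcome rather than the
reverse) is tested per screen row with the Steiger test.

The screening design the defaults emulate is a panel of immune-cell
traits (flow cytometry in a cohort of 3,757) tested trait-by-trait
against myasthenia gravis GWAS outcomes: a discovery set of 38,243 with
1,873 cases and two registry-based validation sets of 217,288 with 232
cases and 386,783 with 152 cases. Those shapes, and a per-trait
instrument strength around the screened median ($R^2 = 0.06$, rising to
$\approx 0.24$ for the strongly instrumented receptor-expression traits
such screens identify), are the package's default simulation conditions.

## Instrument selection

`select_instruments()` applies four steps whose thresholds live in
`selection_config()`:

* **Significance and frequency.** `pval < 5e-8` (strict, so a SNP at
  exactly $5\times10^{-8}$ is excluded) and minor allele frequency
  `min(eaf, 1 - eaf) > 0.01`. Units: `eaf` is the effect-allele fraction.
* **Clumping.** Greedy, PLINK-style: the remaining SNP with the lowest p
  becomes an index, and every SNP on the same chromosome within
  ±10,000 kb (interpreted as ±10,000,000 bp, inclusive) with
  $r^2 \ge 0.001$ to the index is removed. Iteration order is ascending
  p, ties broken by chromosome, position, then SNP id — the "keep the
  lowest-p SNP" rule made deterministic. SNPs missing from the LD panel
  are conservatively treated as unlinked and retained, with a warning.
* **Outcome lookup with proxies.** Instruments absent from the outcome
  table are replaced, on the outcome side only, by the outcome-present
  SNP with maximal $r^2 \ge 0.8$; ties break by basepair distance, then
  id. The exposure-side statistics always remain the original
  instrument's, and proxies can be disabled (`use_proxies = FALSE`).
* **Weak-instrument filter.** Per-SNP strength is
  $F = R^2(n-k-1)/(k(1-R^2))$ evaluated at $k=1$; SNPs with $F < 10$ are
  dropped. Note that at one SNP this $F$ equals $t^2$ of the exposure
  association, so any genome-wide-significant SNP ($|t| > 5.45$) passes
  automatically — the filter only bites when the significance threshold
  is relaxed, which is why it is still exposed as a separate step.

Per-SNP variance explained uses the t-statistic transform
$R^2_j = t_j^2/(t_j^2 + n - 2)$ (`snp_r2()`); the set-level $R^2$ is the
sum over retained instruments and the set-level $F$ re-applies the
formula at the set's $k$. Summing per-SNP $R^2$ ignores residual LD
between retained instruments, which clumping has already capped at
$r^2 < 0.001$; a joint-regression alternative would need individual-level
data the two-sample design deliberately avoids. The same transform is
used, on the observed scale, for the binary outcome's $R^2$ in the
Steiger test; it is isolated behind one function precisely so a
liability-scale or $2p(1-p)\beta^2$ variant can be swapped in.

## Harmonization

`harmonize()` aligns outcome records to the exposure's effect allele:
identical pairs pass through; swapped orientation negates
$\hat\beta_y$ and mirrors the frequency; complementary-strand pairs are
complemented first; anything irreconcilable (including indels) is
dropped. Palindromic SNPs (A/T, G/C) cannot be strand-resolved from
labels, so after label alignment they are kept only when both
frequencies fall on the same side of 0.5 **and** both lie outside
$0.5 \pm$ `palindrome_eaf_tol`. The default tolerance 0.08 (band
0.42–0.58) is the de-facto community default for this rule; a strict
mode drops every palindrome for analysts who prefer to lose a SNP rather
than trust frequency inference.

## The estimator suite

Routing follows the instrument count (`select_method()`): one SNP — Wald
ratio; two or three — IVW; more than three — IVW plus the sensitivity
suite, whose members stay consistent under progressively weaker
assumptions at the cost of power.

* **Wald ratio.** SE by the first-order delta method
  $se(\hat\beta_y)/|\hat\beta_x|$; a second-order option adds the
  exposure-side term.
* **IVW.** Weighted mean of ratios with $w_j = \hat\beta_{xj}^2 /
  se(\hat\beta_{yj})^2$ — algebraically the zero-intercept weighted
  regression of outcome on exposure betas. Two SEs are always reported:
  fixed-effect $1/\sqrt{\sum w_j}$ and multiplicative random effects,
  the fixed SE scaled by $\max(1, \sqrt{Q/(k-1)})$ with $Q$ Cochran's
  heterogeneity. The default estimate carries the floored random-effects
  SE (the community convention for screens, where pleiotropic
  heterogeneity is the rule). Under a clean homogeneous null this floor
  is deliberately conservative — the validation suite therefore checks
  test size on the fixed-effect p-value, which is the exactly calibrated
  test in that regime, and interval coverage on the default
  (random-effects) CI, the one the package reports.
* **MR-Egger.** Weighted free-intercept regression after orienting all
  exposure betas nonnegative; the intercept estimates the mean direct
  effect, the slope the pleiotropy-adjusted causal effect. SEs carry a
  multiplicative overdispersion parameter floored at 1; p-values use
  $t_{k-2}$.
* **Weighted median.** Ratio estimates sorted; the estimate is the
  linear interpolation of the value at which standardized cumulative
  weight — with the half-own-weight convention $s_j = \sum_{i \le j} w_i
  - w_j/2$ — crosses 0.5. This convention is stated explicitly because
  published descriptions vary. SE by parametric bootstrap (resampling
  both betas from normals at their SEs), default 1,000 draws, seeded.
* **Modes.** Gaussian-kernel density over the ratios, maximised on a
  1,024-point grid spanning the ratio range ±3 bandwidths; the simple
  mode weights SNPs equally, the weighted mode by $w_j$. Bandwidth is
  `bandwidth_factor` × the MAD-based rule of thumb
  $0.9\min(sd, mad)\,k^{-1/5}$; the factor is exposed because the mode
  is the one estimator here that is genuinely bandwidth-sensitive.
* **MR-PRESSO.** Global test: observed
  $RSS = \sum_j (\hat\beta_{yj} - \hat\beta_{(-j)}\hat\beta_{xj})^2$
  with leave-one-out IVW slopes, compared against parametric simulations
  from the fitted values (default 1,000, seeded); empirical p-values use
  the add-one rule so they stay in (0, 1]. Outliers: per-SNP simulated
  residual distributions, Bonferroni-corrected over k, flagged below
  0.05. The corrected estimate re-runs IVW without flagged SNPs. The
  distortion p-value is a permutation variant — random subsets of the
  outlier count are removed and the relative shift of the IVW estimate
  recomputed — chosen because the reference procedure's exact resampling
  scheme is not uniquely specified in print.

All CIs use $z = 1.959964$. Every stochastic routine takes an explicit
seed and restores the caller's RNG state, so results are reproducible
bit-for-bit and independent of call order.

## Diagnostics and ranking

The Steiger test compares instrument correlation with exposure vs
outcome on the Fisher-z scale; a tie is reported as *not* supporting the
assumed direction, with p = 1. Power for a binary outcome uses the
normal approximation $\Phi(|\ln OR|\sqrt{N R^2 K(1-K)} - z_{1-\alpha/2})$
with case fraction $K$ — exactly $\alpha/2$ at OR = 1, and monotone in
effect size, instrument strength and sample size. FDR adjustment is
Benjamini–Hochberg via `stats::p.adjust`, applied separately per outcome
with the family equal to the exposures that produced an estimate
(skipped exposures are excluded and the family size is logged); screen
rows are ranked by adjusted then raw p.

## The synthetic generator

`sim_gwas()` draws summary statistics directly at the summary level
rather than simulating genotypes: allele frequencies uniform on
(0.05, 0.5); contiguous LD blocks with exchangeable within-block $r^2$;
positive instrument effects (one per block lead) scaled so standardized
effects sum to the configured $R^2$, with per-instrument shares within
±20% of equal so every planted instrument clears genome-wide
significance at realistic budgets; exposure estimates
$N(\mu_{xj},\ 1/\sqrt{2p_j(1-p_j)n})$; outcome log-ORs
$N(\beta\mu_{xj} + \alpha_j,\ 1/\sqrt{2p_j(1-p_j)NK(1-K)})$ — the
rare-outcome variance approximation. Non-lead SNPs in an instrument's
block carry the LD-attenuated marginal echo ($\sqrt{r^2}$ times the
standardized effect), so clumping faces realistic shadow signals, and
noise is block-correlated with the genotype correlation. Allele labels
include configurable palindromic and orientation-flipped fractions;
instrument frequencies are drawn in (0.05, 0.40) so palindromic
instruments stay outside the harmonization ambiguity band. Pleiotropy
modes: none, balanced, directional, or a single-SNP outlier.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: winner's-curse selection of
instruments discovered in the same exposure GWAS, sample overlap between
exposure and outcome studies, fine-scale LD (exchangeable blocks only),
population stratification, and any real genetic architecture such as
major-histocompatibility effects. It validates the machinery, not the
biology.

Seed handling: derived seeds inside `sim_gwas()`/`sim_screen()` use
prime-spaced offsets (e.g. +499979) rather than consecutive integers,
because consecutive `set.seed()` values produced visibly dependent
replicate streams in calibration runs; all derived seeds stay below
$2^{31}$.

## Numerical choices and degenerate inputs

Strict inequality at the significance threshold; MAF boundary exclusive;
window bounds inclusive. Zero surviving instruments is a typed,
non-fatal result that lands in the screen's skip list. `bx = 0` is a
domain error for ratio-based estimators. Estimators below their minimum
instrument count return typed not-applicable results so the pipeline can
continue. Empirical p-values use (1 + exceedances)/(1 + draws). The mode
estimator returns the common value directly when all ratios coincide
(the density argmax is then bandwidth-independent).

## Validation suite: problem sizes and design choices

The acceptance-style checks run at the study's shapes but desk scale:
IVW size and coverage over 1,000 seeded replicates of 10 valid
instruments (exposure n = 3,757; outcome 38,243 with K = 0.049);
MR-PRESSO outlier recovery over 100 seeds; Egger intercept recovery over
400 replicates (400 rather than 200 because the 2-Monte-Carlo-SE
assertion at 200 sat within one part in a thousand of its own noise
floor); and the end-to-end screen over 50 seeds of 20 exposures, where
the three causal traits carry the protective shape such screens report
(OR 0.67 per SD, instrument $R^2 = 0.24$) and the seventeen null traits
the screen-median $R^2 = 0.06$. With all twenty traits at the median
strength the top-3-ranking property is not attainable (the weakest of
three causal z-scores, non-centrality ≈ 4.1, is overtaken by the best of
seventeen nulls in roughly a fifth of seeds) — the strongly instrumented
causal shape is the scenario the ranking claim is about.

## Known limitations

* Per-SNP outcome $R^2$ for rare binary traits is computed on the
  observed scale; liability-scale conversion is not implemented, so
  Steiger z-values for very rare outcomes are conservative in magnitude.
* The MR-PRESSO distortion test is a documented permutation variant, not
  a line-by-line reimplementation of the reference procedure.
* Proxy substitution assumes the proxy tags the instrument's haplotype
  with the LD panel's stored phase; allele-phase mismatches in a real
  panel would need the panel to carry haplotype information this
  structure does not model.
* The multiple-testing family is "exposures tested per outcome"; if an
  analyst prefers the full pre-attrition trait count as the family, the
  adjusted values must be recomputed from the raw p column.
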