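---
title: "Methods: the weighted telomere-length score and its case-control pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the weighted telomere-length score and its case-control pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teloscore)
```

## The score and its assumptions

Leukocyte telomere length (LTL) is a heritable quantitative trait. The
package's panel holds eleven GWAS-discovered SNPs, each annotated with the
allele associated with longer telomeres (the effect allele, EA), its
frequency, and the per-allele effect on LTL both in SD units and in base
pairs. The base-pair weights are the SD-scale effects multiplied by a
uniform 1200 bp per SD — the single constant consistent with every panel
row at printed precision — and `bpFromBeta()` exposes that conversion.

For subject $i$ with effect-allele counts $g_{ij} \in \{0, 1, 2\}$ and
weights $w_j$ (bp), the raw score is
$S_i = \sum_j g_{ij} w_j$, defined only for subjects with a complete
panel. Because real TaqMan panels miss a few percent of calls, the headline
statistic is the *scaled* score
$\tilde S_i = \sum_{j \in \text{called}(i)} g_{ij} w_j \, / \, n_i$,
the mean per-genotype contribution over the $n_i \ge 1$ called SNPs. The
scaled score assumes missingness is unrelated to genotype (calls missing at
random); under that assumption it is an unbiased per-SNP average and lets
every subject above the call-rate floor contribute. Both variants are
available in `quintileAssociation(score_variant =)`, the scaled one being
the default.

The score is a weighted allele count, so it is linear: per-SNP
contributions add, and raising one genotype by one allele raises
$\tilde S_i$ by exactly $w_j / n_i$. The test suite asserts these
identities directly.

## QC before analysis

The pipeline (`analyzeCohort()`) applies QC in a fixed order, exclusions
first:

1. **Call-rate filter.** Subjects need at least `min_called` (default 8)
   of the 11 panel genotypes — the integer-count formulation avoids
   floating-point ambiguity at the equivalent 72.7% rate. The filter is
   idempotent and logs every excluded subject with its call count.
2. **Hardy-Weinberg equilibrium in controls.** Genotyping artifacts
   inflate or deplete heterozygotes, so each SNP is tested in the retained
   controls. We use the Levene–Haldane *exact* conditional test: given the
   observed allele counts, the probability of each possible heterozygote
   count is computed in closed form and the two-sided p-value sums the
   probabilities of all configurations no more likely than the observed
   one. The exact test is the field standard at minor allele frequencies
   like this panel's (0.04–0.5), where the chi-square approximation is
   unreliable in the rare-homozygote cell; a chi-square variant is
   available (`hweControls(method = "chisq")`). The flagging threshold is
   0.05 per SNP, configurable. A brute-force enumeration oracle verifies
   the exact test for all allele totals up to 50 in the test suite.
3. **Duplicate concordance.** `duplicateConcordance()` pools both-called
   genotype comparisons over duplicated-sample pairs; plates are typically
   accepted above 99%.

Subjects missing an adjustment covariate are excluded from model fits with
a logged count (complete-case analysis); constant covariates — which can
arise in small strata or single-country cohorts — are inestimable and are
dropped from the design with a message rather than crashing the fit.

## Quintile and per-SNP models

Cases are distributed into quintiles of the **control** score
distribution: cutpoints are the 20/40/60/80th percentiles of control
scores, computed with the linear-interpolation percentile definition
(`quantile(type = 7)`), and recorded in the output so results are
reproducible bit for bit. A score exactly on a threshold falls in the
lower bin — a deterministic, documented tie-break that matters rarely for
continuous scores. With tie-free scores, controls self-assign to bins of
size $n/5 \pm 1$.

Association is by unconditional logistic regression (`stats::glm`,
binomial family, convergence tolerance $10^{-10}$, at most 100
iterations), adjusted by default for age (continuous, years), sex and
country (indicators, largest control category as reference). The quintile
analysis fits bins 2–5 against bin 1 plus a separate trend model entering
the quintile index 1–5 as one numeric term, so the "per-quintile
increment" OR is directly comparable across cohorts. Confidence intervals
and p-values are Wald ($\exp(\hat\beta \pm 1.96\,\mathrm{se})$), the
default in standard epidemiology software; on a saturated 2×2 design the
fitted OR equals the cross-product ratio to at least six significant
digits (asserted in the tests). Fits that fail to converge or show
quasi-separation ($|\hat\beta| > 15$) are flagged and propagate a nonzero
exit status through `cmdAnalyze()` rather than being reported silently.

Per-SNP models code the **minor** allele, determined in controls, with a
tie at frequency 0.5 resolved to the panel's other allele; an
effect-allele coding is available for orientation-consistent comparisons
with the score (the two codings give exactly reciprocal ORs). Supported
models: allelic (log-additive count), codominant (heterozygote and
rare-homozygote contrasts against the common homozygote), dominant
(carrier of ≥ 1 minor allele) and recessive (minor homozygote vs the
rest). These are the conventional definitions of dominant/recessive for
the minor allele; published tables sometimes swap the two labels, so the
output spells each contrast out in the `term` column. A codominant
rare-homozygote contrast with an empty case or control cell — expected for
the rarest panel SNP, where only a couple of rare homozygotes exist per
thousand subjects — is omitted with an explicit note instead of being
fitted into separation.

Multiple testing uses Bonferroni over SNPs × models exactly
($0.05/22 = 0.0023$ for the default panel and model pair); no FDR
alternative is offered because the pipeline mirrors a fixed published
design. Stratified runs restrict cases to each level of JAK2-V617F status
or MPN subtype while keeping all controls; quintile cutpoints are
re-derived from each analysis's controls by default (`cutpoints =
"per-stratum"`), with fixed overall cutpoints as an option — whether a
stratified reanalysis should reuse overall cutpoints is genuinely open,
and since all strata share the same controls the two choices coincide
unless score subjects are dropped differentially. Strata with fewer than
10 cases are computed but flagged as low-power.

The continuous trend term enters the quintile *index*, not the underlying
score; the raw score can be modeled by passing it to `fitLogistic()`
directly, but the index is the primary definition because the per-quintile
increment is the unit the headline analysis reports.

## The simulator: what it emulates, and what it does not

`simulateCaseControl()` exists so every stage above can be validated by
parameter recovery without individual-level study data. Its defaults are
the study conditions of the motivating MPN case-control design:

* 480 cases / 909 controls; country weights proportional to the control
  margins 75 Hungary / 182 Italy / 132 Poland / 520 Spain; male fraction
  0.50; case subtype weights 149 CML / 173 ET / 36 PMF / 122 PV; half of
  cases JAK2-positive.
* Ages drawn from a normal distribution with mean 53 and SD 11, truncated
  to [18, 95] by inverse-CDF. The study reports only medians and IQRs
  (about 52–56, IQR ~46–68), so this truncated normal is a stand-in
  consistent with those margins, not an asserted fact; it is
  config-exposed. Cases and controls draw covariates from the same
  distributions, emulating frequency matching; residual imbalance is
  handled by adjustment, as in the real design.
* Genotypes: independent SNPs under HWE at the panel effect-allele
  frequencies (a Binomial(2, EAF) count per SNP). The 11 SNPs lie on 9
  chromosomes and the score treats them additively, so linkage
  disequilibrium modeling would add nothing to pipeline validation.
* Missing calls: 3% per genotype, missing completely at random, targeting
  the ~97% average call rate of a well-run TaqMan panel.

Disease is generated *prospectively*: a pool of `pool_factor` × (cases +
controls) subjects (default 20×) receives case probabilities
$\mathrm{logit}^{-1}(\beta_0 + \text{effects})$, status is drawn, and the
requested margins are sampled without replacement. Logistic odds ratios
are invariant to outcome-dependent sampling, so injected ORs are
recoverable by the analysis; the intercept default $\beta_0 = -2$ only
controls how efficiently the pool yields cases, and an exhausted pool
raises an error suggesting a larger pool or intercept. Quintile effects
need cutpoints before status exists, which is circular; the generator
resolves it in two passes — pool-wide cutpoints give a provisional status
draw, and the non-cases of that draw define the final cutpoints used to
assign effects — so the injected contrasts are anchored to (approximately)
the same control distribution the analysis will later estimate.
Missingness is applied only after status assignment, so the disease model
always acts on true genotypes; the analysis then sees the scaled score
with its realistic measurement error, which is why recovered extreme-
quintile ORs sit a few percent below the injected values in any single
replicate while remaining within Monte-Carlo error on average.

What the simulator does **not** model: linkage disequilibrium, population
stratification within country, genotype-calling intensity artifacts
(missingness is MCAR, never informative), clonal hematopoiesis in
controls, or measured telomere lengths. Passing recovery tests therefore
demonstrates that the pipeline's arithmetic and inference are correct
under the stated generative model — not that the model captures every
feature of real cohorts.

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation between order statistics (type 7),
  recorded with the outputs. Fewer than 5 distinct control scores is a
  degenerate distribution and an error.
* HWE exact test: probabilities computed on the log scale via `lgamma`;
  the two-sided sum uses a $10^{-10}$ slack when comparing configuration
  probabilities so ties are included despite floating-point rounding.
* Raw scores demand a complete panel and error otherwise, pointing the
  caller at the scaled score; zero called genotypes is an error for
  scoring and MAF computation.
* VCF input matches panel sites by chromosome + position and accepts the
  allele pair in either REF/ALT orientation (flipping the count when the
  effect allele is REF); any other allele pair at a matched position is
  skipped with a warning, never silently strand-complemented.
* All simulation randomness flows from one integer seed; identical config
  + seed reproduces the cohort byte for byte.

## Validation scale

The test suite validates recovery at the full study size (480/909): 200
replicates for the quintile-effect and per-allele recovery checks (about a
minute together), 30 seeded null cohorts for the type-I-error check at the
0.0023 threshold, and 100 seeds for the HWE-in-generated-controls
property. These sizes put Monte-Carlo standard errors around 1–2% of the
recovered ORs, small enough to detect any systematic implementation bias
while keeping the default test run fast.

## Known limitations

* The score's weights are fixed literature constants; the package never
  re-estimates them from measured telomere length, and offers no qPCR/FISH
  LTL handling.
* Conditional logistic regression for individually matched designs is out
  of scope (the emulated design is frequency-matched).
* Multi-allelic variants and genotype imputation are unsupported; panel
  VCF sites must be biallelic with diploid GT fields.
* Wald inference can be anti-conservative in near-separated strata; such
  fits are flagged rather than corrected (no Firth penalization).
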