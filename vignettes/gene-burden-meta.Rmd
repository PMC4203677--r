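---
title: "Gene-based rare-allele burden meta-analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based rare-allele burden meta-analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rareburden)
```

## The problem

Individually, rare variants (minor allele frequency, MAF, at or below
3%) carry too few carriers for single-marker case-control tests, even
in cohorts of thousands.  The collapsing (burden) strategy aggregates
the rare variation within a gene into one per-sample score and tests
that score instead.  `rareburden` implements this strategy for
*imputed dosage* data pooled across several case-control studies of
unequal size — the setting of the public Alzheimer's disease cohorts
(ADNI, GenADA, eMERGE, NIA-LOAD, Framingham) whose joint structure the
package's synthetic generator emulates — together with the surrounding
machinery: quality control, meta-analysis, conditioning on a dominant
known risk locus (APOE ε4), and a two-stage confirmatory design.

## The statistic

For a gene with $n$ qualifying rare variants and per-sample imputed
dosages $G_1, \dots, G_n \in [0, 2]$, the gene dosage is the mean

$$D = \frac{1}{n} \sum_{i=1}^{n} G_i \in [0, 2].$$

Qualifying means: inside the gene's interval (1-based inclusive
coordinates; a variant at the exact start or end counts, and a variant
may belong to several overlapping genes), study-level MAF in the
configured window (default $0 \le \mathrm{MAF} \le 0.03$, both bounds
inclusive), and imputation quality INFO $\ge 0.4$.  Risk and
protective alleles are pooled deliberately: direction-aware weighting
before gene selection inflates type-I error, at a known cost in
power.  A sample missing some of the included dosages averages over
its non-missing ones (its effective $n$ shrinks); a sample missing all
of them is excluded from that gene's test.

Per study, case/control status is regressed on $D$ with covariate
adjustment (age, sex, education as a single continuous category,
principal components supplied as data, optionally the ε4 count) and
the Wald $z = \hat\beta / \widehat{se}$ with its two-sided normal $P$
is reported.  The default family is logistic — the phenotype is
binary, and per-study effects are then interpretable as log odds
ratios per unit of $D$ — with ordinary least squares available as
`family = "linear"` for compatibility with linear-model burden
engines.  This is a declared approximation: the classical collapsing
tool this design follows is linear-regression-based, but its published
per-study effect sizes only make sense on a logit scale.

Education harmonization follows the four-category scheme
(≤4, (4,10], (10,15], >15 years); the published category boundaries
leave years in (10, 11] formally unassigned, and the package closes
that gap at 10 (category 3 starts above 10 years).  Missing education
is imputed to the study mean category.

## Meta-analysis

Studies are combined by the sample-size-weighted fixed-effects
Z-score (Stouffer) scheme of METAL.  Each study's weight is
$w_i = \sqrt{N_{E,i}}$ with the effective sample size

$$N_E = \frac{4}{1/N_{\mathrm{cases}} + 1/N_{\mathrm{controls}}},$$

and

$$z_{\mathrm{meta}} = \frac{\sum_i w_i z_i}{\sqrt{\sum_i w_i^2}}.$$

$N_E$ equals $2N$ for a balanced study and is capped by the total
sample size, so a badly unbalanced study (e.g. 259 cases against
4,323 controls) contributes far less than its headcount suggests.
$z_\mathrm{meta}$ is invariant to rescaling all $N_E$ by a constant.
Only the *sample-size* METAL mode is implemented; inverse-variance
weighting and heterogeneity statistics are out of scope.  Per-study
availability is carried in a direction string over the fixed study
order — `+` ($z_i>0$), `-` ($z_i<0$), `?` (no qualifying variants,
MAF/INFO window failure, or a degenerate fit) — and `?` studies get
zero weight.

Genome-wide gene-based significance is Bonferroni over the gene count:
$0.05 / 28{,}517 \approx 1.8\times10^{-6}$ for the full human
annotation; scans over simulated gene sets default to $0.05/G$ for the
$G$ genes actually tested.  Scan calibration can be checked with the
genomic inflation factor
$\lambda_{GC} = \mathrm{median}(\chi^2_1(1-P)) / q_{\chi^2_1}(0.5)$.

## Quality control

Variant-level rules mirror standard array-era practice: directly
genotyped variants are dropped at MAF < 1%, call rate < 95%, or
Hardy-Weinberg exact $P < 10^{-6}$; imputed variants are dropped at
INFO < 0.4 (strictly below: INFO = 0.4 survives).  The HWE test is the
exact conditional test — given the allele totals, sum the
probabilities of all heterozygote counts no more probable than the
observed one — computed in log space over the full support, so no
sample size needs asymptotics.  It is applied to hard calls only;
fractional dosages do not enter.

Sample-level rules: call rate < 95%; autosomal heterozygosity
outliers, found by converting each sample's heterozygosity rate to a
two-sided $P$ under a normal approximation of the cohort distribution
and applying Benjamini–Hochberg at FDR 1% (the published pipelines
name only "FDR < 1%", so this concrete recipe is a declared,
approximate reconstruction); and relatedness, where any pair with mean
identity-by-state $\mathrm{IBS} = \mathrm{mean}\,(2-|g_1-g_2|)/2$
above 0.95 loses its lower-call-rate member (ties broken
deterministically by sample order).  The IBS matrix is computed by
indicator cross-products and can be thinned to a fixed variant subset
for large cohorts.

## The two-stage design

Stage 1 scans every gene as above and flags genes passing the
Bonferroni threshold.  Stage 2 then makes the signal portable: each
variant of a selected gene is tested as a classical single SNP per
study, meta-analyzed, and kept only if meta $P < 0.05$, meta $Z > 0$
(risk direction), and its study-level MAF lies in $[0.5\%, 3\%]$ — the
floor guards against the poor imputation accuracy of very rare
alleles.  The MAF/INFO windows are evaluated per study, so a SNP can
contribute in some studies and be `?` in others.  The selected SNPs
are re-collapsed and re-meta-analyzed with and without ε4 adjustment.
Because stage 2 reuses the stage-1 data, its $P$ values are labelled
confirmatory-in-sample — they demonstrate that a compact SNP panel
carries the gene's signal, not independent replication.  A
candidate-gene lookup extracts named genes (e.g. established
disease-database hits) from the stage-1 table in request order.

## Conditioning on a dominant risk locus

A gene-based hit near a very strong common signal (APOE ε4 for
Alzheimer's disease) may be borrowed significance through linkage
disequilibrium.  Two diagnostics are provided.  First, the adjusted
re-scan appends the per-sample ε4 value — the genotyped 0/1/2 count
where available, otherwise the imputed ε4 dosage — to the covariates
and re-runs the full scan-plus-meta path; an independent signal keeps
its meta $Z$ (small changes reflecting only the noncollapsibility of
logistic coefficients), whereas an LD-borne signal collapses toward
zero.  Second, the variance inflation factor
$\mathrm{VIF} = 1/(1-R^2)$ from regressing $D$ on ε4 *within the full
covariate design* (age, sex, education, PCs — measuring collinearity
inside the model actually fitted, a choice this package declares since
the original covariate set for this diagnostic is not documented).
VIF near 1 certifies the gene and the confounder are carrying separate
information.

## The synthetic cohort generator

No individual-level data from the emulated studies can ship with a
package, so the generator produces cohorts with the same statistical
anatomy and known ground truth:

* **Study sizes.** Defaults are the six post-QC case/control shapes of
  the emulated studies (totalling 4,171 cases and 9,358 controls),
  preserving their imbalance — the feature that makes $N_E$ weighting
  matter.
* **Variants.** Genes are laid contiguously on a synthetic coordinate
  system (10 kb genes every 20 kb); population MAFs are truncated-Beta
  draws, default $\mathrm{Beta}(0.8, 35)$ on $[0.001, 0.05]$, putting
  roughly three quarters of the mass below 3% — the published sources
  do not state the imputed rare-MAF spectrum, so this is a modelling
  default, exposed in the configuration.  Genotypes are Hardy-Weinberg
  binomial draws.  Variants monomorphic in a generated study are
  redrawn up to 100 times and otherwise kept for QC to remove; columns
  of causal or LD-linked genes are never redrawn, so the stored truth
  stays consistent.
* **Disease model and ascertainment.** Case probability is logistic:
  intercept (default −1.2, a population risk near 23% at covariate
  means, typical of elderly AD cohorts) plus per-unit-$D$ effects of
  the causal genes computed from *true* genotypes, the ε4-like
  confounder effect (default log 3, the ballpark of the real ε4 odds
  ratio), and age/sex/education/PC effects.  Studies are filled by
  rejection sampling: population individuals are drawn and kept until
  the case and control quotas are both met (the fixed-quota design of
  the emulated studies), with a bounded number of augmentation rounds
  before an unreachable configuration errors out.
* **Confounder geometry.** By default the ε4-like locus is independent
  of every gene; setting `confounder_ld_gene` draws that gene's
  alleles only on confounder haplotypes
  ($q_v = \mathrm{MAF}_v / f_{\varepsilon4}$ per haplotype), giving the
  strong-LD regime in which adjustment must dismantle the signal.
* **Imputation noise.** Each hard call is miscalled with probability
  $e$ into a random Hardy-Weinberg draw at the estimated frequency
  $\hat\theta$, and the emitted dosage is the posterior mean
  $(1-e)\,g_{\mathrm{obs}} + e\,2\hat\theta$.  INFO is the
  ratio-of-variances score
  $1 - \overline{\mathrm{Var}}_{\mathrm{post}} /
  (2\hat\theta(1-\hat\theta))$, clamped to $[0,1]$, with INFO = 0 for
  monomorphic variants by convention.  $e = 0$ reproduces the
  genotypes exactly with INFO = 1; a range `c(lo, hi)` draws
  per-variant rates uniformly so the INFO < 0.4 filter has something
  to remove.  No haplotype estimation or reference-panel imputation is
  performed — this parametric model replaces them.
* **Covariates.** Age $\sim N(75, 6^2)$, sex Bernoulli(½), education a
  fixed multinomial over categories 1–4 with a configurable missing
  rate (exercising mean-imputation), standard-normal PCs, ε4 count
  binomial with frequency 0.15.

What the generator does **not** emulate — and what green tests
therefore cannot certify about real data — includes linkage
disequilibrium among rare variants within a gene, pedigree structure
(the family-based cohort among the emulated studies would need a
kinship-aware association model), population stratification beyond
user-supplied PCs, genotyping batch effects, and non-random
missingness.

## Power scaling and the choice of demonstration scenarios

Because effects are parameterized per unit of $D$, and $D$ is a mean
of $m$ rare dosages,
$\mathrm{sd}(D) \approx \sqrt{2\bar p(1-\bar p)/m}$ is small: about
0.1 for $m = 5$ variants at 2% MAF.  The expected meta noncentrality
is approximately
$\beta \cdot \mathrm{sd}(D) \cdot \sqrt{\textstyle\sum_i N_{E,i}/4}$,
so at the full six-study scale ($\sum N_E \approx 9{,}200$) a
per-unit-$D$ log OR of $\log 1.7$ yields expected $z \approx 2$ —
real-data scans at that effect size are *underpowered* at the
genome-wide threshold, which is precisely why burden studies lean on
large $N$ and why detection demonstrations here use configurations
chosen by this power formula: few variants per gene, MAF near the 3%
ceiling, and a per-unit-$D$ effect near 1.7 (e.g. the packaged
detection scenario with two studies and $\sum N_E \approx 3{,}900$
gives expected $z \approx 6.4$).  Calibration and coverage checks do
not depend on power and run at the null or with moderate effects.

## Numerical choices and degenerate inputs

* HWE probabilities are computed from log factorials and normalized in
  place; the P value sums terms with probability
  $\le p_{\mathrm{obs}}(1+10^{-12})$, the usual tie guard.
* Threshold directions follow the published wording exactly: filters
  drop at strictly-less-than (call rate < 95%, INFO < 0.4, MAF < 1%
  for genotyped panels, HWE $P < 10^{-6}$), while the rare-window
  bounds are inclusive (MAF ≤ 3%, ≥ 0.5% in stage 2).
* Association fits use the weighted QR of `glm.fit`; non-convergence,
  collinearity (an aliased predictor), $|\hat\beta| > 15$ or
  $\widehat{se} > 100$ (separation), and zero-variance predictors are
  all returned as non-estimable rather than as errors, and propagate
  to `?` in meta direction strings.  A single-class phenotype is an
  error.  An ε4 column with zero variance is aliased against the
  intercept, so the adjusted fit equals the unadjusted one exactly.
* Missing dosages are `NA` end to end, never 0; `.gen` files encode a
  missing dosage as the all-zero probability triple.
* Determinism: one integer seed drives the whole generator;
  identical configuration and seed give byte-identical cohorts, and
  the full pipeline is reproducible end to end.

## Problem sizes used by the shipped checks

The packaged test-and-acceptance workloads were sized as study
conditions in their own right: the null-calibration suite uses 4
studies of 1,000/1,000 samples and 100 genes, repeated to ~2,000
gene-level tests; parameter recovery uses a single 4,000/4,000 study
with a causal gene at log OR $\log 1.5$, 100 replicates, judged by
2-SE coverage; the conditional contrasts use two 700/700 studies with
a $\log 3$ confounder; and the exact-HWE comparison enumerates every
genotype configuration with up to 200 samples.

## Known limitations

Logistic (not the original linear) burden regression is the default,
recorded as an approximation; GRANVIL's exact treatment of per-sample
missingness is undocumented, and the averaging rule used here is a
declared substitute.  Stage-2 significance is in-sample.  Pedigree
data, BGEN/PLINK binary formats, variance-component (SKAT-type)
tests, functional variant weighting, and annotation-aware filtering
are out of scope.
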