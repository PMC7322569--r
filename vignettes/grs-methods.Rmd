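---
title: "Methods: clumping-and-thresholding risk scores and their evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clumping-and-thresholding risk scores and their evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`grsct` packages a complete genetic-risk-score (GRS) analysis for a
polygenic disease and a within-case severity sub-phenotype: score
construction by LD clumping and thresholding (C+T), cross-cohort and
cross-ancestry evaluation, a polarized Z-score polygenicity test, and
genetic-load stratification of severity and onset age.  This vignette
explains the models, the tunable parameters and their defaults, what the
synthetic cohorts do and do not emulate, and the numerical and design
choices made where the method leaves them open.

## The liability-threshold cohort model

The simulator treats disease as a thresholded latent liability

$$L_i = G_i + e_i, \qquad G_i = \sum_j \beta_j\,(g_{ij} - 2p_j), \qquad
e_i \sim N(0,\, 1 - h^2),$$

with a sample a case iff $L_i > \Phi^{-1}(1 - K)$ for prevalence $K$.
Causal effects are drawn $N(0, \cdot)$ at `n_causal` randomly placed SNPs
and rescaled so $\sum_j 2p_j(1-p_j)\beta_j^2 = h^2$ exactly — exact
variance control under linkage equilibrium.  With effect signs random,
linkage disequilibrium (LD) between causal SNPs adds cross-terms of zero
expectation, so realized $\mathrm{Var}(G)/\mathrm{Var}(L)$ stays near
$h^2$ (a property the test suite asserts).

Haplotypes follow a first-order copying chain: the allele at SNP $j$ is
drawn from transition probabilities chosen so the chain preserves every
marginal frequency exactly and attains the target adjacent-allele
correlation `ld_rho` whenever that correlation is feasible for the
frequency pair; infeasible pairs are truncated to the feasible maximum,
never at the expense of the marginal.  This is the minimal LD model with
one tunable parameter that still gives clumping something real to do:
correlation decays geometrically with SNP distance, and the chain
restarts at each of the `n_chrom` chromosome blocks (variants are laid
out `spacing_bp` apart, defaults 22 chromosomes and 10 kb, so a 250 kb
clumping window spans ±25 SNPs).

Retrospective case-control sampling draws population samples until the
requested case and control quotas fill, discarding the surplus stratum —
the direct analogue of oversampling cases into a case-control study.  At
1% prevalence a 4,000-case cohort consumes roughly 400,000 population
draws, so the chain simulation runs in compiled code; its random stream
is seeded from R's RNG, and a single master seed fixes every cohort
bit-for-bit.

A second ancestry is modelled by Balding–Nichols drift: subpopulation
frequencies are drawn from
$\mathrm{Beta}\!\big(p\tfrac{1-F_{st}}{F_{st}},\,(1-p)\tfrac{1-F_{st}}{F_{st}}\big)$,
mean $p$ and variance $F_{st}\,p(1-p)$, applied to the shared panel so
the two cohorts keep common variant identities and causal effects.

Within cases, the severity indicator and onset age are tied to
standardized genetic load $G^{std}$ (standardized over the case set, so
the configured slopes are per case-distribution SD):

$$P(\text{renal}=1 \mid \text{case}) =
  \mathrm{logit}^{-1}(\alpha + \gamma\,G^{std}), \qquad
\text{onset} = \mu + \delta\,G^{std} + N(0, \sigma^2),$$

floored at 1 year.  Defaults: $\alpha = -0.55$ (renal fraction ≈ 0.37,
matching the roughly one-in-three renal involvement typical of lupus
cohorts), $\gamma = 0.5$, $\mu = 33$, $\delta = -3$ years/SD,
$\sigma = 12$ — onset means and spreads in the range clinical cohorts
report, with higher load presenting earlier.  No generative parameters
for real cohorts exist to estimate these from; they are calibration
choices made once and documented here.  Default `h2_liab = 0.3`,
`prevalence = 0.01`, `ld_rho = 0.2`, `maf_range = (0.05, 0.5)`.

**What the generator does not emulate:** realistic human LD maps (block
structure, recombination hotspots), sex chromosomes, genotyping and
imputation error, cryptic relatedness, and ascertainment beyond simple
case oversampling.  Variant allele pairs are drawn non-ambiguous
(no A/T or C/G), emulating post-QC array content; the strand-ambiguity
handling in the aligner is therefore exercised by dedicated fixtures, not
by the simulator.  Tests passing on these cohorts show the pipeline's
statistics behave correctly under the stated model — not that any
particular real cohort satisfies that model.

## C+T scoring

The association stage supports logistic Wald regression (the default,
and the only test accepting covariates such as principal components), an
allelic chi-square on the 2×2N allele table (beta = Woolf log allelic OR;
P from the Pearson statistic), and the 1-df Cochran–Armitage trend test.
Genome-scale sweeps in this package's own experiments use the vectorized
allelic test; the logistic route fits one GLM per SNP and is intended for
candidate sets.  Monomorphic SNPs are flagged and never tested;
separation or non-convergence yields a missing effect, never a fabricated
one.

Greedy clumping follows the reference tool: candidates with `P < p1`
in ascending P, ties broken by (chromosome, position, id) for
determinism; members join by `r² ≥ r2_max` within ±`window_kb` on the
same chromosome; each SNP belongs to at most one clump; the secondary
P threshold is fixed at 1 (any SNP may join a clump).  r² is composite
LD on dosages, matching genotype-only input.  Undefined correlations
(constant vectors on the shared support) count as not-in-LD.  The
published grid (8 P thresholds × 2 r² × 2 windows = 32 configurations)
ships as `default_ct_grid()`.

Weights are the training-GWAS index-SNP betas.  Alignment to a scoring
dataset keeps a weight whose effect allele matches allele1, flips the
dosage (`2 − g`) when it matches allele2, tries the strand complement
before declaring failure, and always drops strand-ambiguous variants —
no frequency-based strand inference, correctness over yield.  Missing
dosages impute to `2 × EAF` of the scored cohort by default (keeps
scores comparable across samples); `omit` is available.  Two MHC
tag-SNP pairs for the classical class-II risk haplotypes (European:
rs2187668, rs9267992; Chinese: rs9271366, rs9275328) can augment a
within-population European score, weighted from the training table;
cross-population scoring omits them.

## Evaluation machinery

AUC is the Mann–Whitney statistic with ties at one half; variance and
CIs come from the midrank DeLong structural components, truncated to
[0, 1], with degenerate zero-variance cases returning point CIs.  The
paired test uses the component covariance; an exactly zero AUC
difference (identical or monotone-equivalent scores) reports p = 1.
The unit tests check both against `pROC` and against exhaustive pair
enumeration; the acceptance suite additionally compares the paired
test with a studentized sign-flip permutation oracle — studentizing the
permuted statistic is what makes the permutation distribution the right
reference for the normal-approximation z at n ≈ 30.

Quintile stratification sorts by score with a stable order (tied
boundary values fall in the lower stratum, flagged when more than 1% of
boundaries tie), compares each upper stratum with the lowest by Pearson
chi-square, and reports Woolf log-scale 95% CIs with Haldane–Anscombe
correction on zero cells.  The two-way ANOVA of score over age-of-onset
(cut at 30 years by default, parameterized) and renal groups uses
sequential type-I sums of squares in the order age, renal, interaction;
under the balanced designs of interest this equals the type-III
decomposition, which the tests verify by refitting in both orders.

The polygenicity test polarizes a target study's Z scores to the
discovery risk allele (the allele with positive discovery beta; zero
betas are dropped as directionless) after the same harmonization rules
as scoring, then t-tests mean Z within discovery-P bins
(1–0.9, …, 0.1–0; left-open/right-closed so P = 1 lands in the top bin).
The test is two-sided — the alternative of interest is directional, but
the symmetric test is conservative and the sign is reported.  Input is
expected to be LD-thinned (the pipeline clumps at r² = 0.1, 250 kb
window, P threshold 1 before testing).  Bins with fewer than two SNPs
report undefined statistics; an all-equal bin reports p = 1 when its
mean is zero.

The power calculator is the allelic two-proportion normal approximation:
case frequency $p_1 = p_0\,\mathrm{OR}/(1 + p_0(\mathrm{OR} - 1))$,
allele counts $2n$, null SE from the pooled frequency, and two-sided
rejection with both tails counted — so OR = 1 returns exactly alpha.
The genotypic 2-df alternative, prevalence corrections and D′ settings
of interactive calculators are deliberately out of scope; this closed
form is the package's defined contract and is monotone in OR, n and
alpha.

## Numerical and design notes

- **Determinism.** Every stage derives its seed from the master seed
  plus a stage label; rerunning any stage alone reproduces its output.
  Derived seeds stay below 2³¹.
- **QC bounds are closed**: MAF ≥ threshold passes, INFO ≥ threshold
  passes; region exclusions are inclusive base-pair intervals (the
  extended MHC default is chr6:24–36 Mb); `variant_qc` is idempotent.
- **Relatedness** uses the method-of-moments IBS decomposition given
  allele frequencies (PI_HAT), removing the higher-missingness member of
  each flagged pair; estimates below 50 usable SNPs warn as unstable.
- **PCs**: dosages centered and scaled by $\sqrt{2p(1-p)}$, missing
  imputed to the mean, eigen-decomposition on the smaller dimension,
  sign fixed by making each component's largest-magnitude coordinate
  positive.
- **Meta-analysis** is fixed-effects inverse-variance — the standard for
  a two-cohort GWAS meta-analysis; single-study SNPs are carried through
  flagged rather than dropped.
- **Memory**: the dosage matrix is a plain integer matrix without
  dimnames (naming an n×m matrix forces a full copy at scale); validation
  uses in-place scans.  An 11,000 × 20,000 cohort peaks around 4 GB
  through the full train-test pass.
- **Problem sizes.** The package's own experiments run at up to 20,000
  SNPs with 2,000 causal, an 11,000-sample training cohort and a
  4,000-sample test cohort — large enough for the C+T score to beat
  chance decisively and for the true-effect score to sit within Monte
  Carlo error of the attainable-AUC ceiling, while a full suite run
  completes in minutes.  Null calibrations use 10,000 null SNPs
  (inflation, P uniformity), 200 replicate cohort pairs (binned-Z
  type-I error) and 2,000-sample null pairs (cross-cohort AUC).

## Known limitations

- The chain LD model cannot represent long-range LD or haplotype blocks,
  so clumping difficulty is milder than in real MHC-scale regions — one
  reason the pipeline, like practitioners, excludes the extended MHC and
  re-admits it only through tag SNPs.
- The allelic test assumes HWE allele counting; its Wald z (beta/SE) and
  Pearson P differ slightly by construction, and both are reported.
- Logistic per-SNP association at genome scale is slow by design (one
  GLM per SNP); use the allelic or trend test for sweeps.
- `attainable_auc` assumes bivariate-normal score and liability; scores
  built from few, large-effect SNPs violate that normality and can sit
  measurably off the ceiling (the recovery experiments use thousands of
  causal SNPs, where the approximation is excellent).
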