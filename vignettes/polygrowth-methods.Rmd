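---
title: "Models and methods behind polygrowth"
author: "polygrowth maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polygrowth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`polygrowth` analyses the genetics of plant rosette growth: it turns
per-plant diameter time series into growth parameters, asks how much of
their variation is genetic, maps that variation with a mixed-model GWAS,
and then asks the evolutionary question — has growth diverged between
regions more than neutral drift would allow? This vignette explains each
model, the tunable parameters, the synthetic data used for testing, and
the numerical choices, in the package's own terms.

## Growth curves

Rosette expansion is modelled as a three-parameter logistic,

$$d(t) = \frac{FS}{1 + e^{-slope\,(t - t_{50})}},$$

where $FS$ (cm) is the final diameter, $t_{50}$ (days) the inflection
point at which half the final size is reached, and $slope$ (per day) the
rate constant of the near-linear phase. `fit_logistic()` minimises the
residual sum of squares with Levenberg–Marquardt (`minpack.lm`), starting
from $FS_0 = \max d$, $t_{50,0}$ = the first day exceeding $FS_0/2$ and
$slope_0 = 4\,\max(\Delta d/\Delta t)/FS_0$, with a fixed grid of jittered
restarts on failure, so fits are deterministic. We use the convention
$slope > 0$ for an increasing curve; some growth-curve software
parameterises the same model with the opposite sign. Because "slope" is
also used in the field for the fold increase of the linear phase, the
derivative at the inflection point ($slope \cdot FS/4$) is emitted as
`slope_linear`; the rate constant is primary. Fits are per plant —
replicate-level data support that resolution and it is what the
downstream variance decomposition needs — and a fit whose asymptote runs
far beyond the data (more than five times the largest observed diameter)
is flagged as failed rather than reported.

## Genotypic means, plasticity, heritability

The experiments follow a randomized block design: each genotype once per
block, blocks split into trays with row/column positions.
`genotypic_means()` fits
`parameter ~ genotype + block + tray + tray:row + tray:col`
by least squares with sum-to-zero contrasts on the nuisance factors (tray
labels are made unique within block). The genotypic mean is the marginal
mean over the observed design: predictions are formed for every plant's
design covariates with the genotype switched, then averaged. In a
balanced design this equals the estimated marginal mean over the level
grid (asserted against `emmeans` in the tests); in unbalanced designs it
remains defined even when missing design cells make grid-based marginal
means non-estimable.

Growth plasticity (GxE) is the residual of the low-light genotypic mean
regressed on the high-light mean: a genotype's deviation from the
population-average light response. Broad-sense heritability uses the
replicate-level model `value ~ block` with a random genotype intercept
(REML via `nlme::lme`), $H^2 = V_g/(V_g+V_e)$, clipped to $[0,1]$. For a
selfing species these are broad-sense components: replicates are selfed
progeny, so all genetic variance (not only additive) is shared within a
genotype.

## Mixed-model association

Markers are filtered at 5% minor allele frequency and 5% missingness
(boundaries inclusive: only markers *below* 5% MAF or *above* 5% missing
are removed). Kinship is identity-by-state allele sharing,
$K_{ij} = 1 - |g_i - g_j|/2$ averaged over pairwise-complete markers —
for inbred lines simply the fraction of identical calls.

Association uses the standard two-variance-component mixed model
$y = X\beta + u + e$, $u \sim N(0, \sigma^2_g K)$,
$e \sim N(0, \sigma^2_e I)$. REML is profiled over the variance ratio
$\delta = \sigma^2_e/\sigma^2_g$ on the eigenbasis of $K$ (coarse grid
plus golden-section refinement on $\log\delta \in [-12, 12]$). The
default per-marker test keeps $\delta$ fixed at the null-model estimate
(the EMMAX approximation), rotates phenotype and genotypes, and applies
generalized least squares with $t$-tests on $n - \mathrm{rank}(X) - 1$
degrees of freedom; exact per-marker re-estimation (EMMA) is available
and agrees within $|\Delta\log_{10} p| \le 0.2$ on small instances (a
test asserts this). Missing genotypes are mean-imputed per marker for
testing only, never for kinship. `pseudo_h2` — the phenotypic variance
fraction explained by relatedness — is reported from the null fit; note
that for genotypic-mean phenotypes (one value per line) it often runs to
the upper boundary, because a kinship with near-unit diagonal can absorb
line-level residuals. Loss-of-function (LOF) association replaces allele
dosages with binary gene states and reuses the same machinery, as does
the kinship-corrected trait correlation (Pearson r, Wald p from the
mixed model).

## Differentiation: Fst, Qst and their nulls

Per-SNP Fst is Nei's $1 - H_s/H_t$ with small-sample corrected gene
diversities, treating selfing lines as haploid-equivalent (a heterozygous
call contributes one half). Negative estimates are clamped to zero.
Gene-level Fst aggregates SNPs in a gene interval by ratio of sums,
$\sum(H_t - H_s)/\sum H_t$, the standard multi-locus form; averaging
per-SNP ratios is biased and not used.

Qst is $V_B/(V_B + V_W)$ from a random-region-intercept REML fit on the
genotypic means; $V_W$ is the among-genotype-within-region variance. A
means-level model is used because extracting exactly one intercept and
one residual variance only decomposes cleanly there. Three references
guard the comparison with Fst:

* the **percentile** of the genome-wide per-SNP Fst distribution attained
  by Qst (local adaptation is suggested when Qst exceeds the 95th
  percentile);
* a **permutation null**: region labels permuted across genotypes, test
  statistic $Q_{st} - F_{st,95}$, $p = (1 + \#\{\ge obs\})/(n+1)$;
* a **multivariate-normal null**: neutral genotypic values drawn from
  $N(0, V_g K)$, Qst recomputed per draw. Within-region relatedness
  widens this null — structure alone creates apparent divergence.

The resampling nulls recompute Qst thousands of times, so they use an
internal profiled REML for the one-way random-intercept model (the
within/between sufficient statistics make each fit microseconds); a test
asserts its agreement with `nlme::lme` to four decimals. Because REML
clips $V_B$ at zero, the neutral Qst distribution has a point mass at 0;
the reported $p$ keeps the "fraction $\ge$ observed" convention, and the
self-consistency test uses the randomized probability integral transform,
which is the exact uniformity statement for a mixed distribution.

## Polygenic scores and the Qx test

Associated SNPs are reduced to quasi-independent index SNPs by greedy
p-value-ordered clumping (1 Mb window, secondary threshold 0.01,
$r^2 \ge 0.5$; ties on p broken by position then id, so results are
input-order independent). The genome-scale defaults (index threshold
$10^{-4}$) are tuned to genome-wide marker counts; at desk scale the
threshold should be chosen to reproduce the intended *size* of the
associated set (a few dozen SNPs) rather than its nominal value — the
synthetic acceptance run uses $5\times10^{-3}$ for this reason, since the
Qx quadratic form needs dozens of markers before its chi-square null is
trustworthy.

A unit's polygenic score is $Z = 2\sum_l \alpha_l p_l$; a single selfing
genotype is its own unit with $p_l \in \{0, \frac12, 1\}$. Under neutral
drift, centered scores satisfy
$\mathrm{Cov}(Z) = 2 V_A F$ with
$V_A = 4\sum_l \alpha_l^2 \epsilon_l (1-\epsilon_l)$
($\epsilon_l$ the across-unit mean frequency) and $F$ the among-unit
drift covariance, estimated from genome-wide standardized frequencies
(`drift_covariance()`, scaled so the identity above holds). The Qx
statistic is the Mahalanobis norm of the centered scores on the top
$n-1$ eigenvectors of $F$ and is $\chi^2_{n-1}$ under neutrality. The
chi-square null is exact under Gaussian drift (verified at 500 seeds);
with strongly skewed Beta-distributed frequencies and few units its tail
deviates by a few percent, which is why the test also reports an
empirical p from random marker sets matched to the associated set by
frequency decile. An optional `selfing` switch doubles the drift scaling
for fully selfing units; both variants are reported in pipelines where it
matters.

Three validation schemes quantify whether scores carry real signal:
training on 80% of genotypes and scoring the rest; training on two
replicates and validating on the third; and comparing the associated
set's score–phenotype correlation with the distribution over equal-sized
random marker sets. The last is evaluated in-sample, so selection bias
inflates the associated set's correlation even for pure noise — the
scheme demonstrates *relative* signal strength, and out-of-sample schemes
are the guard against overfitting.

## GO enrichment

Each gene receives the smallest association p among its internal SNPs,
or the nearest SNP's p (midpoint distance, ties toward smaller p).
Tandem duplicates (alignment e-value $< 10^{-30}$, fewer than 10 genes
apart) are pruned by removing the downstream member, iterated to a fixed
point so pruning is idempotent. Over-representation is the one-sided
hypergeometric test on candidate genes within 10 kb of associated SNPs;
rank-based enrichment is a one-sided Kolmogorov–Smirnov test of term
gene ranks. Terms with five or fewer genes are suppressed. Because many
terms are tested on correlated gene sets, the significance threshold is
calibrated by running the full enrichment on random gene sets of the
same size and taking the 0.01% quantile of the pooled p-value
distribution. No GO-graph decorrelation (elim/weight) is applied: the
classic test is reproducible and oracle-checkable.

## The synthetic study

`synthio` generates data with the statistical structure the analysis
assumes, so every stage is testable against known truth:

* **Genotypes.** Fully homozygous selfing lines in two or more regions.
  Ancestral frequencies are Uniform(0.05, 0.95) (avoiding near-fixed
  markers while exercising the MAF filter); regional frequencies follow a
  Balding–Nichols Beta model. The divergence parameter is calibrated by
  deterministic Monte-Carlo inversion so that the *realized* mean per-SNP
  Nei Fst equals `fst_target` — the mean of per-SNP ratio estimators sits
  well below the ratio of expectations, so a closed-form inversion is not
  adequate.
* **Trait.** Effects at `n_causal` markers, genotypic values scaled to
  unit variance, so `regional_shift` is in genetic standard deviations.
  The shift is realized through causal allele-frequency divergence
  aligned with effect signs — the signature of polygenic adaptation the
  Qx and Qst machinery is designed to detect — with any remainder the
  realized frequencies cannot support added as a constant genetic offset
  (the only option when `fst_target = 0`). Optionally, causal loci draw
  their frequencies with a larger divergence parameter (`causal_fst`)
  than the neutral background, emulating divergent selection; without
  this, a detectable trait shift forces a heavy background Fst tail and
  the Qst-vs-Fst95 comparison loses meaning.
* **Growth experiment.** Per-plant logistic trajectories at the
  configured measurement days, with genotypic values mapped onto final
  size, additive block and tray offsets, per-plant biological deviations
  (`plant_sd`) and measurement noise. The defaults (final size 8 ± 1 cm
  between genotypes, ± 0.8 cm between replicate plants, 0.2 cm
  measurement noise, three blocks) give a broad-sense heritability of
  final size near 0.6, the magnitude seen in replicated rosette
  experiments. Environmental heritability control in `simulate_trait`
  scales replicate noise so realized $H^2$ matches `h2`.
* **LOF matrix.** Bernoulli gene states at a configurable carrier
  frequency; one designated gene can shift the trait.

What the generator does **not** emulate: linkage disequilibrium decay
along chromosomes (markers are exchangeable given their frequencies),
genotype-by-environment interactions beyond the two-regime design,
selection acting within regions, and sequencing artefacts. Passing tests
therefore show the *statistical machinery* is correct under the stated
model, not that real data meet the model's assumptions.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on
2 × 100 lines × 5000 SNPs with 15 causal loci (`causal_fst = 0.35`,
background 0.1, shift 1.5 genetic SD), 200–1000 permutations, 300–2000
MVN draws and 300–500 random marker sets — sizes chosen so an entire run
completes in about a minute on one CPU while leaving every statistic
identifiable. Key numerical guards: kinship eigen-decompositions jitter
the diagonal by $10^{-6}$ when the smallest eigenvalue falls below
$10^{-8}$; Cholesky factors escalate jitter geometrically; the REML
ratio search brackets on a coarse grid before refining, and collapses
the boundary to exactly zero variance; p-values are floored at
$10^{-300}$; permutation and exceedance p-values use the $+1$
correction and can never be zero. All randomness flows from a single
seed through `stage_seed()`, a deterministic per-stage expansion, so any
stage can be re-run in isolation and reproduce its output bit for bit.

## Known limitations

The EMMAX approximation mildly misstates per-marker variance components
for markers of large effect (the exact EMMA option exists for small
problems). The Qx chi-square p is anti-conservative by a few percent
when drift is strongly non-Gaussian; prefer the empirical p when the two
disagree. Qst from two regions rests on a variance component estimated
from a single between-group contrast and is accordingly noisy — the
permutation and MVN nulls, not the point estimate, carry the inference.
The GO stage tests terms independently; strongly overlapping terms will
co-appear. And the synthetic study's exchangeable-marker design means
clumping rarely has real LD to remove — the clumping logic is therefore
tested against constructed LD blocks rather than the generator.
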