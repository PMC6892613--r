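---
title: "Methods: QTL mapping and variance decomposition in round-robin crosses"
author: "rrqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTL mapping and variance decomposition in round-robin crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `rrqtl`, the assumptions they
make, the tunable parameters and their defaults, the numerical choices in
the fitting code, and what the synthetic-data generator does and does not
emulate. Everything quantitative stated here is computed by the test suite
or by `scripts/acceptance.R`; this document explains *why* the code does
what it does.

## The design

Sixteen (or generally k) inbred haploid parents are crossed in a ring, each
parent to its two neighbors, giving k biparental crosses and a panel of
haploid recombinant segregants. Every biallelic variant carried by one
parent segregates 50:50 in that parent's two crosses, regardless of how
rare the variant is in the broader population — this is what decouples
detection power from population allele frequency and motivates the whole
stack. Genotypes are coded **−1** where a segregant carries the reference
parent's allele and **+1** otherwise; a marker whose two parents are
identical within a cross does not segregate there and is missing (NA) for
all of that cross's segregants.

## The synthetic-data generator

The generator reproduces the statistical structure needed to exercise the
methods; it is first-class, tested code with a known ground truth.

* **Site-frequency spectrum.** Panel minor allele frequencies are drawn as
  0.5·Beta(a, b) with a = `sfs_shape` (default 0.5, low-frequency-skewed)
  and b solved numerically so that P(MAF < 0.01) equals `rare_target`
  (default 0.278, a realistic rare fraction for a large yeast collection).
  Minor-allele counts are then binomial, clamped to keep every marker
  biallelic in the panel.
* **Ascertainment.** With `ascertain_in = k`, each marker is conditioned on
  having at least one minor-allele carrier among the k parents. This mirrors
  how cross markers arise in practice — variants are discovered in the
  parents and their frequency looked up in the population panel — and it is
  the reason panel-rare variants segregate in crosses at all. A rare variant
  typically has a single carrier parent and therefore segregates in exactly
  the two crosses containing that parent (the private-variant pattern).
* **Genetic map.** Markers are placed uniformly on chromosomes of
  `chrom_len_cM` centimorgans (default 100) with a constant `bp_per_cM`
  (default 2500). The mapping methods only need marker order and linkage
  decay, so a uniform map is adequate; both knobs matter for linkage
  disequilibrium geometry (see *Problem sizes* below).
* **Meiosis.** Crossovers per chromosome per meiosis are Poisson with mean
  equal to the map length in Morgans, positions uniform in cM, no
  interference. Each progeny chromosome is a two-strand mosaic.
* **Effects.** Causal-marker effect magnitudes are
  `effect_scale · (2·maf·(1−maf))^coupling_tau · |N(0,1)|` per standardized
  genotype: `coupling_tau = 0` decouples effect from frequency;
  negative values give the larger-effects-at-lower-MAF signature of
  negative selection. With probability `sign_bias_recent` the derived
  (non-ancestral) allele's effect is trait-decreasing. The ancestral allele
  is the panel major allele for `ancestral_major_frac` (default 0.8) of
  markers and can be masked as unknown for a configurable fraction.
* **Phenotypes.** Per replicate: additive value + pairwise interaction
  terms + a segregant-level deviate + replicate noise. Within each cross the
  genetic values are rescaled so the realized additive fraction of
  single-replicate variance equals `h2_additive` and the total repeatable
  fraction equals `repeatability`; impossible budgets raise an error. Raw
  replicate values are emitted; standardization happens downstream, per
  cross, as the analyses require.

What the generator does **not** emulate: sequencing error and genotype
uncertainty, segregation distortion, crossover interference, non-uniform
marker density, structural variation, diploidy, and population structure
within the panel beyond the ascertainment conditioning. Tests passing on
this generator therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to those real-data
complications.

## Within-cross mapping

The scan statistic is r², the squared Pearson correlation between the
(covariate-residualized) phenotype and each marker. Significance is
calibrated by the empirical null of the genome-wide maximum over B
permutations of phenotype-to-strain assignment; the empirical p-value is
the fraction of null maxima at or above the observed maximum, floored at
1/B (1e−4 at the conventional within-cross B = 10,000; reduced-B runs stay
calibrated because the floor scales). Forward selection appends each step's
p-value and stops at the **first** step where
FS(k) = −(1/k)·Σ log(1−pᵢ) exceeds `alpha`; the selected set is the prefix
before the exceedance. Numerical details:

* With covariates, scans correlate covariate-regression *residuals* with
  each marker, and permutations shuffle those residuals (Freedman–Lane
  style) rather than the raw phenotype; re-residualizing permuted raw
  phenotypes is available as `scheme = "raw"`. The residual scheme is the
  default because it keeps the per-step null vectorizable and is exact
  under the null of no additional QTL.
* Ties at the maximum statistic resolve to the lowest (chromosome,
  position) index, for determinism.
* p = 1 would make the ForwardStop term infinite; recorded p-values are
  capped just below 1 before the running mean.
* Peak re-localization tries every marker on the peak's chromosome with all
  other peaks as covariates and keeps the residual-sum-of-squares minimizer;
  this can only increase the model likelihood.
* LOD-drop intervals convert r² to LOD = −(n/2)·log₁₀(1−r²), the standard
  correspondence for a Gaussian single-marker model, and extend the
  contiguous run of markers within `drop` (default 1.5) of the peak LOD.
* Cross-validated variance explained re-runs the full stepwise procedure in
  each training fold and evaluates the fitted multi-QTL predictor on the
  held-out fold as 1 − SSE/SST; it is near 0 (possibly negative) for null
  traits and bounded above, on average, by the REML additive variance.

## REML variance components

All mixed models share one fitting routine: y = Xβ + Σᵢ uᵢ + e,
uᵢ ~ N(0, σᵢ²Kᵢ), residual identity on observations appended automatically,
segregant-level kernels expanded through the replicate incidence matrix Z.
Restricted likelihood is maximized by Newton steps using the expected
(Fisher) information with step halving, which guarantees monotone progress;
convergence is declared when the scaled score vanishes or the likelihood
is flat at a full step. Choices worth recording:

* **Non-negativity.** Variances are constrained by projection: a component
  at zero with a negative score is frozen (active set); `constrain = FALSE`
  recovers the unconstrained behavior of classical REML software.
* **Initialization.** Equal split of the phenotypic variance across
  components — scale-free and reproducible.
* **Standard errors** are square roots of the diagonal of the inverse
  Fisher information at the final iteration; shares of variance
  (e.g. rare/(rare+common)) get delta-method errors from the same matrix.
* **Standardization and kinships.** Markers are standardized with
  population moments (divide by n), so MM′/m has average diagonal exactly 1
  and Gower centering (K·n/tr(K)) is consistent with it. Non-segregating
  entries become zeros after standardization, which *is* the exclusion of
  those segregants from genetic covariance. Kinship construction divides by
  the marker count m; the alternative printed convention of dividing by the
  segregant count does not satisfy the average-diagonal-1 property and is
  treated as a transcription slip.
* **Epistasis kernels** are element-wise (Hadamard) products of additive
  kinships, re-Gower-centered; the Schur product theorem keeps them PSD.
  The seven-component model (QTL, genome, QTL∘QTL, QTL∘genome,
  genome∘genome, repeatability, residual) and its reduced form (dropping
  the two QTL interaction terms) are both available.
* **Frequency partitioning** uses per-bin Gower kinships over the joint
  panel with per-cross fixed effects. A marker at exactly the rare/common
  boundary (MAF = 0.01) is common. Equal-count bins are formed by rank, so
  bin sizes differ by at most one.

## Joint mapping

Per trait and cross, variance components are estimated once on the
genome-wide kinship (with the within-cross QTL as fixed effects) and reused
across chromosomes; for each chromosome of interest the phenotype is
residualized by subtracting off-chromosome QTL effects and the
leave-one-chromosome-out polygenic BLUP, then re-standardized per cross.
The pooled statistic for a marker is t = r√(n−2)/√(1−r²) over its
informative segregants (n varies per marker; degrees of freedom n−2), and
−log₁₀ of the two-sided t p-value is the scan statistic, computed in log
space to survive extreme t. Permutations shuffle the residualized
phenotype **within cross only**; both the scan and the null first remove
per-cross means, which makes the procedure exactly invariant to
cross-specific shifts. Selection is ForwardStop as before, with
joint-selected markers entering later steps as regression covariates
(missing covariate entries set to 0, i.e. the cross mean).

Effect sizes are per-cross multiple-regression coefficients of the
standardized phenotype on the −1/+1 peak genotypes, averaged over the
crosses where the peak segregates; under this coding a balanced cross has
genotype variance 1, so variance explained is β². Because the same numbers
are sometimes reported as allele-mean differences, 2β is emitted alongside.
A 9/10 detection / 1/10 estimation split (`unbiased_effects`) removes
winner's-curse inflation; its held-out estimates are attenuated only by
linkage between the selected and causal marker.

With a single cross and residualization disabled, the joint procedure
reduces *exactly* to the within-cross one: at constant n the map from r² to
−log₁₀ p is monotone, so the selected markers and empirical p-values
coincide permutation for permutation.

## Fine-mapping

Only QTL explaining more than 2% of variance (|β| > 0.1414 SD) are
fine-mapped; weaker signals do not localize. For each candidate variant in
the closed ±25 kb window, 500 simulated phenotypes are built as the
observed effect times the candidate's standardized genotype plus a
permutation of the within-cross QTL-model residuals, and the window is
re-scanned. The posterior probability of causality is the normalized
fraction of simulations in which the observed peak is the lead variant.
Numerical choices:

* The re-scan covers the window only, not the genome: all simulated signal
  lies in the window, and this keeps 500·|window| scans inexpensive.
* One set of residual permutations is drawn per window and shared across
  candidate variants, so identical candidate genotypes receive identical
  simulations.
* Lead credit at exactly tied maxima (perfect-LD variants produce
  bitwise-equal statistics) is split evenly among the tied variants — the
  expected assignment under uniform tie-breaking — which makes the
  perfect-LD symmetry exact and the result independent of marker order.
* A window with zero residual variance is degenerate: mass is placed
  uniformly on the variants in perfect LD with the peak, with a warning.
* Variants with zero simulation hits keep probability 0 (no pseudocount).

QTL from crosses sharing a parent, with overlapping (closed-interval)
1.5-LOD-drop confidence intervals and consistent effect signs, are
combined by multiplying per-variant probabilities over the variants shared
and segregating in both crosses, renormalizing to 1. Gene scores sum the
combined probabilities over gene territories — the ORF plus half of each
flanking intergenic span, terminal genes taking the full chromosome-end
span, a variant exactly at a midpoint going to the left gene — and the
gene-level FDR at rank k is the cumulative mean of (1 − score) down the
sorted list. The statistic assumes a single causal variant per window and
error-free effect estimates; violations inflate the reported FDR.

## Population-frequency summaries

Rare means panel MAF strictly below 0.01. The derived (recent) allele is
the one not shared with the outgroup; its panel frequency is the unfolded
frequency, and a variant whose major allele matches the outgroup is recent,
minor-match ancient, no-match unknown (in practice outgroup status resolves
for roughly 80% of variants, and the generator can mask a matching
fraction). Enrichment tables report the *sample* odds ratio ad/bc with the
exact (hypergeometric) two-sided p-value; a zero cell adds a flagged
continuity-corrected ratio. Effect-vs-frequency plots bin QTL by lead-variant
MAF into consecutive groups of ~100 and report mean |effect| ± s.e.m.;
absolute values are used because raw signs depend on the arbitrary allele
orientation.

## Problem sizes used in validation

The suite and the acceptance script run at desk scale, sizes chosen so each
check is statistically meaningful:

* Null calibration: 200 traits × (400 segregants × 500 markers), B = 200.
  Permutation-p uniformity uses 500 traits because the Kolmogorov–Smirnov
  statistic of a perfectly uniform sample of 200 exceeds 0.05 about half
  the time — a sample that size cannot certify uniformity at that level.
* Power and effect-size checks: n = 800, effects 0.2–0.5 SD, 30–100
  replicates; REML recovery at n = 600 with 10–20 replicate traits.
* The frequency-partition recovery uses a 16-chromosome genome at ~1.6 cM
  marker spacing and averages the estimated rare share over 8 replicate
  traits: on a compact, densely-marked genome the rare and common kinships
  become nearly collinear (adjacent-marker LD ≥ 0.99) and the partition is
  not identifiable at n = 1600, and a single REML fit carries a share
  standard error of ~0.15, so replicate averaging is required to resolve a
  ±0.10 recovery band.
* The PICS localization check uses a map of ~600 bp/cM so that a 50 kb
  window holds 20–25 segregating variants at moderate linkage; with much
  denser windows neighboring variants are statistically indistinguishable
  from the causal one at 0.3 SD and n = 800, for any method.

## Known limitations

* Dense REML is O(L³) per iteration; panels beyond a few thousand
  observations need low-rank or eigendecomposition tricks not implemented
  here.
* The joint stepwise residualization is computed once from the within-cross
  QTL set and not refreshed as joint QTL accumulate; strong joint-only QTL
  on other chromosomes therefore remain in the scan noise until selected.
* Pair-only combination of overlapping QTL: a QTL replicated in all three
  crosses of two shared parents contributes as pairs, not as a triple.
* The PICS probability is conditional on the single-causal-variant
  assumption; allelic series within a window split mass across their
  variants and depress gene-level scores.
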