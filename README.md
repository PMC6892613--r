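# rrqtl

Statistical genetics for **round-robin multiparental crosses** of haploid
organisms (budding yeast is the motivating system). A panel of k inbred
parents is crossed in a ring — each parent to exactly two others — and each
cross yields hundreds to a thousand haploid recombinant segregants. The
package maps quantitative trait loci (QTL) in this design, decomposes trait
variance into additive, epistatic and frequency-partitioned components, and
fine-maps QTL to genes, with a synthetic-data generator that reproduces the
design's statistical structure (site-frequency spectrum, marker ascertainment
in the parents, Poisson-crossover meiosis, frequency-coupled effect sizes)
so that every method can be validated against a known ground truth.

## What it implements

**Within-cross QTL mapping.** Linkage at each marker is tested as r², the
squared Pearson correlation between segregant genotypes (coded −1/+1 against
a reference parent) and phenotypes. Significance comes from an empirical
null of the genome-wide maximum statistic over B permutations of
phenotype-to-strain assignment (p floored at 1/B). Markers are added by
forward stepwise selection — each step re-scans conditional on the selected
set and draws a fresh permutation null — and selection stops at the first
step where the ForwardStop statistic

&nbsp;&nbsp;&nbsp;&nbsp;FS(k) = −(1/k) Σᵢ₌₁ᵏ log(1 − pᵢ)

exceeds the target FDR (default 5%). Peaks are re-localized by maximum
likelihood, given 1.5-LOD-drop intervals (LOD = −(n/2)·log₁₀(1−r²)), and
the variance they explain is estimated by 10-fold cross-validation.

**Variance components (REML).** Mixed models y = Xβ + Σᵢ uᵢ + e with
uᵢ ~ N(0, σᵢ² Kᵢ), fitted by Newton iterations with expected (Fisher)
information and step halving; standard errors come from the inverse Fisher
information. Kinships are built from standardized markers (mean 0, variance
1 over the segregants of crosses where the marker segregates) and
Gower-centered — K·n/tr(K), average diagonal exactly 1. Supported models:
the additive model y = a + e; the seven-component replicated model with
detected-QTL, genome-wide, three Hadamard-product epistasis kernels,
segregant repeatability and residual; and the allele-frequency-partitioned
model y = Xβ + r + c + e with separate kinships for rare (panel MAF < 1%)
and common variants, or any number of equal-count MAF bins.

**Joint QTL mapping across crosses.** Phenotypes are standardized per cross
and residualized per chromosome: detected off-chromosome QTL enter as fixed
effects and the leave-one-chromosome-out polygenic background is removed as
a REML-based BLUP. Each marker is then tested with a pooled statistic
t = r·√(n−2)/√(1−r²) over its informative segregants (those from crosses
where it segregates — the source of the power gain for rare variants), with
permutations performed strictly within cross. Selection again uses
ForwardStop; effects are estimated per cross by multiple regression and
averaged, with a 9/10 detection / 1/10 estimation split available to remove
winner's-curse inflation.

**Fine-mapping (PICS-style).** For each strong QTL (> 2% of variance,
i.e. 0.1414 SD), every variant in a 50 kb window around the peak is
simulated as the causal one — observed effect on its standardized genotype
plus permuted model residuals, 500 times — and re-scanned; the fraction of
simulations in which the observed peak is the lead variant, normalized over
the window, is the variant's posterior probability of causality. QTL
replicated in two crosses sharing a parent (overlapping LOD intervals,
consistent sign) are combined by multiplying per-variant probabilities over
the shared variants; probabilities are summed within gene territories (ORF
plus half of each flanking intergenic span) and ranked by the
cumulative-mean posterior error probability, a gene-level FDR.

**Population-frequency analyses.** Rare/common classification (MAF < 0.01),
derived-allele assignment from an outgroup (ancestral = allele shared with
the outgroup), binned mean |effect| vs MAF, Fisher's exact enrichment of
large effects among rare or recent variants, and the fraction of
fitness-decreasing effects among recent vs ancient alleles.

## Worked example

```r
library(rrqtl)

panel  <- simulate_panel(n_strains = 300, n_markers = 1000, n_chroms = 8,
                         rare_target = 0.278, ascertain_in = 8, seed = 1)
design <- build_round_robin(panel, n_parents = 8)
G      <- simulate_cross_genotypes(panel, design, n_progeny = 200, seed = 2)
truth  <- assign_effects(panel, n_qtl = 12, coupling_tau = -0.3,
                         effect_scale = 0.4, sign_bias_recent = 0.75, seed = 3)
ph     <- simulate_phenotypes(G, truth, h2_additive = 0.5,
                              repeatability = 0.8, n_replicates = 2, seed = 4)
y <- ph$segregant_means
```

```
Population panel: 300 strains x 1000 biallelic markers on 8 chromosomes
  rare markers (MAF < 0.01): 29.6%
Recoded genotype matrix: 1600 segregants x 1000 markers, 8 cross(es)
  missing (non-segregating) entries: 68.5%
```

About 30% of markers are rare in the panel and two thirds of genotype
entries are missing — a marker is NA for every segregant of a cross whose
parents carry the same allele. Mapping within one cross:

```r
rows <- which(G$cross == "X02")
segc <- which(!is.na(G$values[rows[1], ]))
Vc   <- G$values[rows, segc]; Vc <- Vc[, apply(Vc, 2, var) > 0]
forward_stepwise(scale(y[rows])[, 1], Vc, alpha = 0.05, B = 1000, seed = 5)
```

```
Forward stepwise QTL trace (alpha = 0.05 ): 1 marker(s) selected
 step        marker index       stat     p forwardstop selected
    1 chr05_0108944   171 0.53603557 0.001   0.0010005     TRUE
    2 chr02_0168528    61 0.02079718 0.921   1.2696540    FALSE
```

One QTL passes: its r² = 0.54 beat all 1,000 permutation maxima
(p = 1/B = 0.001), while the second candidate's p = 0.92 pushes ForwardStop
far above 0.05 and stops the selection. The additive variance component in
the same cross:

```r
M <- standardize_markers(G$values[rows, segc])
fit <- additive_model(y[rows], kinship_gower(M))
```

```
REML variance-component fit (200 observations, 8 iterations, converged)
 component  sigma2      se
         A 0.34652 0.12340
  residual 0.47603 0.05631
restricted log-likelihood: -54.9265
```

giving ĥ² = 0.42 for this cross (replicate means of a trait simulated at
single-replicate h² = 0.5). The joint analysis pools all eight crosses and
recovers more QTL, each with its per-cross effects and panel frequency:

```r
jq  <- joint_forward_stepwise(y, G, alpha = 0.05, B = 500, seed = 6)
estimate_effects_per_cross(y, G, jq$selected)
```

```
                     marker chrom   panel_maf   mean_beta n_crosses
chr05_0108944 chr05_0108944     5 0.010000000  0.69192497         2
chr02_0103367 chr02_0103367     2 0.033333333  0.70636729         2
chr06_0117259 chr06_0117259     6 0.053333333 -0.47210273         2
chr03_0171402 chr03_0171402     3 0.003333333 -0.49481720         2
...
chr06_0046646 chr06_0046646     6 0.103333333 -0.07142808         2
```

Eleven QTL at 5% FDR; most are rare in the panel (large effects were
simulated with negative frequency coupling) and segregate in exactly the
two crosses that contain their carrier parent — the private-variant pattern
the joint analysis is designed to exploit. `run_pipeline(pipeline_config())`
chains all stages (simulation, within-cross scans, variance components,
joint mapping, PICS fine-mapping, frequency summaries) into one manifest.

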