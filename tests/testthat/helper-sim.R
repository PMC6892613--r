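# Fixture builders shared across test files. Everything is generated in code
# at test time; no stored data.

# A single biparental cross: n haploid segregants x m markers, recoded -1/+1
# against parent 1, NA where the parents carry the same allele.
make_cross <- function(n = 200, m = 400, n_chroms = 5, seed = 1, maf = 0.5,
                       len_cM = 100, bp_per_cM = 2500) {
  panel <- simulate_panel(16, m, n_chroms, maf = maf, seed = seed,
                          chrom_len_cM = len_cM, bp_per_cM = bp_per_cM)
  hapA <- panel$haplotypes[1, ]
  hapB <- panel$haplotypes[2, ]
  A <- simulate_meiosis(hapA, hapB, n, panel$markers,
                        len_cM = stats::setNames(panel$chrom_len_cM,
                                                 unique(panel$markers$chrom)),
                        seed = seed + 1)
  V <- matrix(NA_real_, n, m)
  seg <- hapA != hapB
  V[, seg] <- ifelse(A[, seg, drop = FALSE] ==
                       matrix(hapA[seg], n, sum(seg), byrow = TRUE), -1, 1)
  colnames(V) <- panel$markers$id
  list(values = V, markers = panel$markers,
       cross = factor(rep("X01", n)), panel = panel, seg = seg,
       hapA = hapA, hapB = hapB)
}

# Columns of a cross that segregate (non-NA and polymorphic).
seg_cols <- function(cr) {
  which(!apply(cr$values, 2L, anyNA) &
          apply(cr$values, 2L, function(v) stats::var(v) > 0))
}

# A trait with one planted additive QTL of effect `beta` (SD units per
# standardized genotype) at marker column `j`.
planted_trait <- function(cr, j, beta, seed = 1) {
  set.seed(seed)
  g <- cr$values[, j]
  as.numeric(beta * (g - mean(g)) / sqrt(mean((g - mean(g))^2)) +
               sqrt(max(1 - beta^2, 0)) * stats::rnorm(nrow(cr$values)))
}

# A small multi-cross panel with recoded genotypes.
make_panel_design <- function(n_strains = 100, m = 400, n_chroms = 4,
                              n_parents = 4, n_progeny = 150, seed = 1,
                              rare_target = 0.278, sfs_shape = 0.5) {
  panel <- simulate_panel(n_strains, m, n_chroms, sfs_shape = sfs_shape,
                          rare_target = rare_target,
                          ascertain_in = n_parents, seed = seed)
  design <- build_round_robin(panel, n_parents)
  G <- simulate_cross_genotypes(panel, design, n_progeny, seed = seed + 1)
  list(panel = panel, design = design, G = G)
}
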