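#' Assign causal effects to panel markers
#'
#' Draws a set of causal markers with additive effects whose magnitude can be
#' coupled to allele frequency (negative-selection-like architectures) and
#' whose sign can be biased so that the recent (derived, non-ancestral) allele
#' tends to decrease the trait.
#'
#' Effect magnitudes are |effect| = effect_scale * (2*maf*(1-maf))^coupling_tau
#' * |N(0,1)|, so \code{coupling_tau < 0} gives larger effects at lower MAF
#' and \code{coupling_tau = 0} decouples effect size from frequency. Effects
#' are expressed in phenotype-SD units per standardized genotype.
#'
#' @param panel a \code{pop_panel}.
#' @param n_qtl number of causal markers.
#' @param coupling_tau exponent of the heterozygosity coupling (<= 0 typical).
#' @param effect_scale overall magnitude scale.
#' @param sign_bias_recent probability, in [0.5, 1], that the recent allele's
#'   effect is trait-decreasing; markers with unknown ancestral state get a
#'   symmetric random sign.
#' @param seed integer seed.
#' @param candidate_markers optional vector of marker indices (or ids) to
#'   sample causal markers from; defaults to all panel markers.
#' @param epistatic_pairs number of causal marker pairs given an interaction
#'   effect (drawn among the additive causal markers).
#' @param epi_scale magnitude scale of interaction effects.
#' @return an object of class \code{sim_truth}: list with \code{qtl} (data
#'   frame: marker, index, maf, ancestral_allele, effect_minor — the effect of
#'   the panel minor allele — and effect_derived_sign), \code{epistasis}
#'   (data frame of pairs with interaction effects), the targets and the seed.
#' @export
assign_effects <- function(panel, n_qtl, coupling_tau = 0, effect_scale = 0.3,
                           sign_bias_recent = 0.5, seed = 1L,
                           candidate_markers = NULL, epistatic_pairs = 0L,
                           epi_scale = effect_scale) {
  mk <- panel$markers
  if (is.null(candidate_markers)) candidate_markers <- seq_len(nrow(mk))
  if (is.character(candidate_markers))
    candidate_markers <- match(candidate_markers, mk$id)
  if (n_qtl > length(candidate_markers))
    stop("n_qtl exceeds the number of candidate markers")
  if (sign_bias_recent < 0.5 || sign_bias_recent > 1)
    stop("sign_bias_recent must lie in [0.5, 1]")
  set.seed(seed)
  idx <- sort(sample(candidate_markers, n_qtl))
  maf <- mk$panel_maf[idx]
  mag <- effect_scale * (2 * maf * (1 - maf))^coupling_tau * abs(stats::rnorm(n_qtl))

  anc <- mk$ancestral_allele[idx]
  # Sign of the effect carried by the *recent* (non-ancestral) allele.
  s_recent <- ifelse(stats::runif(n_qtl) < sign_bias_recent, -1, 1)
  # Translate into the effect of the panel minor allele (allele 1):
  # ancestral = 0 (major)  -> recent allele is the minor allele
  # ancestral = 1 (minor)  -> recent allele is the major allele
  effect_minor <- ifelse(is.na(anc),
                         ifelse(stats::runif(n_qtl) < 0.5, -1, 1) * mag,
                         ifelse(anc == 0L, s_recent, -s_recent) * mag)
  qtl <- data.frame(marker = mk$id[idx], index = idx, maf = maf,
                    ancestral_allele = anc,
                    effect_minor = effect_minor,
                    effect_derived_sign = ifelse(is.na(anc), NA_real_,
                                                 s_recent),
                    stringsAsFactors = FALSE)
  epi <- NULL
  if (epistatic_pairs > 0) {
    if (2 * epistatic_pairs > n_qtl)
      stop("not enough causal markers for the requested epistatic pairs")
    pick <- matrix(sample(idx, 2L * epistatic_pairs), ncol = 2L)
    epi <- data.frame(marker_a = mk$id[pick[, 1]], marker_b = mk$id[pick[, 2]],
                      index_a = pick[, 1], index_b = pick[, 2],
                      effect = epi_scale * stats::rnorm(epistatic_pairs),
                      stringsAsFactors = FALSE)
  }
  structure(list(qtl = qtl, epistasis = epi, seed = seed,
                 coupling_tau = coupling_tau,
                 sign_bias_recent = sign_bias_recent),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulated genetic architecture:", nrow(x$qtl), "additive QTL")
  if (!is.null(x$epistasis)) cat(",", nrow(x$epistasis), "epistatic pairs")
  cat("\n  effect-frequency coupling tau =", x$coupling_tau,
      "; recent-allele sign bias =", x$sign_bias_recent, "\n")
  invisible(x)
}

#' Simulate replicated phenotypes with a known variance budget
#'
#' Builds per-replicate trait values from the causal architecture: the sum of
#' additive effects on within-cross standardized genotypes, plus pairwise
#' interaction terms, a segregant-level repeatability deviate and replicate
#' measurement noise. Within each cross the genetic values are rescaled so
#' that the realized additive fraction of single-replicate variance equals
#' \code{h2_additive} and the total segregant-level (repeatable) fraction
#' equals \code{repeatability}.
#'
#' @param G a \code{geno_matrix} (recoded -1/+1/NA).
#' @param truth a \code{sim_truth} from \code{\link{assign_effects}}.
#' @param h2_additive target additive fraction of single-replicate variance.
#' @param repeatability target segregant-level fraction (>= h2_additive plus
#'   the realized interaction fraction).
#' @param n_replicates replicate measurements per segregant.
#' @param seed integer seed.
#' @return an object of class \code{sim_pheno}: list with \code{pheno} (long
#'   data frame: segregant, cross, replicate, value), \code{segregant_means},
#'   \code{genetic_value}, \code{additive_value} and per-cross realized
#'   effect sizes (\code{effects_by_cross}, per standardized genotype).
#' @export
simulate_phenotypes <- function(G, truth, h2_additive = 0.5,
                                repeatability = 0.8, n_replicates = 2L,
                                seed = 1L) {
  if (h2_additive < 0 || h2_additive > 1) stop("h2_additive must be in [0,1]")
  if (repeatability < h2_additive || repeatability > 1)
    stop("impossible variance budget: need h2_additive <= repeatability <= 1")
  set.seed(seed)
  V <- G$values
  n <- nrow(V)
  qtl <- truth$qtl
  # effect of the +1 (non-reference) allele at each causal marker
  eff_plus <- ifelse(G$ref_hap[qtl$index] == 0L,
                     qtl$effect_minor, -qtl$effect_minor)

  g_add <- numeric(n)
  g_epi <- numeric(n)
  crosses <- levels(G$cross)
  scale_by_cross <- stats::setNames(numeric(length(crosses)), crosses)
  effects_by_cross <- list()
  for (cr in crosses) {
    rows <- which(G$cross == cr)
    ga <- numeric(length(rows))
    eff_real <- stats::setNames(numeric(0), character(0))
    for (q in seq_len(nrow(qtl))) {
      v <- V[rows, qtl$index[q]]
      if (anyNA(v) || stats::var(v) == 0) next  # non-segregating here
      ga <- ga + eff_plus[q] * .std(v)
      eff_real[qtl$marker[q]] <- eff_plus[q]
    }
    ge <- numeric(length(rows))
    if (!is.null(truth$epistasis)) {
      for (p in seq_len(nrow(truth$epistasis))) {
        va <- V[rows, truth$epistasis$index_a[p]]
        vb <- V[rows, truth$epistasis$index_b[p]]
        if (anyNA(va) || anyNA(vb) ||
            stats::var(va) == 0 || stats::var(vb) == 0) next
        ge <- ge + truth$epistasis$effect[p] * .std(va) * .std(vb)
      }
    }
    va <- mean((ga - mean(ga))^2)
    if (va > 0) {
      s <- sqrt(h2_additive / va)
    } else {
      s <- 0
      if (h2_additive > 0)
        warning("no causal marker segregates in cross ", cr,
                "; its additive variance is 0")
    }
    ga <- s * (ga - mean(ga))
    ge <- s * (ge - mean(ge))
    v_epi <- mean(ge^2)
    if (h2_additive * (va > 0) + v_epi > repeatability)
      stop("impossible variance budget: additive + interaction fraction ",
           "exceeds repeatability in cross ", cr)
    g_add[rows] <- ga
    g_epi[rows] <- ge
    scale_by_cross[cr] <- s
    effects_by_cross[[cr]] <- eff_real * s
  }

  gen <- g_add + g_epi
  v_d <- numeric(n)  # segregant-level non-genetic deviate, per cross budget
  for (cr in crosses) {
    rows <- which(G$cross == cr)
    v_epi <- mean(g_epi[rows]^2)
    v_add <- mean(g_add[rows]^2)
    sd_d <- sqrt(max(repeatability - v_add - v_epi, 0))
    if (sd_d < 1e-7) sd_d <- 0  # guard float dust in a saturated budget
    v_d[rows] <- sd_d * stats::rnorm(length(rows))
  }
  sd_e <- sqrt(1 - repeatability)
  seg_value <- gen + v_d

  reps <- lapply(seq_len(n_replicates), function(r) {
    data.frame(segregant = rownames(V), cross = as.character(G$cross),
               replicate = r,
               value = seg_value + sd_e * stats::rnorm(n),
               stringsAsFactors = FALSE)
  })
  pheno <- do.call(rbind, reps)
  means <- tapply(pheno$value, pheno$segregant, mean)[rownames(V)]
  structure(list(pheno = pheno,
                 segregant_means = as.numeric(means),
                 genetic_value = gen, additive_value = g_add,
                 epistatic_value = g_epi,
                 effects_by_cross = effects_by_cross,
                 h2_additive = h2_additive, repeatability = repeatability,
                 n_replicates = n_replicates, seed = seed),
            class = "sim_pheno")
}

#' @export
print.sim_pheno <- function(x, ...) {
  cat("Simulated phenotypes:", length(x$genetic_value), "segregants x",
      x$n_replicates, "replicates\n")
  cat("  target additive fraction:", x$h2_additive,
      "; repeatability:", x$repeatability, "\n")
  invisible(x)
}
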