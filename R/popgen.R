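#' Classify markers as rare or common by panel MAF
#'
#' Rare means panel MAF strictly below the cutoff (default 0.01); a marker
#' at exactly the cutoff is common. Missing MAF gives "unknown".
#'
#' @param maf numeric vector of panel minor allele frequencies in [0, 0.5].
#' @param cutoff rare/common boundary (default 0.01).
#' @return character vector in \{"rare", "common", "unknown"\}.
#' @export
classify_rare_common <- function(maf, cutoff = 0.01) {
  out <- ifelse(is.na(maf), "unknown", ifelse(maf < cutoff, "rare", "common"))
  if (any(!is.na(maf) & (maf < 0 | maf > 0.5)))
    stop("panel MAF must lie in [0, 0.5]")
  out
}

#' Derived-allele classification against an outgroup
#'
#' The allele matching the outgroup sequence is ancestral; the other allele
#' is derived (recent). The derived frequency is the panel frequency of the
#' non-outgroup allele. A variant whose major allele matches the outgroup is
#' classified recent (its minor allele arose recently); one whose minor
#' allele matches the outgroup is ancient. An outgroup allele matching
#' neither allele gives "unknown".
#'
#' @param major_allele,minor_allele allele labels per marker.
#' @param minor_freq panel frequency of the minor allele.
#' @param outgroup_allele outgroup (ancestral) allele label, NA if unknown.
#' @return data frame with \code{derived_freq} and \code{age_class}
#'   ("recent", "ancient" or "unknown").
#' @export
classify_derived <- function(major_allele, minor_allele, minor_freq,
                             outgroup_allele) {
  n <- length(major_allele)
  derived_freq <- rep(NA_real_, n)
  age <- rep("unknown", n)
  is_major <- !is.na(outgroup_allele) & outgroup_allele == major_allele
  is_minor <- !is.na(outgroup_allele) & outgroup_allele == minor_allele
  derived_freq[is_major] <- minor_freq[is_major]
  age[is_major] <- "recent"
  derived_freq[is_minor] <- 1 - minor_freq[is_minor]
  age[is_minor] <- "ancient"
  data.frame(derived_freq = derived_freq, age_class = age,
             stringsAsFactors = FALSE)
}

#' Mean QTL effect size in allele-frequency bins
#'
#' QTLs are sorted by the panel MAF of their lead variant and grouped into
#' consecutive bins of approximately \code{bin_size} variants; the mean
#' absolute effect and its standard error of the mean are reported per bin.
#'
#' @param maf panel MAF of each QTL lead variant.
#' @param effect QTL effect sizes (absolute value is taken).
#' @param bin_size approximate number of QTLs per bin (default 100).
#' @return data frame: bin, n, mean_maf, mean_abs_effect, sem.
#' @export
bin_effects_by_frequency <- function(maf, effect, bin_size = 100L) {
  if (!length(maf)) stop("at least one QTL needed")
  o <- order(maf)
  maf <- maf[o]; eff <- abs(effect[o])
  n_bins <- max(1L, round(length(maf) / bin_size))
  bin <- ceiling(seq_along(maf) * n_bins / length(maf))
  agg <- function(f) as.numeric(tapply(f, bin, mean))
  sem <- as.numeric(tapply(eff, bin, function(x)
    stats::sd(x) / sqrt(length(x))))
  data.frame(bin = seq_len(n_bins),
             n = as.integer(table(bin)),
             mean_maf = agg(maf),
             mean_abs_effect = agg(eff),
             sem = sem)
}

#' Two-by-two enrichment test
#'
#' Sample odds ratio (ad/bc) and two-sided exact hypergeometric p-value
#' (Fisher's exact test). With a zero cell, a continuity-corrected odds
#' ratio (adding 0.5 to every cell) is reported alongside and flagged.
#'
#' @param table 2x2 integer matrix of counts.
#' @return list with \code{odds_ratio}, \code{p}, and (when a cell is zero)
#'   \code{odds_ratio_cc} and \code{flagged = TRUE}; a zero margin makes the
#'   odds ratio NA with \code{undefined = TRUE}.
#' @export
enrichment_test <- function(table) {
  table <- as.matrix(table)
  if (!all(table >= 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(odds_ratio = NA_real_, p = NA_real_, undefined = TRUE))
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  p <- stats::fisher.test(table)$p.value
  out <- list(odds_ratio = or, p = p)
  if (any(table == 0)) {
    tc <- table + 0.5
    out$odds_ratio_cc <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
    out$flagged <- TRUE
  }
  out
}

#' Effect-size threshold equivalent to a variance fraction
#'
#' Under -1/+1 coding in a balanced cross the genotype has variance 1, so a
#' QTL explaining a fraction v of phenotypic variance has an effect of
#' sqrt(v) SD units (0.02 corresponds to 0.1414 SD).
#'
#' @param var_frac fraction of phenotypic variance in [0, 1].
#' @return effect size in SD units per standardized genotype.
#' @export
effect_threshold_from_variance <- function(var_frac) {
  if (any(var_frac < 0 | var_frac > 1)) stop("var_frac must lie in [0, 1]")
  sqrt(var_frac)
}

#' Direction of derived-allele effects by age class
#'
#' Counts fitness-decreasing vs fitness-increasing QTL effects (signed on
#' the derived allele) within the recent and ancient age classes and runs
#' the 2x2 enrichment test. QTLs with unknown age class are excluded and
#' counted.
#'
#' @param age_class "recent"/"ancient"/"unknown" per QTL.
#' @param effect_derived QTL effect signed on the derived allele.
#' @return list with the 2x2 \code{counts} (rows recent/ancient, columns
#'   decrease/increase), per-class decrease fractions, the
#'   \code{enrichment} result, the decrease-fraction \code{ratio}
#'   (recent/ancient; NA-flagged when a class is empty) and
#'   \code{n_excluded}.
#' @export
direction_summary <- function(age_class, effect_derived) {
  keep <- age_class %in% c("recent", "ancient") & !is.na(effect_derived)
  n_excluded <- sum(!keep)
  a <- age_class[keep]; e <- effect_derived[keep]
  counts <- rbind(recent = c(decrease = sum(a == "recent" & e < 0),
                             increase = sum(a == "recent" & e >= 0)),
                  ancient = c(decrease = sum(a == "ancient" & e < 0),
                              increase = sum(a == "ancient" & e >= 0)))
  frac <- counts[, "decrease"] / pmax(rowSums(counts), 1)
  ratio <- if (any(rowSums(counts) == 0))
    structure(NA_real_, undefined = TRUE)
  else frac["recent"] / frac["ancient"]
  list(counts = counts,
       decrease_fraction = frac,
       ratio = ratio,
       enrichment = if (all(rowSums(counts) > 0) && all(colSums(counts) > 0))
         enrichment_test(counts) else NULL,
       n_excluded = n_excluded)
}
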