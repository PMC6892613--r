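#' Simulate a population panel of haploid strains
#'
#' Generates a panel of haploid strains genotyped at biallelic markers, with
#' per-marker minor allele frequencies drawn from a Beta-family site-frequency
#' spectrum tuned so that an expected fraction \code{rare_target} of markers is
#' rare (panel MAF < 0.01). The panel plays the role of a large reference
#' collection in which marker frequencies and ancestral (outgroup) alleles are
#' looked up.
#'
#' Allele 0 is the panel major allele, allele 1 the minor allele, so
#' \code{panel_maf} is the realized frequency of allele 1. The ancestral allele
#' is the major allele for a fraction \code{ancestral_major_frac} of markers
#' (the rest are ancient minor alleles), and is set to unknown for a fraction
#' \code{unknown_frac}, mimicking incomplete outgroup alignment.
#'
#' With \code{ascertain_in = k}, every marker is conditioned on having at least
#' one minor-allele carrier among the first \code{k} strains. This emulates
#' marker ascertainment in the cross parents: variants are discovered in the
#' parents and their frequency is looked up in the panel, so even panel-rare
#' variants segregate in crosses.
#'
#' @param n_strains number of haploid strains in the panel (>= 16).
#' @param n_markers number of biallelic markers.
#' @param n_chroms number of chromosomes; markers are split evenly.
#' @param sfs_shape first Beta shape parameter of the frequency spectrum;
#'   values < 1 skew mass towards low frequencies.
#' @param rare_target expected fraction of markers with MAF < 0.01.
#' @param ancestral_major_frac fraction of (known-status) markers whose
#'   ancestral allele is the panel major allele.
#' @param unknown_frac fraction of markers with unknown ancestral state.
#' @param chrom_len_cM genetic length of each chromosome in centimorgans
#'   (recycled to \code{n_chroms}).
#' @param bp_per_cM physical bases per centimorgan (uniform map).
#' @param ascertain_in if non-NULL, number of leading strains (the parent
#'   pool) forced to contain at least one minor-allele carrier per marker.
#' @param maf optional vector of forced minor allele frequencies (recycled
#'   to \code{n_markers}), bypassing the site-frequency-spectrum draw.
#' @param seed integer seed; the output is reproducible given the seed.
#' @return an object of class \code{pop_panel}: a list with \code{n_strains},
#'   \code{markers} (data frame: id, chrom, pos_bp, pos_cM, ref_allele,
#'   alt_allele, panel_maf, ancestral_allele) and \code{haplotypes}
#'   (strains x markers 0/1 matrix).
#' @export
simulate_panel <- function(n_strains, n_markers, n_chroms = 4L,
                           sfs_shape = 0.5, rare_target = 0.278,
                           ancestral_major_frac = 0.8, unknown_frac = 0,
                           chrom_len_cM = 100, bp_per_cM = 2500,
                           ascertain_in = NULL, maf = NULL, seed = 1L) {
  if (n_strains < 16) stop("n_strains must be at least 16")
  if (n_markers < n_chroms) stop("n_markers must be >= n_chroms")
  if (sfs_shape <= 0) stop("sfs_shape must be positive")
  if (!is.numeric(rare_target) || rare_target <= 0 || rare_target >= 1)
    stop("rare_target must lie strictly inside (0, 1)")
  if (unknown_frac < 0 || unknown_frac > 1) stop("unknown_frac in [0,1]")

  set.seed(seed)
  if (is.null(maf)) {
    # Solve for the second Beta shape so that P(MAF < 0.01) = rare_target,
    # where MAF = 0.5 * B and B ~ Beta(sfs_shape, b). pbeta(0.02, a, b) is
    # monotone increasing in b.
    f <- function(b) stats::pbeta(0.02, sfs_shape, b) - rare_target
    if (f(1e-6) > 0) {
      b_shape <- 1e-6
    } else {
      b_shape <- stats::uniroot(f, c(1e-6, 1e6), tol = 1e-10)$root
    }
    maf <- 0.5 * stats::rbeta(n_markers, sfs_shape, b_shape)
  } else {
    maf <- rep_len(maf, n_markers)
  }
  maf <- pmin(pmax(maf, 1e-6), 0.5)

  # Minor-allele counts: binomial draw clamped to keep every marker biallelic
  # in the panel and allele 1 the minor allele; a forced MAF of exactly 0.5
  # gives exact balanced counts.
  k <- stats::rbinom(n_markers, n_strains, maf)
  k[maf == 0.5] <- floor(n_strains / 2)
  k <- pmin(pmax(k, 1L), floor(n_strains / 2))

  H <- matrix(0L, n_strains, n_markers)
  if (!is.null(ascertain_in)) {
    if (ascertain_in < 1 || ascertain_in > n_strains)
      stop("ascertain_in must index a leading subset of strains")
    for (j in seq_len(n_markers)) {
      forced <- sample.int(ascertain_in, 1L)
      rest <- if (k[j] > 1L)
        sample(setdiff(seq_len(n_strains), forced), k[j] - 1L) else integer(0)
      H[c(forced, rest), j] <- 1L
    }
  } else {
    for (j in seq_len(n_markers)) {
      H[sample.int(n_strains, k[j]), j] <- 1L
    }
  }
  panel_maf <- colMeans(H)

  # Ancestral state: major allele (0) ancestral for most markers.
  anc <- ifelse(stats::runif(n_markers) < ancestral_major_frac, 0L, 1L)
  if (unknown_frac > 0)
    anc[stats::runif(n_markers) < unknown_frac] <- NA_integer_

  # Marker map: even split over chromosomes, uniform cM/bp.
  chrom_len_cM <- rep_len(chrom_len_cM, n_chroms)
  chrom <- sort(rep_len(seq_len(n_chroms), n_markers))
  pos_cM <- numeric(n_markers)
  pos_bp <- integer(n_markers)
  for (c in seq_len(n_chroms)) {
    idx <- which(chrom == c)
    p <- sort(stats::runif(length(idx), 0, chrom_len_cM[c]))
    pos_cM[idx] <- p
    pos_bp[idx] <- pmax(1L, as.integer(round(p * bp_per_cM)))
  }

  markers <- data.frame(
    id = sprintf("chr%02d_%07d", chrom, pos_bp),
    chrom = chrom, pos_bp = pos_bp, pos_cM = pos_cM,
    ref_allele = "A", alt_allele = "B",
    panel_maf = panel_maf, ancestral_allele = anc,
    stringsAsFactors = FALSE
  )
  # De-duplicate accidental id collisions at the same rounded bp.
  markers$id <- make.unique(markers$id, sep = "_")

  structure(list(n_strains = n_strains, markers = markers, haplotypes = H,
                 chrom_len_cM = chrom_len_cM, seed = seed),
            class = "pop_panel")
}

#' @export
print.pop_panel <- function(x, ...) {
  cat("Population panel:", x$n_strains, "strains x", nrow(x$markers),
      "biallelic markers on", length(x$chrom_len_cM), "chromosomes\n")
  rare <- mean(x$markers$panel_maf < 0.01)
  cat(sprintf("  rare markers (MAF < 0.01): %.1f%%\n", 100 * rare))
  invisible(x)
}

#' Build a round-robin cross design
#'
#' Arranges parents in a ring so that each parent is crossed to exactly two
#' others, giving as many crosses as parents.
#'
#' @param panel a \code{pop_panel}.
#' @param n_parents number of parents (>= 3); the first \code{n_parents}
#'   strains of the panel are used unless \code{parents} is given.
#' @param parents optional explicit strain indices to use as parents.
#' @return an object of class \code{cross_design}: list with \code{parents}
#'   (strain indices) and \code{crosses} (data frame: cross, parent_a,
#'   parent_b).
#' @export
build_round_robin <- function(panel, n_parents = 16L, parents = NULL) {
  if (is.null(parents)) parents <- seq_len(n_parents)
  n_parents <- length(parents)
  if (n_parents < 3) stop("a round robin needs at least 3 parents")
  if (anyDuplicated(parents)) stop("duplicate parent ids in design")
  if (max(parents) > panel$n_strains) stop("parent index outside panel")
  nxt <- c(parents[-1], parents[1])
  crosses <- data.frame(
    cross = sprintf("X%02d", seq_len(n_parents)),
    parent_a = parents, parent_b = nxt,
    stringsAsFactors = FALSE
  )
  structure(list(parents = parents, crosses = crosses), class = "cross_design")
}

#' @export
print.cross_design <- function(x, ...) {
  cat("Round-robin design:", length(x$parents), "parents,",
      nrow(x$crosses), "crosses (each parent in exactly 2 crosses)\n")
  invisible(x)
}
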