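#' Simulation-based posterior probability of causality within a QTL window
#'
#' For each candidate variant in a window centered on a detected QTL peak,
#' simulates the observed effect size on that variant's standardized
#' genotype against permuted model residuals, re-scans the window, and
#' records the fraction of simulations in which the observed peak marker is
#' the lead variant. With equal priors on causality and on lead status,
#' normalizing these fractions to sum 1 over the window gives each variant's
#' posterior probability of being the causal one.
#'
#' Only QTL above the effect-size gate (by default 0.1414 SD, i.e. 2% of
#' phenotypic variance) are intended to be fine-mapped; the gate is the
#' caller's responsibility.
#'
#' @param G a \code{geno_matrix} restricted to one cross (or a plain matrix
#'   plus \code{markers}).
#' @param peak marker index (or id) of the observed QTL peak.
#' @param effect observed QTL effect in SD units per standardized genotype.
#' @param residuals residuals of the within-cross multi-QTL model (length =
#'   number of segregants); their empirical distribution is the noise model.
#' @param n_sims simulations per candidate variant (default 500).
#' @param window_kb total window width in kb (default 50: peak +/- 25 kb).
#' @param seed integer seed.
#' @param markers marker data frame when G is a plain matrix.
#' @return object of class \code{pics_window}: list with \code{window}
#'   (marker indices), \code{ppc} (normalized posterior probabilities,
#'   summing to 1), \code{hits} (raw lead fractions), \code{peak},
#'   \code{effect}, \code{n_sims}, \code{degenerate} flag.
#' @export
pics_window <- function(G, peak, effect, residuals, n_sims = 500L,
                        window_kb = 50, seed = 1L, markers = NULL) {
  V <- if (is.list(G) && !is.null(G$values)) G$values else G
  if (is.null(markers) && is.list(G)) markers <- G$markers
  if (is.null(markers)) stop("marker map (chrom, pos_bp) required")
  if (is.character(peak)) peak <- match(peak, colnames(V))
  half_bp <- window_kb * 1000 / 2
  win <- which(markers$chrom == markers$chrom[peak] &
                 abs(markers$pos_bp - markers$pos_bp[peak]) <= half_bp)
  win <- win[vapply(win, function(j) {
    v <- V[, j]
    !anyNA(v) && stats::var(v) > 0
  }, logical(1))]
  if (!length(win)) stop("empty fine-mapping window")
  n <- nrow(V)
  Mw <- .std_cols(V[, win, drop = FALSE])
  peak_pos <- match(peak, win)
  set.seed(seed)
  degenerate <- stats::var(residuals) == 0
  if (degenerate) {
    # no noise: probability mass on variants in perfect LD with the peak
    ld <- abs(crossprod(Mw, Mw[, peak_pos]) / n)
    hits <- as.numeric(ld > 1 - 1e-12)
    ppc <- hits / sum(hits)
    warning("zero residual variance: degenerate window, mass on perfect-LD ",
            "variants")
  } else {
    res_c <- residuals - mean(residuals)
    # one permutation of the residuals per simulation, shared across
    # candidate variants (so identical candidate genotypes get identical
    # simulated phenotypes)
    E <- matrix(res_c[vapply(seq_len(n_sims),
                             function(b) sample.int(n), integer(n))],
                n, n_sims)
    hits <- numeric(length(win))
    for (v in seq_along(win)) {
      Y <- effect * Mw[, v] + E
      Y <- sweep(Y, 2L, colMeans(Y), "-")
      sdy <- sqrt(colMeans(Y^2))
      Y <- sweep(Y, 2L, sdy, "/")
      R2 <- (crossprod(Mw, Y) / n)^2
      # lead credit is split evenly among exactly tied maxima (variants in
      # perfect LD give bitwise-equal statistics), so the hit fraction is
      # the expected one under uniform tie-breaking and does not depend on
      # marker order
      mx <- apply(R2, 2L, max)
      tied <- R2 == rep(mx, each = nrow(R2))
      hits[v] <- mean(tied[peak_pos, ] / colSums(tied))
    }
    if (sum(hits) == 0) {
      ppc <- rep(0, length(win))
      ppc[peak_pos] <- 1
      warning("no simulation reproduced the observed lead; defaulting mass ",
              "to the peak")
    } else {
      ppc <- hits / sum(hits)
    }
  }
  structure(list(window = win, marker = markers$id[win],
                 ppc = stats::setNames(ppc, markers$id[win]),
                 hits = hits, peak = peak, peak_marker = markers$id[peak],
                 effect = effect, n_sims = n_sims, seed = seed,
                 degenerate = degenerate),
            class = "pics_window")
}

#' @export
print.pics_window <- function(x, ...) {
  cat("PICS window around", x$peak_marker, ":", length(x$window),
      "variants,", x$n_sims, "simulations each\n")
  top <- order(x$ppc, decreasing = TRUE)[1:min(3, length(x$ppc))]
  cat("  top variants:",
      paste(sprintf("%s (%.2f)", names(x$ppc)[top], x$ppc[top]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Find overlapping QTL between crosses sharing a parent
#'
#' Two QTL (same trait) qualify as overlapping when their crosses share a
#' parent, their 1.5-LOD-drop confidence intervals overlap (closed
#' intervals, in bp), and their effect directions agree under the common
#' allele orientation.
#'
#' @param qtl data frame with columns cross, chrom, left_bp, right_bp,
#'   effect, and an id column (e.g. peak marker); one row per QTL, one trait.
#' @param design a \code{cross_design}.
#' @return data frame of qualifying row-index pairs (i, j).
#' @export
find_overlapping_qtl <- function(qtl, design) {
  cr <- design$crosses
  parents_of <- function(cid) {
    r <- cr[cr$cross == cid, ]
    c(r$parent_a, r$parent_b)
  }
  pairs <- list()
  n <- nrow(qtl)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (qtl$cross[i] == qtl$cross[j]) next
    if (!length(intersect(parents_of(qtl$cross[i]),
                          parents_of(qtl$cross[j])))) next
    if (qtl$chrom[i] != qtl$chrom[j]) next
    if (qtl$right_bp[i] < qtl$left_bp[j] ||
        qtl$right_bp[j] < qtl$left_bp[i]) next  # closed-interval overlap
    if (sign(qtl$effect[i]) != sign(qtl$effect[j])) next
    pairs[[length(pairs) + 1L]] <- data.frame(i = i, j = j)
  }
  if (!length(pairs)) return(data.frame(i = integer(0), j = integer(0)))
  do.call(rbind, pairs)
}

#' Combine causality probabilities of a cross pair
#'
#' Elementwise product of the two windows' posterior probabilities over the
#' variants shared (and segregating) in both crosses, renormalized to sum 1.
#'
#' @param w1,w2 \code{pics_window} objects.
#' @return named numeric vector of combined probabilities, or NULL (with a
#'   warning) when no variant is shared.
#' @export
combine_cross_pair <- function(w1, w2) {
  shared <- intersect(names(w1$ppc), names(w2$ppc))
  if (!length(shared)) {
    warning("no shared segregating variant between the two windows; ",
            "pair dropped")
    return(NULL)
  }
  p <- w1$ppc[shared] * w2$ppc[shared]
  if (sum(p) == 0) return(stats::setNames(rep(0, length(shared)), shared))
  p / sum(p)
}

#' Assign variant probabilities to gene territories and sum per gene
#'
#' A gene's territory is its open reading frame plus half of each flanking
#' intergenic span; the first and last genes of a chromosome take the full
#' terminal spans. A variant exactly midway between two ORFs is assigned to
#' the left gene. Gene score = sum of assigned variant probabilities.
#'
#' @param ppc named numeric vector of combined variant probabilities; names
#'   must resolve in \code{markers}.
#' @param genes data frame with columns gene, chrom, start, end (1-based,
#'   inclusive), non-overlapping within a chromosome.
#' @param markers marker data frame (id, chrom, pos_bp).
#' @return data frame: gene, ppc_gene, sorted as in \code{genes}.
#' @export
aggregate_to_genes <- function(ppc, genes, markers) {
  idx <- match(names(ppc), markers$id)
  if (anyNA(idx)) stop("unknown variant id in ppc")
  chrom <- unique(markers$chrom[idx])
  if (length(chrom) > 1) stop("window spans multiple chromosomes")
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) stop("no gene annotation for chromosome ", chrom)
  g <- g[order(g$start), , drop = FALSE]
  # Territory boundaries: midpoint between consecutive ORFs; a variant at
  # the exact midpoint falls to the left gene (boundary is inclusive-left).
  bounds <- (g$end[-nrow(g)] + g$start[-1]) / 2
  pos <- markers$pos_bp[idx]
  assign <- findInterval(pos, bounds, left.open = TRUE) + 1L
  score <- vapply(seq_len(nrow(g)),
                  function(i) sum(ppc[assign == i]), numeric(1))
  data.frame(gene = g$gene, ppc_gene = score, stringsAsFactors = FALSE)
}

#' Gene-level FDR by cumulative-mean posterior error probability
#'
#' Genes are sorted by decreasing posterior probability of causality; the
#' posterior error probability is 1 - ppc and the FDR at rank k is the mean
#' PEP of the top k genes.
#'
#' @param gene_scores data frame with columns gene and ppc_gene (possibly
#'   pooled over many combined QTL windows).
#' @return the data frame sorted by decreasing ppc_gene with columns rank,
#'   pep and fdr added.
#' @export
gene_fdr <- function(gene_scores) {
  o <- order(gene_scores$ppc_gene, decreasing = TRUE)
  out <- gene_scores[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$pep <- 1 - out$ppc_gene
  out$fdr <- cumsum(out$pep) / out$rank
  rownames(out) <- NULL
  out
}
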