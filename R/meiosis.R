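#' Simulate haploid meiotic progeny of two parents
#'
#' Each progeny chromosome is a mosaic of the two parental haplotypes. The
#' number of crossovers per chromosome per meiosis is Poisson with mean equal
#' to the chromosome's genetic length in Morgans (cM / 100), crossover
#' positions are uniform on the genetic map, and there is no interference.
#'
#' @param hapA,hapB parental haplotypes: integer vectors of 0/1 alleles
#'   aligned to the same marker list.
#' @param n_progeny number of haploid progeny to generate.
#' @param map data frame with columns \code{chrom} and \code{pos_cM} aligned
#'   to the haplotypes; chromosome length defaults to the max position unless
#'   a \code{len_cM} attribute or argument supplies it.
#' @param len_cM optional named vector of chromosome genetic lengths (cM).
#' @param seed integer seed.
#' @param return_strands if TRUE, attach the latent strand-origin matrix and
#'   simulated crossover counts as attributes (used for invariant checks).
#' @return an \code{n_progeny x n_markers} integer matrix of 0/1 alleles.
#' @export
simulate_meiosis <- function(hapA, hapB, n_progeny, map, len_cM = NULL,
                             seed = 1L, return_strands = FALSE) {
  if (length(hapA) != length(hapB) || length(hapA) != nrow(map))
    stop("parental haplotypes and marker map have mismatched lengths")
  set.seed(seed)
  m <- length(hapA)
  chroms <- unique(map$chrom)
  if (is.null(len_cM)) {
    len_cM <- vapply(chroms, function(c) max(map$pos_cM[map$chrom == c]),
                     numeric(1))
    names(len_cM) <- as.character(chroms)
  }
  strands <- matrix(0L, n_progeny, m)  # 0 = from A, 1 = from B
  n_co <- matrix(0L, n_progeny, length(chroms),
                 dimnames = list(NULL, as.character(chroms)))
  for (ci in seq_along(chroms)) {
    c <- chroms[ci]
    idx <- which(map$chrom == c)
    pos <- map$pos_cM[idx]
    L <- len_cM[[as.character(c)]]
    k <- stats::rpois(n_progeny, L / 100)
    start <- stats::rbinom(n_progeny, 1L, 0.5)
    for (i in seq_len(n_progeny)) {
      if (k[i] == 0L || L <= 0) {
        strands[i, idx] <- start[i]
      } else {
        co <- sort(stats::runif(k[i], 0, L))
        # strand at a marker flips once per crossover to its left
        strands[i, idx] <- (start[i] + findInterval(pos, co)) %% 2L
      }
    }
    n_co[, ci] <- k
  }
  G <- matrix(hapA, n_progeny, m, byrow = TRUE)
  GB <- matrix(hapB, n_progeny, m, byrow = TRUE)
  G[strands == 1L] <- GB[strands == 1L]
  storage.mode(G) <- "integer"
  if (return_strands) {
    attr(G, "strands") <- strands
    attr(G, "n_crossovers") <- n_co
  }
  G
}

#' Simulate recoded segregant genotypes for a whole cross design
#'
#' Runs \code{\link{simulate_meiosis}} for every cross of a round-robin design
#' and recodes the progeny alleles against a reference parent: -1 where the
#' segregant carries the reference strain's allele, +1 otherwise. Markers at
#' which the two parents of a cross carry identical alleles do not segregate
#' in that cross and are set missing (NA) for its segregants.
#'
#' @param panel a \code{pop_panel}.
#' @param design a \code{cross_design}.
#' @param n_progeny progeny per cross (scalar or vector, one per cross).
#' @param reference strain index of the reference parent (default: first
#'   parent of the design).
#' @param seed integer seed.
#' @return an object of class \code{geno_matrix}: list with \code{values}
#'   (segregants x markers matrix in -1/+1/NA), \code{cross} (factor),
#'   \code{markers}, \code{ref_hap} (reference parent's 0/1 haplotype) and
#'   \code{design}.
#' @export
simulate_cross_genotypes <- function(panel, design, n_progeny,
                                     reference = design$parents[1],
                                     seed = 1L) {
  crosses <- design$crosses
  n_progeny <- rep_len(n_progeny, nrow(crosses))
  ref_hap <- panel$haplotypes[reference, ]
  vals <- vector("list", nrow(crosses))
  labs <- vector("list", nrow(crosses))
  for (i in seq_len(nrow(crosses))) {
    hapA <- panel$haplotypes[crosses$parent_a[i], ]
    hapB <- panel$haplotypes[crosses$parent_b[i], ]
    A <- simulate_meiosis(hapA, hapB, n_progeny[i], panel$markers,
                          len_cM = stats::setNames(panel$chrom_len_cM,
                                                   unique(panel$markers$chrom)),
                          seed = .subseed(seed, i))
    V <- matrix(NA_real_, n_progeny[i], ncol(A))
    seg <- hapA != hapB
    V[, seg] <- ifelse(A[, seg, drop = FALSE] ==
                         matrix(ref_hap[seg], n_progeny[i], sum(seg),
                                byrow = TRUE), -1, 1)
    vals[[i]] <- V
    labs[[i]] <- rep(crosses$cross[i], n_progeny[i])
  }
  values <- do.call(rbind, vals)
  colnames(values) <- panel$markers$id
  rownames(values) <- sprintf("%s_s%04d", unlist(labs),
                              unlist(lapply(n_progeny, seq_len)))
  structure(list(values = values,
                 cross = factor(unlist(labs), levels = crosses$cross),
                 markers = panel$markers, ref_hap = ref_hap,
                 reference = reference, design = design),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("Recoded genotype matrix:", nrow(x$values), "segregants x",
      ncol(x$values), "markers,", nlevels(x$cross), "cross(es)\n")
  cat(sprintf("  missing (non-segregating) entries: %.1f%%\n",
              100 * mean(is.na(x$values))))
  invisible(x)
}

# Internal: logical markers-by-crosses segregation table.
.segregation_table <- function(G) {
  crosses <- levels(G$cross)
  seg <- matrix(FALSE, ncol(G$values), length(crosses),
                dimnames = list(colnames(G$values), crosses))
  for (cr in crosses) {
    rows <- which(G$cross == cr)
    seg[, cr] <- !is.na(G$values[rows[1], ])
  }
  seg
}
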