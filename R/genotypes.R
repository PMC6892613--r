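#' Recode biallelic genotypes against a reference strain
#'
#' Codes each segregant's allele as -1 where it matches the reference strain
#' and +1 where it does not. Markers at which the two parents of a cross carry
#' the same allele do not segregate there and are set missing (NA) for all
#' segregants of that cross.
#'
#' @param alleles segregants x markers matrix of allele codes (any atomic
#'   type; each marker must show at most two distinct alleles).
#' @param ref_allele per-marker allele of the reference strain.
#' @param cross factor of per-segregant cross labels.
#' @param markers optional marker data frame carried along.
#' @param mark_nonsegregating set markers fixed within a cross to NA for
#'   that cross (default TRUE); FALSE keeps the raw -1/+1 coding.
#' @return a \code{geno_matrix}.
#' @export
recode_biallelic <- function(alleles, ref_allele, cross,
                             markers = NULL, mark_nonsegregating = TRUE) {
  if (length(ref_allele) != ncol(alleles))
    stop("ref_allele must have one entry per marker")
  if (length(cross) != nrow(alleles))
    stop("cross labels must have one entry per segregant")
  cross <- as.factor(cross)
  nall <- apply(alleles, 2L, function(a) length(unique(a[!is.na(a)])))
  if (any(nall > 2L))
    stop("multi-allelic marker(s): ", paste(which(nall > 2L)[1]))
  if (anyNA(ref_allele)) stop("unknown reference allele at some markers")
  V <- ifelse(alleles == matrix(ref_allele, nrow(alleles), ncol(alleles),
                                byrow = TRUE), -1, 1)
  if (mark_nonsegregating) for (cr in levels(cross)) {
    rows <- which(cross == cr)
    fixed <- apply(V[rows, , drop = FALSE], 2L,
                   function(v) length(unique(v[!is.na(v)])) < 2L)
    V[rows, fixed] <- NA_real_
  }
  colnames(V) <- if (!is.null(markers)) markers$id else colnames(alleles)
  structure(list(values = V, cross = cross, markers = markers,
                 ref_hap = NULL, design = NULL),
            class = "geno_matrix")
}

#' Standardize marker genotypes to mean 0, variance 1
#'
#' Each marker column is centered and scaled over its standardization scope:
#' either within each cross separately, or jointly over the segregants of all
#' crosses in which the marker segregates. Variance is the population moment
#' (divide by n), so a balanced -1/+1 column is left unchanged. Entries
#' outside a marker's scope (non-segregating crosses) are set to 0, which
#' removes those segregants from any genetic covariance computed from the
#' matrix. Markers constant over their entire scope are excluded with a
#' warning.
#'
#' @param G a \code{geno_matrix} or a plain numeric matrix (single cross).
#' @param scope \code{"joint"} (default) or \code{"cross"}.
#' @return a numeric matrix with attributes \code{scope} and
#'   \code{excluded} (ids/indices of dropped constant markers).
#' @export
standardize_markers <- function(G, scope = c("joint", "cross")) {
  scope <- match.arg(scope)
  if (is.matrix(G)) G <- list(values = G, cross = factor(rep("X", nrow(G))))
  V <- G$values
  M <- matrix(0, nrow(V), ncol(V), dimnames = dimnames(V))
  keep <- rep(TRUE, ncol(V))
  if (scope == "joint") {
    for (j in seq_len(ncol(V))) {
      obs <- which(!is.na(V[, j]))
      if (length(obs) < 2L) { keep[j] <- FALSE; next }
      x <- V[obs, j]
      if (stats::var(x) == 0) { keep[j] <- FALSE; next }
      M[obs, j] <- .std(x)
    }
  } else {
    cross <- as.factor(G$cross)
    any_used <- rep(FALSE, ncol(V))
    for (cr in levels(cross)) {
      rows <- which(cross == cr)
      for (j in seq_len(ncol(V))) {
        x <- V[rows, j]
        if (anyNA(x) || stats::var(x) == 0) next
        M[rows, j] <- .std(x)
        any_used[j] <- TRUE
      }
    }
    keep <- any_used
  }
  if (any(!keep)) {
    warning(sum(!keep), " marker(s) fixed over their scope were excluded")
    M <- M[, keep, drop = FALSE]
  }
  attr(M, "scope") <- scope
  attr(M, "excluded") <- colnames(V)[!keep]
  M
}

#' Marker-count normalized kinship
#'
#' K = MM'/m for an n x m standardized genotype matrix, so that with
#' population-moment standardization the average diagonal is 1.
#'
#' @param M standardized genotype matrix.
#' @return a \code{kinship} matrix (attribute \code{normalization} =
#'   \code{"per-marker"}).
#' @export
kinship_simple <- function(M) {
  if (ncol(M) == 0L) stop("no markers")
  K <- tcrossprod(M) / ncol(M)
  structure(K, normalization = "per-marker", class = c("kinship", "matrix"))
}

#' Gower-center a relatedness matrix
#'
#' Rescales a cross-product matrix K to K * n / tr(K), which makes the
#' average diagonal coefficient exactly 1 (trace = n). Idempotent.
#'
#' @param K square symmetric matrix (e.g. MM').
#' @return a \code{kinship} with \code{normalization = "gower"}.
#' @export
gower_center <- function(K) {
  if (nrow(K) != ncol(K)) stop("K must be square")
  tr <- sum(diag(K))
  if (tr <= 0) stop("trace of K is not positive; cannot Gower-center")
  K <- K * (nrow(K) / tr)
  structure(as.matrix(K), normalization = "gower",
            class = c("kinship", "matrix"))
}

#' Gower-centered kinship from standardized markers
#'
#' @param M standardized genotype matrix (n x m).
#' @return \code{gower_center(MM')}.
#' @export
kinship_gower <- function(M) {
  if (ncol(M) == 0L) stop("no markers")
  gower_center(tcrossprod(M))
}

#' Hadamard (element-wise) product of two kinships
#'
#' The element-wise product of two relatedness matrices models pairwise
#' epistatic covariance. The product is re-Gower-centered.
#'
#' @param K1,K2 kinship matrices of equal dimension.
#' @return a Gower-centered \code{kinship}.
#' @export
hadamard <- function(K1, K2) {
  if (!all(dim(K1) == dim(K2))) stop("kinship dimension mismatch")
  gower_center(unclass(K1) * unclass(K2))
}

#' Check that a kinship is positive semidefinite (to tolerance)
#'
#' Eigenvalues below \code{-tol * max(eigenvalue)} raise an error; small
#' negative eigenvalues are clipped to 0 with a warning.
#' @param K kinship matrix.
#' @param tol relative tolerance on the minimum eigenvalue.
#' @return K, possibly with negative eigenvalues clipped.
#' @export
kinship_psd <- function(K, tol = 1e-8) {
  e <- eigen(K, symmetric = TRUE)
  lmax <- max(e$values)
  if (min(e$values) < -tol * max(lmax, 1))
    stop("kinship is not positive semidefinite")
  if (any(e$values < 0)) {
    warning("clipping ", sum(e$values < 0), " tiny negative eigenvalue(s)")
    K2 <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    dimnames(K2) <- dimnames(K)
    return(structure(K2, normalization = attr(K, "normalization"),
                     class = c("kinship", "matrix")))
  }
  K
}

#' Bin markers by panel minor allele frequency
#'
#' Either explicit MAF cut points are given (a marker with MAF exactly at a
#' cut point goes to the upper bin, so the rare/common boundary 0.01 is
#' common), or \code{n_bins} bins with approximately equal marker counts are
#' formed by rank (sizes differ by at most 1).
#'
#' @param markers marker data frame with a \code{panel_maf} column.
#' @param edges numeric vector of interior cut points.
#' @param n_bins number of equal-count bins.
#' @return an object of class \code{marker_bins}: list with \code{assignment}
#'   (integer bin per marker; NA for markers without MAF), \code{n_bins},
#'   \code{edges} (when given) and \code{n_excluded}.
#' @export
bin_markers_by_maf <- function(markers, edges = NULL, n_bins = NULL) {
  maf <- markers$panel_maf
  miss <- is.na(maf)
  assignment <- rep(NA_integer_, length(maf))
  if (!is.null(edges)) {
    assignment[!miss] <- findInterval(maf[!miss], sort(edges),
                                      left.open = FALSE) + 1L
    nb <- length(edges) + 1L
  } else if (!is.null(n_bins)) {
    if (n_bins < 1) stop("n_bins must be >= 1")
    r <- rank(maf[!miss], ties.method = "first")
    assignment[!miss] <- as.integer(ceiling(r * n_bins / sum(!miss)))
    nb <- n_bins
  } else stop("supply either edges or n_bins")
  if (any(miss))
    message(sum(miss), " marker(s) without panel MAF excluded from binning")
  structure(list(assignment = assignment, n_bins = nb, edges = edges,
                 n_excluded = sum(miss)),
            class = "marker_bins")
}

#' Per-frequency-bin Gower-centered kinships over the joint panel
#'
#' For each MAF bin, markers are standardized over the segregants of crosses
#' in which they segregate (zeros elsewhere) and a Gower-centered kinship is
#' built from that bin's markers. Markers fixed within a cross contribute no
#' covariance among that cross's segregants, implementing the exclusion of
#' non-segregating variants from genetic covariance.
#'
#' @param G a \code{geno_matrix} spanning all crosses.
#' @param bins a \code{marker_bins} over \code{G}'s markers.
#' @return named list of \code{kinship} matrices, one per bin.
#' @export
build_partitioned_kinships <- function(G, bins) {
  M <- standardize_markers(G, scope = "joint")
  # map retained columns back to bin assignment
  col_ids <- colnames(M)
  assign <- bins$assignment[match(col_ids, colnames(G$values))]
  out <- vector("list", bins$n_bins)
  for (b in seq_len(bins$n_bins)) {
    cols <- which(assign == b)
    if (length(cols) == 0L)
      stop("frequency bin ", b, " contains no usable markers")
    out[[b]] <- kinship_gower(M[, cols, drop = FALSE])
  }
  names(out) <- paste0("bin", seq_len(bins$n_bins))
  out
}
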