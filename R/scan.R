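#' Single-marker genome scan by squared correlation
#'
#' Tests linkage at each marker as r-squared, where r is the Pearson
#' correlation between segregant genotypes at the marker and the phenotype.
#' With covariate markers present, the phenotype is first residualized on
#' them and r is computed between the residual and each marker.
#'
#' @param y phenotype vector (one value per segregant of one cross).
#' @param G genotype matrix (segregants x markers, -1/+1; columns that are NA
#'   or constant get an NA statistic) or a \code{geno_matrix}.
#' @param covariates indices or ids of previously selected marker columns.
#' @param markers optional marker data frame (chrom/pos per column).
#' @return object of class \code{qtl_scan}: list with \code{stat} (per-marker
#'   r-squared), \code{r}, \code{best_marker}, \code{best_stat},
#'   \code{n}, and the residualized phenotype used.
#' @export
genome_scan_r2 <- function(y, G, covariates = NULL, markers = NULL) {
  V <- .geno_values(G)
  if (is.null(markers) && is.list(G)) markers <- G$markers
  if (stats::var(y) == 0) stop("phenotype has zero variance")
  if (is.character(covariates)) covariates <- match(covariates, colnames(V))
  yr <- .resid_on(y, if (length(covariates)) V[, covariates, drop = FALSE])
  n <- length(yr)
  ys <- .std(yr)
  ok <- !apply(V, 2L, anyNA)
  mus <- colMeans(V[, ok, drop = FALSE])
  Vc <- sweep(V[, ok, drop = FALSE], 2L, mus, "-")
  sdv <- sqrt(colMeans(Vc^2))
  usable <- sdv > 0
  r <- rep(NA_real_, ncol(V))
  r[ok][usable] <- as.numeric(
    crossprod(sweep(Vc[, usable, drop = FALSE], 2L, sdv[usable], "/"), ys)) / n
  stat <- r^2
  names(stat) <- colnames(V)
  best <- which.max(stat)  # ties: first index = lowest (chrom, pos) order
  structure(list(stat = stat, r = r,
                 best_marker = names(stat)[best], best_index = best,
                 best_stat = stat[[best]], n = n, residual = yr,
                 markers = markers),
            class = "qtl_scan")
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat("Genome scan over", length(x$stat), "markers, n =", x$n, "\n")
  cat(sprintf("  peak: %s  r^2 = %.4f\n", x$best_marker, x$best_stat))
  invisible(x)
}

#' Permutation null distribution of the genome-wide maximum statistic
#'
#' Permutes phenotype-to-strain assignment B times against fixed genotypes
#' and records the maximum scan statistic for each permutation. With
#' covariates, either the covariate residuals are permuted (default,
#' Freedman-Lane style) or the raw phenotype is permuted and re-residualized.
#'
#' @param y phenotype vector.
#' @param G genotype matrix or \code{geno_matrix}.
#' @param covariates selected covariate marker columns.
#' @param B number of permutations (>= 1).
#' @param seed integer seed.
#' @param scheme \code{"residual"} or \code{"raw"}.
#' @return object of class \code{perm_null}: list with \code{max_stats}
#'   (length B), \code{B}, \code{seed}.
#' @export
max_stat_permutation_null <- function(y, G, covariates = NULL, B = 1000L,
                                      seed = 1L, scheme = c("residual", "raw")) {
  scheme <- match.arg(scheme)
  if (B < 1) stop("B must be at least 1")
  V <- .geno_values(G)
  if (is.character(covariates)) covariates <- match(covariates, colnames(V))
  X <- if (length(covariates)) V[, covariates, drop = FALSE]
  n <- nrow(V)
  set.seed(seed)
  perms <- replicate(B, sample.int(n))
  ok <- !apply(V, 2L, anyNA)
  Vc <- V[, ok, drop = FALSE]
  Vc <- sweep(Vc, 2L, colMeans(Vc), "-")
  sdv <- sqrt(colMeans(Vc^2))
  Vs <- sweep(Vc[, sdv > 0, drop = FALSE], 2L, sdv[sdv > 0], "/")
  if (scheme == "residual" || is.null(X)) {
    yr <- .std(.resid_on(y, X))
    Y <- matrix(yr[perms], n, B)
    R <- crossprod(Vs, Y) / n
    mx <- apply(R^2, 2L, max)
  } else {
    mx <- numeric(B)
    for (b in seq_len(B)) {
      yp <- .std(.resid_on(y[perms[, b]], X))
      mx[b] <- max((crossprod(Vs, yp) / n)^2)
    }
  }
  structure(list(max_stats = mx, B = B, seed = seed, scheme = scheme),
            class = "perm_null")
}

#' Empirical p-value against a permutation null
#'
#' p = (number of null maxima >= observed) / B, floored at 1/B (at the
#' conventional B = 10,000 within-cross this floor is 1e-4; at B = 1,000 for
#' joint scans it is 1e-3).
#'
#' @param observed_max observed maximum statistic.
#' @param null a \code{perm_null}.
#' @return the empirical p-value.
#' @export
empirical_pvalue <- function(observed_max, null) {
  if (!length(null$max_stats)) stop("empty null distribution")
  max(mean(null$max_stats >= observed_max), 1 / null$B)
}

#' ForwardStop sequential stopping statistic
#'
#' For ordered selection p-values p_1..p_k, ForwardStop = -(1/k) * sum of
#' log(1 - p_i). Forward selection is stopped once this exceeds the target
#' FDR level.
#'
#' @param pvalues ordered p-values in [0, 1).
#' @return the ForwardStop statistic.
#' @export
forwardstop <- function(pvalues) {
  if (!length(pvalues)) return(0)
  if (any(pvalues < 0 | pvalues >= 1))
    stop("p-values must lie in [0, 1); p = 1 gives an infinite term")
  -mean(log1p(-pvalues))
}

#' Forward stepwise QTL selection with permutation p-values and ForwardStop
#'
#' At each step the genome is scanned conditional on the already selected
#' markers, the maximum-statistic marker is taken, and its empirical p-value
#' is computed against a fresh covariate-conditional permutation null. The
#' p-value is appended to the prefix p_1..p_k and selection stops at the
#' first step whose ForwardStop statistic exceeds \code{alpha}; the selected
#' set is the markers before that exceedance.
#'
#' @param y phenotype vector (one cross).
#' @param G genotype matrix or \code{geno_matrix}.
#' @param alpha FDR stopping level (default 0.05).
#' @param B permutations per step (10,000 is the full-scale convention;
#'   smaller values keep desk-scale runs fast and the floor 1/B calibrated).
#' @param seed integer seed (advanced per step).
#' @param max_steps safety cap on the number of forward steps.
#' @param scheme permutation scheme, see
#'   \code{\link{max_stat_permutation_null}}.
#' @return object of class \code{qtl_trace}: list with \code{steps} (data
#'   frame: step, marker, index, stat, p, forwardstop, selected) and
#'   \code{selected} (marker indices retained).
#' @export
forward_stepwise <- function(y, G, alpha = 0.05, B = 1000L, seed = 1L,
                             max_steps = 25L, scheme = "residual") {
  V <- .geno_values(G)
  if (ncol(V) == 0L)
    return(structure(list(steps = data.frame(), selected = integer(0),
                          alpha = alpha), class = "qtl_trace"))
  selected <- integer(0)
  pvals <- numeric(0)
  rows <- list()
  if (alpha > 0) for (k in seq_len(max_steps)) {
    sc <- genome_scan_r2(y, V, covariates = selected)
    null <- max_stat_permutation_null(y, V, covariates = selected, B = B,
                                      seed = .subseed(seed, k),
                                      scheme = scheme)
    p <- empirical_pvalue(sc$best_stat, null)
    pvals <- c(pvals, min(p, 1 - 1e-12))
    fs <- forwardstop(pvals)
    keep <- fs <= alpha
    rows[[k]] <- data.frame(step = k, marker = sc$best_marker,
                            index = sc$best_index, stat = sc$best_stat,
                            p = p, forwardstop = fs, selected = keep,
                            stringsAsFactors = FALSE)
    if (!keep) break
    selected <- c(selected, sc$best_index)
  }
  structure(list(steps = if (length(rows)) do.call(rbind, rows)
                 else data.frame(),
                 selected = selected, alpha = alpha, B = B, seed = seed),
            class = "qtl_trace")
}

#' @export
print.qtl_trace <- function(x, ...) {
  cat("Forward stepwise QTL trace (alpha =", x$alpha, "):",
      length(x$selected), "marker(s) selected\n")
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}

#' @export
summary.qtl_trace <- function(object, ...) {
  cat(length(object$selected), "selected QTL at ForwardStop alpha =",
      object$alpha, "\n")
  invisible(object$steps)
}

#' Re-localize stepwise peaks by maximum likelihood
#'
#' For each selected peak in turn, all other peaks are held as covariates and
#' every marker on the peak's chromosome is tried in the multiple regression;
#' the marker maximizing the model likelihood (minimizing the residual sum of
#' squares) replaces the peak.
#'
#' @param y phenotype vector.
#' @param G a \code{geno_matrix} (marker chromosome assignments needed).
#' @param trace a \code{qtl_trace}.
#' @return the trace with re-localized \code{selected} indices.
#' @export
relocalize_peaks <- function(y, G, trace) {
  V <- .geno_values(G)
  markers <- if (is.list(G)) G$markers else NULL
  if (is.null(markers)) stop("marker map with chromosomes required")
  sel <- trace$selected
  if (!length(sel)) return(trace)
  usable <- !apply(V, 2L, anyNA) & apply(V, 2L, function(v) stats::var(v) > 0)
  for (i in seq_along(sel)) {
    others <- sel[-i]
    cand <- which(markers$chrom == markers$chrom[sel[i]] & usable)
    X0 <- cbind(1, V[, others, drop = FALSE])
    r0 <- stats::lm.fit(X0, y)$residuals
    Vc <- V[, cand, drop = FALSE]
    Vr <- apply(Vc, 2L, function(v) stats::lm.fit(X0, v)$residuals)
    num <- as.numeric(crossprod(Vr, r0))
    den <- colSums(Vr^2)
    rss <- sum(r0^2) - ifelse(den > 0, num^2 / den, 0)
    sel[i] <- cand[which.min(rss)]
  }
  trace$selected <- sel
  trace$steps$index[trace$steps$selected] <- sel
  trace$steps$marker[trace$steps$selected] <- colnames(V)[sel]
  trace
}

#' LOD-drop confidence interval around a peak
#'
#' Computes per-marker LOD = -(n/2) * log10(1 - r^2) on the peak's
#' chromosome, conditional on covariates, and returns the contiguous marker
#' interval around the peak where LOD stays within \code{drop} of the peak
#' LOD.
#'
#' @param y phenotype vector.
#' @param G a \code{geno_matrix}.
#' @param peak marker index (or id) of the peak.
#' @param covariates other selected markers held as covariates.
#' @param drop LOD drop (default 1.5).
#' @return list with \code{left}, \code{right} (marker indices), their ids
#'   and bp positions, and the per-marker LOD vector on the chromosome.
#' @export
lod_drop_interval <- function(y, G, peak, covariates = NULL, drop = 1.5) {
  V <- .geno_values(G)
  markers <- G$markers
  if (is.character(peak)) peak <- match(peak, colnames(V))
  if (is.na(peak) || peak < 1 || peak > ncol(V)) stop("peak not in scan")
  sc <- genome_scan_r2(y, V, covariates = covariates)
  chr <- markers$chrom[peak]
  cand <- which(markers$chrom == chr)
  lod <- -(sc$n / 2) * log10(pmax(1 - sc$stat[cand], .Machine$double.xmin))
  lod[is.na(sc$stat[cand])] <- -Inf
  peak_pos <- match(peak, cand)
  thr <- lod[peak_pos] - drop
  ok <- lod >= thr
  left <- peak_pos
  while (left > 1L && ok[left - 1L]) left <- left - 1L
  right <- peak_pos
  while (right < length(cand) && ok[right + 1L]) right <- right + 1L
  list(left = cand[left], right = cand[right],
       left_id = markers$id[cand[left]], right_id = markers$id[cand[right]],
       left_bp = markers$pos_bp[cand[left]],
       right_bp = markers$pos_bp[cand[right]],
       chrom = chr, lod = stats::setNames(lod, markers$id[cand]))
}

#' Cross-validated variance explained by detected QTL
#'
#' Segregants are split into folds; QTL are detected and their effects
#' estimated in the training folds, and the variance explained by the
#' multi-QTL predictor is evaluated in the held-out fold. Returns the average
#' out-of-fold R-squared (can be negative for null traits).
#'
#' @param y phenotype vector.
#' @param G genotype matrix or \code{geno_matrix}.
#' @param folds number of folds (default 10).
#' @param alpha,B,seed forwarded to \code{\link{forward_stepwise}}.
#' @return list with \code{r2_cv} and per-fold results.
#' @export
crossval_variance_explained <- function(y, G, folds = 10L, alpha = 0.05,
                                        B = 200L, seed = 1L) {
  V <- .geno_values(G)
  n <- length(y)
  if (folds < 2) stop("folds must be >= 2")
  if (n / folds < 10) stop("fold with fewer than 10 segregants")
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  r2 <- numeric(folds)
  nsel <- integer(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    trace <- forward_stepwise(y[tr], V[tr, , drop = FALSE], alpha = alpha,
                              B = B, seed = .subseed(seed, f))
    sel <- trace$selected
    nsel[f] <- length(sel)
    if (length(sel)) {
      fit <- stats::lm.fit(cbind(1, V[tr, sel, drop = FALSE]), y[tr])
      pred <- cbind(1, V[te, sel, drop = FALSE]) %*% fit$coefficients
      r2[f] <- 1 - sum((y[te] - pred)^2) / sum((y[te] - mean(y[tr]))^2)
    } else {
      r2[f] <- 0
    }
  }
  list(r2_cv = mean(r2), per_fold = data.frame(fold = seq_len(folds),
                                               r2 = r2, n_qtl = nsel))
}
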