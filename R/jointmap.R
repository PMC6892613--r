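#' Residualize a cross's phenotype for leave-one-chromosome-out scanning
#'
#' Computes s_c = y_c - Q C - BLUP(a_L): the phenotype minus the fixed
#' effects of detected off-chromosome QTL and the REML-based BLUP of the
#' polygenic contribution of all chromosomes except the chromosome of
#' interest. The result carries only residual and on-chromosome genetic
#' signal.
#'
#' @param y phenotype vector for one cross.
#' @param Q matrix of off-chromosome detected QTL genotypes (or NULL).
#' @param C their effect estimates; if NULL, estimated by least squares.
#' @param K_loco kinship built from off-chromosome markers.
#' @param sigma2 optional named vector \code{c(A=, residual=)} of variance
#'   components to reuse (e.g. estimated once per trait on the genome-wide
#'   kinship); if NULL they are REML-estimated on \code{K_loco}.
#' @param marker_chrom,chrom optional: chromosomes of the columns of Q and
#'   the chromosome of interest, used to reject on-chromosome covariates.
#' @return the residualized phenotype vector s_c (centered).
#' @export
residualize_loco <- function(y, Q = NULL, C = NULL, K_loco = NULL,
                             sigma2 = NULL, marker_chrom = NULL,
                             chrom = NULL) {
  if (!is.null(Q) && !is.null(marker_chrom) && !is.null(chrom) &&
      any(marker_chrom == chrom))
    stop("Q contains markers on the chromosome of interest")
  if (!is.null(Q) && NCOL(Q) > 0) {
    Q <- as.matrix(Q)
    if (is.null(C)) C <- stats::lm.fit(cbind(1, Q), y)$coefficients[-1]
    r <- y - as.numeric(Q %*% C)
  } else {
    r <- y
  }
  r <- r - mean(r)
  if (is.null(K_loco)) return(r)
  if (is.null(sigma2)) {
    fit <- additive_model(r, K_loco, standardize = FALSE)
    sigma2 <- fit$sigma2
  }
  sA <- sigma2[["A"]]; sE <- sigma2[["residual"]]
  if (sA <= 0) return(r)
  n <- length(r)
  V <- sA * unclass(K_loco) + diag(sE, n)
  Vi_r <- solve(V, r)
  a_hat <- sA * as.numeric(unclass(K_loco) %*% Vi_r)
  s <- r - a_hat
  s - mean(s)
}

# Group marker columns by their cross-segregation pattern; within a cross the
# missingness of a marker is all-or-none, so a pattern is a subset of crosses.
.pattern_groups <- function(G, cols) {
  seg <- .segregation_table(G)[cols, , drop = FALSE]
  key <- apply(seg, 1L, function(z) paste(which(z), collapse = ","))
  split(cols, key)
}

# Pooled scan statistics for a set of columns sharing informative segregants.
.joint_stats_for <- function(yr, V, rows, cols) {
  n <- length(rows)
  ys <- .std(yr[rows])
  Vc <- V[rows, cols, drop = FALSE]
  mus <- colMeans(Vc)
  Vc <- sweep(Vc, 2L, mus, "-")
  sdv <- sqrt(colMeans(Vc^2))
  r <- rep(NA_real_, length(cols))
  ok <- sdv > 0
  r[ok] <- as.numeric(crossprod(sweep(Vc[, ok, drop = FALSE], 2L,
                                      sdv[ok], "/"), ys)) / n
  t <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  # -log10(2 * pt(-|t|, n-2)) computed in log space for numerical range
  nlp <- (-(stats::pt(abs(t), df = n - 2, lower.tail = FALSE,
                      log.p = TRUE) + log(2))) / log(10)
  list(r = r, t = t, nlp = nlp, n = n)
}

#' Pooled t-statistic scan over the joint cross panel
#'
#' For each marker on a chromosome, computes the Pearson correlation between
#' the residualized phenotypes s (concatenated across crosses) and the
#' recoded genotypes over the informative segregants (those from crosses in
#' which the marker segregates), the t statistic r*sqrt(n-2)/sqrt(1-r^2)
#' with n the number of informative segregants, and -log10 of the two-sided
#' p-value from the t distribution with n-2 degrees of freedom.
#'
#' @param s residualized phenotype vector over all segregants.
#' @param G a \code{geno_matrix} spanning the crosses.
#' @param chrom chromosome of interest (NULL = all markers).
#' @param covariates previously selected marker columns; s is residualized
#'   on them (missing covariate entries treated as 0) before scanning.
#' @param min_informative markers with fewer informative segregants are
#'   skipped with a warning.
#' @return object of class \code{joint_scan}: data frame with marker, chrom,
#'   r, t, n_informative and nlp (-log10 p), plus \code{best_*} fields.
#' @export
joint_t_scan <- function(s, G, chrom = NULL, covariates = NULL,
                         min_informative = 10L) {
  V <- G$values
  cols <- if (is.null(chrom)) seq_len(ncol(V))
          else which(G$markers$chrom == chrom)
  if (is.character(covariates)) covariates <- match(covariates, colnames(V))
  Xc <- NULL
  if (length(covariates)) {
    Xc <- V[, covariates, drop = FALSE]
    Xc[is.na(Xc)] <- 0
  }
  yr <- .center_by_cross(.resid_on(s, Xc), G$cross)
  seg <- .segregation_table(G)
  groups <- .pattern_groups(G, cols)
  out <- data.frame(index = cols, marker = colnames(V)[cols],
                    chrom = G$markers$chrom[cols],
                    r = NA_real_, t = NA_real_, n_informative = NA_integer_,
                    nlp = NA_real_, stringsAsFactors = FALSE)
  skipped <- 0L
  for (g in groups) {
    cr <- which(seg[g[1], ])
    rows <- which(as.integer(G$cross) %in% cr)
    pos <- match(g, cols)
    out$n_informative[pos] <- length(rows)
    if (length(rows) < min_informative) { skipped <- skipped + length(g); next }
    st <- .joint_stats_for(yr, V, rows, g)
    out$r[pos] <- st$r
    out$t[pos] <- st$t
    out$nlp[pos] <- st$nlp
  }
  if (skipped > 0)
    warning(skipped, " marker(s) skipped: fewer than ", min_informative,
            " informative segregants")
  best <- if (all(is.na(out$nlp))) NA_integer_ else which.max(out$nlp)
  structure(list(table = out,
                 best_marker = if (is.na(best)) NA else out$marker[best],
                 best_index = if (is.na(best)) NA else out$index[best],
                 best_stat = if (is.na(best)) NA else out$nlp[best]),
            class = "joint_scan")
}

#' @export
print.joint_scan <- function(x, ...) {
  cat("Joint pooled-t scan over", nrow(x$table), "markers\n")
  cat(sprintf("  peak: %s  -log10(p) = %.3f\n", x$best_marker, x$best_stat))
  invisible(x)
}

#' Within-cross permutation null for the joint scan
#'
#' Permutes the (covariate-residualized) phenotype within each cross only —
#' never between crosses — and records for each permutation the maximum
#' -log10 p over the scanned markers.
#'
#' @param s residualized phenotype vector.
#' @param G a \code{geno_matrix}.
#' @param chrom chromosome(s) to scan (NULL = genome).
#' @param covariates selected covariate columns.
#' @param B permutations (default 1,000 at full scale; p floor = 1/B).
#' @param seed integer seed.
#' @param min_informative as in \code{\link{joint_t_scan}}.
#' @return a \code{perm_null}.
#' @export
joint_permutation_null <- function(s, G, chrom = NULL, covariates = NULL,
                                   B = 1000L, seed = 1L,
                                   min_informative = 10L) {
  if (B < 1) stop("B must be at least 1")
  V <- G$values
  cols <- if (is.null(chrom)) seq_len(ncol(V))
          else which(G$markers$chrom %in% chrom)
  if (is.character(covariates)) covariates <- match(covariates, colnames(V))
  Xc <- NULL
  if (length(covariates)) {
    Xc <- V[, covariates, drop = FALSE]
    Xc[is.na(Xc)] <- 0
  }
  yr <- .center_by_cross(.resid_on(s, Xc), G$cross)
  n <- length(yr)
  set.seed(seed)
  perm <- matrix(seq_len(n), n, B)
  for (cr in levels(G$cross)) {
    rows <- which(G$cross == cr)
    perm[rows, ] <- replicate(B, sample(rows))
  }
  Y <- matrix(yr[perm], n, B)
  seg <- .segregation_table(G)
  groups <- .pattern_groups(G, cols)
  mx <- rep(-Inf, B)
  for (g in groups) {
    cr <- which(seg[g[1], ])
    rows <- which(as.integer(G$cross) %in% cr)
    np <- length(rows)
    if (np < min_informative) next
    Ys <- Y[rows, , drop = FALSE]
    Ys <- sweep(Ys, 2L, colMeans(Ys), "-")
    sdy <- sqrt(colMeans(Ys^2))
    Ys <- sweep(Ys, 2L, sdy, "/")
    Vc <- V[rows, g, drop = FALSE]
    Vc <- sweep(Vc, 2L, colMeans(Vc), "-")
    sdv <- sqrt(colMeans(Vc^2))
    ok <- sdv > 0
    if (!any(ok)) next
    R <- crossprod(sweep(Vc[, ok, drop = FALSE], 2L, sdv[ok], "/"), Ys) / np
    Tm <- R * sqrt((np - 2) / pmax(1 - R^2, 1e-300))
    NLP <- (-(stats::pt(abs(Tm), df = np - 2, lower.tail = FALSE,
                        log.p = TRUE) + log(2))) / log(10)
    mx <- pmax(mx, apply(NLP, 2L, max))
  }
  structure(list(max_stats = mx, B = B, seed = seed, scheme = "within-cross"),
            class = "perm_null")
}

#' Joint forward stepwise QTL mapping across crosses
#'
#' Per-cross phenotypes are standardized, residualized per chromosome by
#' \code{\link{residualize_loco}} (off-chromosome within-cross QTL as fixed
#' effects plus the leave-one-chromosome-out polygenic BLUP, with variance
#' components estimated once per cross on the genome-wide kinship), and then
#' scanned with the pooled t statistic. At each step the genome-wide maximum
#' -log10 p is assigned an empirical p-value from a within-cross permutation
#' null, the ForwardStop statistic of the p-value prefix is updated, and
#' selection stops at the first exceedance of \code{alpha}. Previously
#' selected markers enter subsequent scans as regression covariates.
#'
#' @param y phenotype vector over all segregants (one value per segregant).
#' @param G a \code{geno_matrix} spanning the crosses.
#' @param within_qtl optional list per cross: list(index = marker indices,
#'   effect = effects) of within-cross detected QTL used for
#'   residualization.
#' @param alpha ForwardStop level (default 0.05).
#' @param B permutations per step.
#' @param seed integer seed.
#' @param loco perform polygenic leave-one-chromosome-out residualization
#'   (requires computing per-cross kinships); FALSE scans the standardized
#'   phenotypes directly, which reduces exactly to the within-cross
#'   procedure when a single cross is supplied.
#' @param max_steps safety cap.
#' @return object of class \code{joint_qtl}: list with \code{steps} data
#'   frame (step, marker, chrom, t, n_informative, p, forwardstop,
#'   selected) and \code{selected} indices.
#' @export
joint_forward_stepwise <- function(y, G, within_qtl = NULL, alpha = 0.05,
                                   B = 1000L, seed = 1L, loco = TRUE,
                                   max_steps = 25L) {
  V <- G$values
  crosses <- levels(G$cross)
  ys <- y
  for (cr in crosses) {
    rows <- which(G$cross == cr)
    ys[rows] <- .std(y[rows])
  }
  chroms <- unique(G$markers$chrom)
  # Residualized phenotype per chromosome of interest.
  S <- matrix(ys, length(ys), length(chroms),
              dimnames = list(NULL, as.character(chroms)))
  if (loco) {
    for (cr in crosses) {
      rows <- which(G$cross == cr)
      Vc <- V[rows, , drop = FALSE]
      segc <- which(!is.na(Vc[1, ]))
      Mc <- standardize_markers(Vc[, segc, drop = FALSE])
      qtl <- within_qtl[[cr]]
      Qall <- if (!is.null(qtl) && length(qtl$index))
        Vc[, qtl$index, drop = FALSE] else NULL
      Kfull <- kinship_gower(Mc)
      r0 <- if (is.null(Qall)) ys[rows]
            else stats::lm.fit(cbind(1, Qall), ys[rows])$residuals
      fit <- additive_model(r0, Kfull, standardize = FALSE)
      for (ch in chroms) {
        off <- segc[G$markers$chrom[segc] != ch]
        Koff <- kinship_gower(standardize_markers(
          Vc[, off, drop = FALSE]))
        qoff <- if (!is.null(qtl))
          qtl$index[G$markers$chrom[qtl$index] != ch] else integer(0)
        Q <- if (length(qoff)) Vc[, qoff, drop = FALSE] else NULL
        S[rows, as.character(ch)] <- residualize_loco(
          ys[rows], Q = Q, C = NULL, K_loco = Koff, sigma2 = fit$sigma2)
      }
      # re-standardize per cross so pooled correlations are scale-free
      for (ch in as.character(chroms))
        S[rows, ch] <- .std(S[rows, ch])
    }
  }
  selected <- integer(0)
  pvals <- numeric(0)
  rows_out <- list()
  if (alpha > 0) for (k in seq_len(max_steps)) {
    best <- NULL
    for (ch in chroms) {
      sc <- suppressWarnings(
        joint_t_scan(S[, as.character(ch)], G, chrom = ch,
                     covariates = selected))
      if (is.na(sc$best_index)) next
      if (is.null(best) || sc$best_stat > best$best_stat) {
        best <- sc; best$chrom <- ch
      }
    }
    if (is.null(best)) break
    null_mx <- rep(-Inf, B)
    set.seed(.subseed(seed, k))
    for (ch in chroms) {
      nl <- suppressWarnings(
        joint_permutation_null(S[, as.character(ch)], G, chrom = ch,
                               covariates = selected, B = B,
                               seed = .subseed(seed, k)))
      null_mx <- pmax(null_mx, nl$max_stats)
    }
    p <- max(mean(null_mx >= best$best_stat), 1 / B)
    pvals <- c(pvals, min(p, 1 - 1e-12))
    fs <- forwardstop(pvals)
    keep <- fs <= alpha
    irow <- best$table[best$table$index == best$best_index, ]
    rows_out[[k]] <- data.frame(step = k, marker = best$best_marker,
                                index = best$best_index, chrom = best$chrom,
                                t = irow$t, n_informative = irow$n_informative,
                                nlp = best$best_stat, p = p, forwardstop = fs,
                                selected = keep, stringsAsFactors = FALSE)
    if (!keep) break
    selected <- c(selected, best$best_index)
  }
  structure(list(steps = if (length(rows_out)) do.call(rbind, rows_out)
                 else data.frame(),
                 selected = selected, alpha = alpha, B = B, seed = seed,
                 loco = loco),
            class = "joint_qtl")
}

#' @export
print.joint_qtl <- function(x, ...) {
  cat("Joint stepwise QTL mapping (alpha =", x$alpha, "):",
      length(x$selected), "marker(s) selected\n")
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Per-cross effect estimates for joint QTL peaks
#'
#' Within each cross the phenotype is standardized to mean 0, variance 1 and
#' the effects of the peak markers segregating in that cross are estimated by
#' multiple regression under the -1/+1 genotype coding. The primary effect is
#' the regression coefficient (variance explained = beta^2 in a balanced
#' cross); the allele-mean difference 2*beta is also reported. The mean
#' effect is the average of the per-cross betas over segregating crosses.
#'
#' @param y phenotype vector over all segregants.
#' @param G a \code{geno_matrix}.
#' @param peaks marker indices (or ids) of the selected joint QTL.
#' @param standardize standardize the phenotype within each cross first
#'   (default TRUE); set FALSE when y is already on the reporting scale.
#' @return data frame with one row per peak: marker, chrom, panel MAF,
#'   mean_beta, allele_diff (= 2*mean_beta), n_crosses and a per-cross beta
#'   matrix in attribute \code{betas}.
#' @export
estimate_effects_per_cross <- function(y, G, peaks, standardize = TRUE) {
  V <- G$values
  if (is.character(peaks)) peaks <- match(peaks, colnames(V))
  crosses <- levels(G$cross)
  betas <- matrix(NA_real_, length(peaks), length(crosses),
                  dimnames = list(colnames(V)[peaks], crosses))
  for (cr in crosses) {
    rows <- which(G$cross == cr)
    segg <- vapply(peaks, function(j) {
      v <- V[rows, j]
      !anyNA(v) && stats::var(v) > 0
    }, logical(1))
    if (!any(segg)) next
    cols <- peaks[segg]
    Xm <- cbind(1, V[rows, cols, drop = FALSE])
    qr_ <- qr(Xm)
    if (qr_$rank < ncol(Xm)) {
      drop_ <- qr_$pivot[-seq_len(qr_$rank)] - 1L  # column positions in cols
      drop_ <- drop_[drop_ > 0]
      warning("dropping ", length(drop_),
              " collinear peak(s) in cross ", cr)
      cols <- cols[-drop_]
      Xm <- cbind(1, V[rows, cols, drop = FALSE])
    }
    yc <- if (standardize) .std(y[rows]) else y[rows]
    cf <- stats::lm.fit(Xm, yc)$coefficients[-1]
    betas[match(cols, peaks), cr] <- cf
  }
  mean_beta <- rowMeans(betas, na.rm = TRUE)
  maf <- if (!is.null(G$markers)) G$markers$panel_maf[peaks] else NA_real_
  out <- data.frame(marker = colnames(V)[peaks],
                    chrom = if (!is.null(G$markers))
                      G$markers$chrom[peaks] else NA,
                    panel_maf = maf,
                    mean_beta = mean_beta,
                    allele_diff = 2 * mean_beta,
                    n_crosses = rowSums(!is.na(betas)),
                    stringsAsFactors = FALSE)
  attr(out, "betas") <- betas
  out
}

#' Winner's-curse-free effect estimation by sample splitting
#'
#' Within each cross, a hold-out fraction of segregants is set aside; QTL are
#' detected in the remaining training segregants by forward stepwise
#' selection and effects of the detected peaks are estimated both in the
#' training data (in-sample, subject to winner's curse) and in the held-out
#' data (unbiased).
#'
#' @param y phenotype vector over all segregants.
#' @param G a \code{geno_matrix}.
#' @param holdout_frac fraction held out per cross (default 1/10).
#' @param alpha,B forwarded to \code{\link{forward_stepwise}}.
#' @param seed integer seed controlling the split and the permutations.
#' @return data frame: cross, marker, index, beta_train, beta_holdout.
#' @export
unbiased_effects <- function(y, G, holdout_frac = 0.1, alpha = 0.05,
                             B = 200L, seed = 1L) {
  V <- G$values
  out <- list()
  set.seed(seed)
  for (cr in levels(G$cross)) {
    rows <- which(G$cross == cr)
    n <- length(rows)
    n_te <- max(1L, round(holdout_frac * n))
    if (n - n_te < 10L || n_te < 10L)
      stop("need at least 10 segregants per cross per fold")
    te <- sample(rows, n_te)
    tr <- setdiff(rows, te)
    segc <- which(!is.na(V[rows[1], ]))
    Gtr <- V[tr, segc, drop = FALSE]
    keep <- apply(Gtr, 2L, function(v) stats::var(v) > 0)
    Gtr <- Gtr[, keep, drop = FALSE]
    trace <- forward_stepwise(.std(y[tr]), Gtr, alpha = alpha, B = B,
                              seed = .subseed(seed, match(cr, levels(G$cross))))
    sel <- segc[keep][trace$selected]
    if (!length(sel)) next
    b_tr <- stats::lm.fit(cbind(1, V[tr, sel, drop = FALSE]),
                          .std(y[tr]))$coefficients[-1]
    b_te <- stats::lm.fit(cbind(1, V[te, sel, drop = FALSE]),
                          .std(y[te]))$coefficients[-1]
    out[[cr]] <- data.frame(cross = cr, marker = colnames(V)[sel],
                            index = sel, beta_train = b_tr,
                            beta_holdout = b_te, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(cross = character(0),
                                      marker = character(0),
                                      index = integer(0),
                                      beta_train = numeric(0),
                                      beta_holdout = numeric(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
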