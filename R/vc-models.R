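#' Additive variance-component model (y = a + e)
#'
#' Two-component REML fit with a single additive kinship; the narrow-sense
#' heritability estimate is sigma2_A / (sigma2_A + sigma2_E). The phenotype
#' is standardized to mean 0, variance 1 before fitting, as is conventional
#' for per-cross trait analyses.
#'
#' @param y phenotype vector (one value per segregant).
#' @param K_A additive kinship matrix.
#' @param standardize standardize y first (default TRUE).
#' @param ... passed to \code{\link{reml_fit}}.
#' @return a \code{vc_fit} with an extra \code{h2} element.
#' @export
additive_model <- function(y, K_A, standardize = TRUE, ...) {
  if (standardize) y <- .std(y)
  fit <- reml_fit(y, kernels = list(A = K_A), ...)
  fit$h2 <- unname(fit$sigma2["A"] / sum(fit$sigma2))
  fit
}

#' Additive + pairwise-epistatic variance components with replicates
#'
#' Fits the seven-component model with replicated observations: detected-QTL
#' kinship (q), genome-wide additive kinship (a), the three Hadamard-product
#' epistasis kernels QTLxQTL (f), QTLxgenome (g) and genomexgenome (i), a
#' segregant-level repeatability term (p) and the observation-level residual
#' (e). The reduced model omits the QTLxQTL and QTLxgenome interaction terms.
#'
#' @param y observation vector of length L = n x replicates.
#' @param Z L x n incidence matrix mapping observations to segregants.
#' @param K_QTL kinship built from detected QTL markers (n x n); NULL drops
#'   the QTL terms entirely (giving additive + epistasis + repeatability).
#' @param K_A genome-wide additive kinship (n x n).
#' @param reduced fit the reduced model (omit f and g).
#' @param X fixed-effect design (default intercept).
#' @param ... passed to \code{\link{reml_fit}}.
#' @return a \code{vc_fit}.
#' @export
epistatic_model <- function(y, Z, K_QTL, K_A, reduced = FALSE, X = NULL,
                            ...) {
  kernels <- list()
  if (!is.null(K_QTL)) kernels$AQTL <- K_QTL
  kernels$A <- K_A
  if (!is.null(K_QTL) && !reduced) {
    kernels[["AQTLxAQTL"]] <- hadamard(K_QTL, K_QTL)
    kernels[["AQTLxA"]] <- hadamard(K_QTL, K_A)
  }
  kernels[["AxA"]] <- hadamard(K_A, K_A)
  kernels[["repeatability"]] <- "segregant"
  reml_fit(y, kernels = kernels, X = X, Z = Z, ...)
}

#' Ratio of non-additive to additive variance
#'
#' (sigma2_QTLxQTL + sigma2_QTLxA + sigma2_AxA) / (sigma2_QTL + sigma2_A)
#' from an epistatic model fit.
#'
#' @param fit a \code{vc_fit} from \code{\link{epistatic_model}}.
#' @return the ratio, or NA with attribute \code{undefined = TRUE} when the
#'   additive denominator is zero.
#' @export
nonadditive_ratio <- function(fit) {
  s <- fit$sigma2
  num <- sum(s[names(s) %in% c("AQTLxAQTL", "AQTLxA", "AxA")])
  den <- sum(s[names(s) %in% c("AQTL", "A")])
  if (den <= 0) return(structure(NA_real_, undefined = TRUE))
  num / den
}

#' Joint allele-frequency-partitioned variance components
#'
#' Fits y = X beta + sum_b u_b + e across the concatenated cross panel,
#' where each random term has covariance sigma2_b * A_b for one Gower-
#' centered per-frequency-bin kinship (e.g. rare MAF < 1 percent vs common),
#' and the fixed effects are per-cross indicators.
#'
#' @param y phenotype vector over all segregants (concatenated crosses),
#'   typically standardized per cross.
#' @param cross_ids per-segregant cross labels.
#' @param kinships named list of per-bin kinships from
#'   \code{\link{build_partitioned_kinships}}.
#' @param ... passed to \code{\link{reml_fit}}.
#' @return a \code{vc_fit}.
#' @export
joint_maf_partition_model <- function(y, cross_ids, kinships, ...) {
  X <- stats::model.matrix(~ factor(cross_ids))
  reml_fit(y, kernels = kinships, X = X, ...)
}

#' Share of variance attributed to a set of components
#'
#' Computes sigma2_num / sigma2_denom with a delta-method standard error from
#' the inverse Fisher information. By default the denominator is all
#' non-residual (genetic) components.
#'
#' @param fit a \code{vc_fit}.
#' @param numerator component names forming the numerator.
#' @param denominator component names forming the denominator (default: all
#'   components except the residual).
#' @return list with \code{share} and \code{se}; share is NA with attribute
#'   \code{undefined} when the denominator total is not positive.
#' @export
variance_share <- function(fit, numerator,
                           denominator = setdiff(names(fit$sigma2),
                                                 "residual")) {
  s <- fit$sigma2
  if (!all(numerator %in% names(s))) stop("unknown component in numerator")
  u <- sum(s[numerator])
  t_ <- sum(s[denominator])
  if (t_ <= 0) return(list(share = structure(NA_real_, undefined = TRUE),
                           se = NA_real_))
  share <- u / t_
  C <- tryCatch(solve(fit$fisher), error = function(e) NULL)
  se <- NA_real_
  if (!is.null(C)) {
    g <- stats::setNames(rep(0, length(s)), names(s))
    g[denominator] <- -u / t_^2
    g[numerator] <- g[numerator] + 1 / t_
    se <- sqrt(max(as.numeric(t(g) %*% C %*% g), 0))
  }
  list(share = share, se = se)
}
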