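# Dense-formula oracle for the restricted log-likelihood (up to the constant
# the fit drops): direct solve()/determinant() evaluation.
dense_reml_ll <- function(y, X, Ks, sigma2) {
  L <- length(y)
  V <- matrix(0, L, L)
  for (i in seq_along(Ks)) V <- V + sigma2[i] * Ks[[i]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus +
                       determinant(XtViX)$modulus +
                       t(y) %*% P %*% y))
}

test_that("restricted likelihood matches the dense oracle on small fits", {
  cr <- make_cross(n = 40, m = 80, n_chroms = 2, seed = 1)
  V <- cr$values[, seg_cols(cr), drop = FALSE]
  K <- kinship_gower(standardize_markers(V))
  set.seed(2)
  y <- stats::rnorm(40)
  fit <- reml_fit(y, kernels = list(A = K))
  X <- matrix(1, 40, 1)
  Ks <- list(unclass(K), diag(40))
  expect_equal(fit$loglik, dense_reml_ll(y, X, Ks, fit$sigma2),
               tolerance = 1e-6)
  # and at a non-optimal point the oracle confirms the optimum is better
  expect_gte(fit$loglik + 1e-8,
             dense_reml_ll(y, X, Ks, c(0.3 * stats::var(y),
                                       0.7 * stats::var(y))))
})

test_that("balanced replicate designs match the closed-form ANOVA fit", {
  set.seed(3)
  n <- 60; r <- 3
  u <- stats::rnorm(n, 0, sqrt(0.6))
  Z <- kronecker(diag(n), rep(1, r))
  y <- as.numeric(Z %*% u) + stats::rnorm(n * r, 0, sqrt(0.4))
  fit <- reml_fit(y, kernels = list(segregant = "segregant"), Z = Z)
  # one-way ANOVA oracle
  gid <- rep(seq_len(n), each = r)
  gm <- tapply(y, gid, mean)
  msb <- r * sum((gm - mean(y))^2) / (n - 1)
  msw <- sum((y - gm[gid])^2) / (n * (r - 1))
  expect_equal(unname(fit$sigma2["segregant"]), (msb - msw) / r,
               tolerance = 1e-6)
  expect_equal(unname(fit$sigma2["residual"]), msw, tolerance = 1e-6)
})

test_that("REML is invariant to reciprocal kernel/variance rescaling", {
  cr <- make_cross(n = 80, m = 100, n_chroms = 2, seed = 4)
  V <- cr$values[, seg_cols(cr), drop = FALSE]
  K <- kinship_gower(standardize_markers(V))
  y <- planted_trait(list(values = V), 3, 0.6, seed = 5)
  f1 <- reml_fit(y, kernels = list(A = K))
  f2 <- reml_fit(y, kernels = list(A = 2 * unclass(K)))
  expect_equal(unname(f2$sigma2["A"]) * 2, unname(f1$sigma2["A"]),
               tolerance = 1e-4)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("null traits give genetic variance estimates consistent with zero", {
  cr <- make_cross(n = 150, m = 200, n_chroms = 3, seed = 6)
  V <- cr$values[, seg_cols(cr), drop = FALSE]
  K <- kinship_gower(standardize_markers(V))
  ok <- 0
  n_rep <- 30
  for (rep in seq_len(n_rep)) {
    set.seed(600 + rep)
    y <- stats::rnorm(150)
    fit <- additive_model(y, K)
    ok <- ok + (fit$sigma2["A"] <= 2 * fit$se["A"] + 1e-9)
  }
  expect_gte(ok / n_rep, 0.9)
})

test_that("singular fixed-effect designs are rejected", {
  set.seed(7)
  y <- stats::rnorm(30)
  expect_error(reml_fit(y, kernels = list(), X = cbind(1, 1)),
               "singular")
})

test_that("heritability is recovered with calibrated standard errors", {
  # simulate traits with additive variance 0.5 on a real kinship
  cr <- make_cross(n = 200, m = 300, n_chroms = 4, seed = 8)
  V <- cr$values[, seg_cols(cr), drop = FALSE]
  M <- standardize_markers(V)
  K <- kinship_gower(M)
  n_rep <- 15
  est <- se <- numeric(n_rep)
  within2 <- 0
  for (rep in seq_len(n_rep)) {
    set.seed(800 + rep)
    b <- stats::rnorm(ncol(M), 0, sqrt(0.5 / ncol(M)))
    y <- as.numeric(M %*% b) + stats::rnorm(200, 0, sqrt(0.5))
    fit <- additive_model(y, K, standardize = FALSE)
    est[rep] <- fit$sigma2["A"]; se[rep] <- fit$se["A"]
    within2 <- within2 + (abs(est[rep] - 0.5) <= 2 * se[rep])
  }
  expect_gte(within2 / n_rep, 0.8)
  # Fisher SEs calibrate against the empirical spread
  expect_lt(mean(se), 1.5 * stats::sd(est) + 0.1)
  # permuted phenotypes destroy the genetic signal
  set.seed(9)
  yp <- sample(as.numeric(M %*% stats::rnorm(ncol(M), 0, sqrt(2 / ncol(M)))))
  fitp <- additive_model(yp, K)
  expect_lte(fitp$sigma2["A"], 2 * fitp$se["A"] + 1e-9)
})

test_that("noiseless genetic traits give heritability near one", {
  cr <- make_cross(n = 120, m = 200, n_chroms = 2, seed = 10)
  M <- standardize_markers(cr$values[, seg_cols(cr), drop = FALSE])
  K <- kinship_gower(M)
  set.seed(11)
  y <- as.numeric(M %*% stats::rnorm(ncol(M), 0, 1 / sqrt(ncol(M))))
  fit <- additive_model(y, K)
  expect_gte(fit$h2, 0.95)
})

test_that("epistatic components are null when no interactions are simulated", {
  cr <- make_cross(n = 250, m = 300, n_chroms = 4, seed = 12)
  V <- cr$values[, seg_cols(cr), drop = FALSE]
  M <- standardize_markers(V)
  K_A <- kinship_gower(M)
  qtl_idx <- round(c(0.15, 0.55, 0.85) * ncol(V))
  K_Q <- kinship_gower(M[, qtl_idx, drop = FALSE])
  set.seed(13)
  n <- nrow(V); r <- 2
  g <- 0.4 * rrqtl:::.std(V[, qtl_idx[1]]) +
    0.35 * rrqtl:::.std(V[, qtl_idx[2]]) +
    as.numeric(M %*% stats::rnorm(ncol(M), 0, sqrt(0.2 / ncol(M))))
  d <- stats::rnorm(n, 0, sqrt(0.15))
  Z <- kronecker(diag(n), rep(1, r))
  y <- as.numeric(Z %*% (g + d)) + stats::rnorm(n * r, 0, sqrt(0.35))
  fit <- epistatic_model(y, Z, K_Q, K_A)
  expect_true(fit$converged)
  epi <- c("AQTLxAQTL", "AQTLxA", "AxA")
  tot_epi <- sum(fit$sigma2[epi])
  C <- vcov(fit)
  se_epi <- sqrt(sum(C[epi, epi]))
  expect_lte(tot_epi, 2 * se_epi + 0.05)
  ratio <- nonadditive_ratio(fit)
  expect_lt(ratio, 0.25)
})

test_that("planted pairwise interactions are recovered in the epistatic model", {
  cr <- make_cross(n = 300, m = 300, n_chroms = 4, seed = 14)
  V <- cr$values[, seg_cols(cr), drop = FALSE]
  M <- standardize_markers(V)
  K_A <- kinship_gower(M)
  set.seed(15)
  n <- nrow(V); r <- 2
  # additive background 50% + pairwise interactions 10% + noise 40%
  g_add <- as.numeric(M %*% stats::rnorm(ncol(M), 0, sqrt(0.5 / ncol(M))))
  pairs <- matrix(sample(ncol(M), 40), ncol = 2)
  g_int <- rowSums(apply(pairs, 1, function(p) M[, p[1]] * M[, p[2]]))
  g_int <- g_int / sqrt(mean((g_int - mean(g_int))^2)) * sqrt(0.10)
  Z <- kronecker(diag(n), rep(1, r))
  y <- as.numeric(Z %*% (g_add + g_int)) +
    stats::rnorm(n * r, 0, sqrt(0.4))
  fit <- epistatic_model(y, Z, K_QTL = NULL, K_A = K_A)
  shr <- variance_share(fit, "AxA",
                        denominator = setdiff(names(fit$sigma2),
                                              c("repeatability", "residual")))
  # epistatic share of genetic variance: truth 0.1/0.6 = 0.167
  expect_lt(abs(shr$share - 1 / 6), 0.10)
})

test_that("identical replicates drive the observation residual to zero", {
  cr <- make_cross(n = 80, m = 100, n_chroms = 2, seed = 16)
  M <- standardize_markers(cr$values[, seg_cols(cr), drop = FALSE])
  K_A <- kinship_gower(M)
  set.seed(17)
  n <- nrow(M); r <- 2
  g <- as.numeric(M %*% stats::rnorm(ncol(M), 0, sqrt(0.5 / ncol(M))))
  seg_val <- g + stats::rnorm(n, 0, sqrt(0.5))
  Z <- kronecker(diag(n), rep(1, r))
  y <- as.numeric(Z %*% seg_val)  # replicates agree exactly
  fit <- suppressWarnings(epistatic_model(y, Z, K_QTL = NULL, K_A = K_A,
                                          reduced = TRUE))
  expect_lt(fit$sigma2["residual"], 0.02)
})

test_that("nonadditive_ratio does the component arithmetic", {
  fake <- structure(list(sigma2 = c(AQTL = 0.3, A = 0.2,
                                    AQTLxAQTL = 0.03, AQTLxA = 0.03,
                                    AxA = 0.02, repeatability = 0.1,
                                    residual = 0.3)),
                    class = "vc_fit")
  expect_equal(nonadditive_ratio(fake), 0.16)
  fake0 <- structure(list(sigma2 = c(AQTL = 0, A = 0, AxA = 0.1)),
                     class = "vc_fit")
  expect_true(is.na(nonadditive_ratio(fake0)))
  expect_true(attr(nonadditive_ratio(fake0), "undefined"))
})

test_that("variance_share computes shares and delta-method errors", {
  f <- structure(list(sigma2 = c(rare = 0.3, common = 0.3, residual = 0.4),
                      fisher = diag(c(100, 100, 100))),
                 class = "vc_fit")
  s <- variance_share(f, "rare")
  expect_equal(s$share, 0.5)
  expect_gt(s$se, 0)
  f2 <- structure(list(sigma2 = c(rare = 0.51, common = 0.49,
                                  residual = 0.2),
                       fisher = diag(3)), class = "vc_fit")
  expect_equal(variance_share(f2, "rare")$share, 0.51)
  f0 <- structure(list(sigma2 = c(rare = 0, common = 0, residual = 1),
                       fisher = diag(3)), class = "vc_fit")
  expect_true(is.na(variance_share(f0, "rare")$share))
})

test_that("the joint frequency-partition model nulls an empty bin", {
  pd <- make_panel_design(n_strains = 200, m = 300, n_parents = 4,
                          n_progeny = 120, seed = 18)
  G <- pd$G
  med <- stats::median(G$markers$panel_maf)
  bins <- bin_markers_by_maf(G$markers, edges = med)
  Ks <- build_partitioned_kinships(G, bins)
  names(Ks) <- c("low", "high")
  # trait built only from high-frequency-bin markers
  M <- standardize_markers(G)
  hi_cols <- which(bins$assignment[match(colnames(M),
                                         G$markers$id)] == 2)
  set.seed(19)
  y <- as.numeric(M[, hi_cols] %*%
                    stats::rnorm(length(hi_cols),
                                 0, sqrt(0.5 / length(hi_cols)))) +
    stats::rnorm(nrow(M), 0, sqrt(0.5))
  fit <- joint_maf_partition_model(y, G$cross, Ks)
  expect_lte(fit$sigma2["low"], 2 * fit$se["low"] + 0.03)
  expect_gt(fit$sigma2["high"], fit$sigma2["low"])
})
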