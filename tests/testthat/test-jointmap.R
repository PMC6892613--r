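test_that("residualization reduces to centering when variance is fixed at 0", {
  set.seed(1)
  y <- stats::rnorm(50)
  s <- residualize_loco(y, K_loco = diag(50),
                        sigma2 = c(A = 0, residual = 1))
  expect_equal(s, y - mean(y), tolerance = 1e-12)
  expect_error(residualize_loco(y, Q = cbind(stats::rnorm(50)),
                                marker_chrom = 2, chrom = 2),
               "chromosome of interest")
})

test_that("residualization removes a planted off-chromosome QTL signal", {
  cr <- make_cross(n = 800, m = 300, n_chroms = 4, seed = 2)
  V <- cr$values[, seg_cols(cr), drop = FALSE]
  mk <- cr$markers[match(colnames(V), cr$markers$id), ]
  j <- which(mk$chrom == 2)[5]  # large QTL on chromosome 2
  y <- planted_trait(list(values = V), j, 0.6, seed = 3)
  off <- which(mk$chrom != 1)
  K_loco <- kinship_gower(standardize_markers(V[, off, drop = FALSE]))
  C <- stats::lm(y ~ V[, j])$coefficients[2]
  s <- residualize_loco(y, Q = V[, j, drop = FALSE], C = C,
                        K_loco = K_loco)
  expect_lt(abs(stats::cor(s, V[, j])), 0.05)
})

test_that("the polygenic BLUP matches Henderson's mixed-model equations", {
  cr <- make_cross(n = 40, m = 80, n_chroms = 2, seed = 4)
  M <- standardize_markers(cr$values[, seg_cols(cr), drop = FALSE])
  K <- unclass(kinship_gower(M))
  K <- K + diag(1e-8, 40)  # keep the oracle's K inverse well-posed
  set.seed(5)
  y <- stats::rnorm(40)
  sA <- 0.6; sE <- 0.4
  s <- residualize_loco(y, K_loco = K, sigma2 = c(A = sA, residual = sE))
  # independent oracle: solve Henderson's MME for (mu, a)
  lambda <- sE / sA
  n <- 40
  lhs <- rbind(cbind(n, t(rep(1, n))),
               cbind(rep(1, n), diag(n) + lambda * solve(K)))
  rhs <- c(sum(y), y)
  sol <- solve(lhs, rhs)
  s_oracle <- y - sol[1] - sol[-1]
  expect_equal(unname(s - mean(s)), unname(s_oracle - mean(s_oracle)),
               tolerance = 1e-8)
})

test_that("the pooled t-statistic follows its closed form and the lm oracle", {
  pd <- make_panel_design(n_strains = 100, m = 200, n_parents = 4,
                          n_progeny = 120, seed = 6)
  G <- pd$G
  set.seed(7)
  y <- stats::rnorm(nrow(G$values))
  sc <- joint_t_scan(y, G)
  tab <- sc$table
  # closed form: t = r * sqrt(n-2) / sqrt(1-r^2), checked at r=0.5, n=102
  expect_equal(0.5 * sqrt(100 / 0.75), 5.773503, tolerance = 1e-6)
  # every scanned marker matches a per-subset least-squares oracle
  yr <- rrqtl:::.center_by_cross(y - mean(y), G$cross)
  seg <- rrqtl:::.segregation_table(G)
  for (k in sample(which(!is.na(tab$t)), 20)) {
    jcol <- tab$index[k]
    rows <- which(as.integer(G$cross) %in% which(seg[jcol, ]))
    fit <- summary(stats::lm(yr[rows] ~ G$values[rows, jcol]))
    expect_equal(unname(tab$t[k]), fit$coefficients[2, "t value"],
                 tolerance = 1e-10)
    expect_equal(tab$n_informative[k], length(rows))
  }
})

test_that("markers with too few informative segregants are skipped", {
  pd <- make_panel_design(n_strains = 100, m = 60, n_parents = 4,
                          n_progeny = 4, seed = 8)
  expect_warning(sc <- joint_t_scan(stats::rnorm(16), pd$G),
                 "skipped")
})

test_that("the joint null permutes within crosses and ignores cross shifts", {
  pd <- make_panel_design(n_strains = 100, m = 150, n_parents = 4,
                          n_progeny = 80, seed = 9)
  G <- pd$G
  set.seed(10)
  s <- stats::rnorm(nrow(G$values))
  n1 <- joint_permutation_null(s, G, B = 100, seed = 11)
  n2 <- joint_permutation_null(s, G, B = 100, seed = 11)
  expect_identical(n1$max_stats, n2$max_stats)
  # adding a per-cross constant leaves the null unchanged
  shift <- c(X01 = 5, X02 = -3, X03 = 0.5, X04 = 100)
  s_shift <- s + shift[as.character(G$cross)]
  n3 <- joint_permutation_null(s_shift, G, B = 100, seed = 11)
  expect_equal(n1$max_stats, n3$max_stats, tolerance = 1e-10)
})

test_that("a single-cross joint analysis reduces to the within-cross scan", {
  cr <- make_cross(n = 150, m = 120, n_chroms = 3, seed = 12)
  cols <- seg_cols(cr)
  V <- cr$values[, cols, drop = FALSE]
  mk <- cr$markers[match(colnames(V), cr$markers$id), ]
  G1 <- structure(list(values = V, cross = factor(rep("X01", 150)),
                       markers = mk),
                  class = "geno_matrix")
  y <- planted_trait(list(values = V), 8, 0.4, seed = 13)
  jq <- joint_forward_stepwise(y, G1, alpha = 0.05, B = 150, seed = 14,
                               loco = FALSE)
  wc <- forward_stepwise(rrqtl:::.std(y), V, alpha = 0.05, B = 150,
                         seed = 14)
  expect_identical(unname(jq$selected), unname(wc$selected))
  expect_equal(jq$steps$p, wc$steps$p, tolerance = 1e-12)
})

test_that("per-cross effect estimation averages betas over crosses", {
  pd <- make_panel_design(n_strains = 150, m = 200, n_parents = 4,
                          n_progeny = 400, seed = 15)
  G <- pd$G
  seg <- rrqtl:::.segregation_table(G)
  j <- which(rowSums(seg) >= 2)[10]
  crosses_j <- which(seg[j, ])
  # plant different true effects in two crosses of a shared variant
  y <- numeric(nrow(G$values))
  true_b <- c(0.2, 0.4, 0.3, 0.25)
  set.seed(16)
  for (ci in seq_len(4)) {
    rows <- which(as.integer(G$cross) == ci)
    if (ci %in% crosses_j) {
      b <- true_b[ci]
      y[rows] <- b * rrqtl:::.std(G$values[rows, j]) +
        stats::rnorm(length(rows), 0, sqrt(1 - b^2))
    } else {
      y[rows] <- stats::rnorm(length(rows))
    }
  }
  eff <- estimate_effects_per_cross(y, G, j)
  betas <- attr(eff, "betas")
  expect_equal(eff$n_crosses, length(crosses_j))
  expect_true(all(is.na(betas[1, -crosses_j])))
  expect_equal(unname(eff$mean_beta),
               mean(true_b[crosses_j]), tolerance = 0.12)
  expect_equal(eff$allele_diff, 2 * eff$mean_beta)
  # noiseless single-cross effect is exact
  rows <- which(as.integer(G$cross) == crosses_j[1])
  y0 <- numeric(nrow(G$values))
  y0[rows] <- 0.3 * rrqtl:::.std(G$values[rows, j])
  G_sub <- structure(list(values = G$values[rows, , drop = FALSE],
                          cross = droplevels(G$cross[rows]),
                          markers = G$markers), class = "geno_matrix")
  e0 <- estimate_effects_per_cross(y0[rows], G_sub, j, standardize = FALSE)
  # beta under -1/+1 coding times the genotype SD = 0.3 per standardized
  # genotype, exactly, for a noiseless trait
  g <- G_sub$values[, j]
  sd_g <- sqrt(mean((g - mean(g))^2))
  expect_equal(unname(e0$mean_beta) * sd_g, 0.3, tolerance = 1e-10)
})

test_that("held-out effect estimates avoid the winner's curse", {
  cr <- make_cross(n = 500, m = 200, n_chroms = 4, seed = 17)
  cols <- seg_cols(cr)
  V <- cr$values[, cols, drop = FALSE]
  mk <- cr$markers[match(colnames(V), cr$markers$id), ]
  G1 <- structure(list(values = V, cross = factor(rep("X01", 500)),
                       markers = mk), class = "geno_matrix")
  j <- 30
  b_true <- 0.18
  diffs <- c()
  n_rep <- 15
  for (r in seq_len(n_rep)) {
    y <- planted_trait(list(values = V), j, b_true, seed = 1700 + r)
    ue <- unbiased_effects(y, G1, holdout_frac = 0.2, alpha = 0.05,
                           B = 100, seed = 1800 + r)
    if (!nrow(ue)) next
    near <- which(mk$chrom[ue$index] == mk$chrom[j] &
                    abs(mk$pos_cM[ue$index] - mk$pos_cM[j]) < 10)
    if (!length(near)) next
    diffs <- rbind(diffs, c(abs(ue$beta_train[near[1]]),
                            abs(ue$beta_holdout[near[1]])))
  }
  skip_if(is.null(diffs) || nrow(diffs) < 5, "too few detections")
  # in-sample magnitudes exceed held-out magnitudes on average
  expect_gt(mean(diffs[, 1]), mean(diffs[, 2]) - 0.01)
  # held-out estimates are centered near the truth
  expect_lt(abs(mean(diffs[, 2]) - b_true), 0.05)
})

test_that("noiseless traits give identical train and held-out estimates", {
  cr <- make_cross(n = 200, m = 80, n_chroms = 2, seed = 19)
  cols <- seg_cols(cr)
  V <- cr$values[, cols, drop = FALSE]
  mk <- cr$markers[match(colnames(V), cr$markers$id), ]
  G1 <- structure(list(values = V, cross = factor(rep("X01", 200)),
                       markers = mk), class = "geno_matrix")
  y <- rrqtl:::.std(V[, 7])
  ue <- unbiased_effects(y, G1, holdout_frac = 0.2, alpha = 0.05, B = 100,
                         seed = 20)
  skip_if(!nrow(ue), "nothing selected")
  k <- ue$index[1]
  # both estimates recover the same projection of the trait on the peak
  expect_equal(ue$beta_train[1], ue$beta_holdout[1], tolerance = 0.05)
  # null trait: no detections
  set.seed(21)
  ue0 <- unbiased_effects(stats::rnorm(200), G1, holdout_frac = 0.2,
                          alpha = 0.05, B = 100, seed = 22)
  expect_lte(nrow(ue0), 1)
})
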