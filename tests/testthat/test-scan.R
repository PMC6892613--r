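test_that("scan statistic is the squared Pearson correlation", {
  cr <- make_cross(n = 50, m = 20, n_chroms = 2, seed = 1)
  cols <- seg_cols(cr)
  V <- cr$values[, cols, drop = FALSE]
  set.seed(2)
  y <- stats::rnorm(50)
  sc <- genome_scan_r2(y, V)
  # independent least-squares oracle per marker
  for (j in seq_len(ncol(V))) {
    fit <- stats::lm(y ~ V[, j])
    expect_equal(unname(sc$stat[j]), summary(fit)$r.squared,
                 tolerance = 1e-12)
  }
  # marker equal to the phenotype -> r2 = 1
  V2 <- cbind(V, y = y)
  sc2 <- genome_scan_r2(y, V2)
  expect_equal(unname(sc2$stat["y"]), 1, tolerance = 1e-12)
  expect_equal(sc2$best_marker, "y")
  # constructed orthogonal marker -> r2 = 0
  g <- rep(c(-1, 1), 25)
  yo <- rep(c(-1, -1, 1, 1), length.out = 50)  # orthogonal to g
  sco <- genome_scan_r2(yo, cbind(g = g))
  expect_lt(unname(sco$stat["g"]), 1e-20)
  expect_error(genome_scan_r2(rep(1, 50), V), "zero variance")
})

test_that("covariate-conditional scan uses covariate residuals", {
  cr <- make_cross(n = 100, m = 30, n_chroms = 2, seed = 3)
  cols <- seg_cols(cr)
  V <- cr$values[, cols, drop = FALSE]
  y <- planted_trait(list(values = V), 1, 0.5, seed = 4)
  sc <- genome_scan_r2(y, V, covariates = 1)
  yr <- stats::lm(y ~ V[, 1])$residuals
  expect_equal(unname(sc$stat[5]), stats::cor(yr, V[, 5])^2,
               tolerance = 1e-12)
})

test_that("empirical p-values follow the counting definition with floor 1/B", {
  null <- structure(list(max_stats = seq_len(10000) / 10000, B = 10000L),
                    class = "perm_null")
  # observed exceeded by 500 of 10,000
  expect_equal(empirical_pvalue(0.95001, null), 0.05)
  # observed above all -> floor 1e-4 at B = 10,000
  expect_equal(empirical_pvalue(2, null), 1e-4)
  # observed below all -> 1
  expect_equal(empirical_pvalue(-1, null), 1)
})

test_that("ForwardStop evaluates its running-mean definition", {
  expect_equal(forwardstop(0), 0)
  expect_equal(forwardstop(numeric(0)), 0)
  # independent arithmetic: -(log(.99) + log(.98) + log(.97)) / 3
  expect_equal(forwardstop(c(0.01, 0.02, 0.03)),
               -(log(0.99) + log(0.98) + log(0.97)) / 3, tolerance = 1e-12)
  expect_equal(round(forwardstop(c(0.01, 0.02, 0.03)), 6), 0.020237)
  expect_equal(forwardstop(1e-4), -log(0.9999), tolerance = 1e-12)
  expect_error(forwardstop(c(0.5, 1)), "p = 1")
  # monotone non-decreasing in each p
  set.seed(1)
  p <- sort(stats::runif(5, 0, 0.3))
  f0 <- forwardstop(p)
  for (i in seq_along(p)) {
    p2 <- p; p2[i] <- p2[i] + 0.05
    expect_gte(forwardstop(p2), f0)
  }
})

test_that("permutation null is reproducible and beaten by a planted signal", {
  cr <- make_cross(n = 100, m = 50, n_chroms = 2, seed = 5)
  cols <- seg_cols(cr)
  V <- cr$values[, cols, drop = FALSE]
  set.seed(6)
  y <- stats::rnorm(100)
  n1 <- max_stat_permutation_null(y, V, B = 200, seed = 7)
  n2 <- max_stat_permutation_null(y, V, B = 200, seed = 7)
  expect_identical(n1$max_stats, n2$max_stats)
  # duplicating the phenotype as a marker forces the observed max past the null
  V2 <- cbind(V, y)
  sc <- genome_scan_r2(y, V2)
  expect_true(all(sc$best_stat > n1$max_stats))
  expect_error(max_stat_permutation_null(y, V, B = 0), "at least 1")
})

test_that("permutation p-values of null traits are uniform", {
  # many independent null traits, each with its own permutation null
  cr <- make_cross(n = 200, m = 400, n_chroms = 4, seed = 8)
  cols <- seg_cols(cr)
  V <- cr$values[, cols, drop = FALSE]
  n_traits <- 500
  B <- 200
  set.seed(9)
  p <- numeric(n_traits)
  for (t in seq_len(n_traits)) {
    y <- stats::rnorm(200)
    sc <- genome_scan_r2(y, V)
    nl <- max_stat_permutation_null(y, V, B = B, seed = 10000 + t)
    p[t] <- empirical_pvalue(sc$best_stat, nl)
  }
  sp <- sort(p)
  D <- max(pmax(abs(seq_len(n_traits) / n_traits - sp),
                abs(sp - (seq_len(n_traits) - 1) / n_traits)))
  expect_lt(D, 0.05)
})

test_that("forward stepwise selects planted QTL and stops under alpha", {
  cr <- make_cross(n = 300, m = 200, n_chroms = 4, seed = 11)
  cols <- seg_cols(cr)
  V <- cr$values[, cols, drop = FALSE]
  j <- 25
  y <- planted_trait(list(values = V), j, 0.5, seed = 12)
  tr <- forward_stepwise(y, V, alpha = 0.05, B = 200, seed = 13)
  expect_gte(length(tr$selected), 1)
  # first selected marker is the causal one or a tightly linked neighbor
  pos <- cr$markers$pos_cM[match(colnames(V), cr$markers$id)]
  chr <- cr$markers$chrom[match(colnames(V), cr$markers$id)]
  k <- tr$selected[1]
  expect_equal(chr[k], chr[j])
  expect_lt(abs(pos[k] - pos[j]), 10)
  # alpha = 0 selects nothing
  tr0 <- forward_stepwise(y, V, alpha = 0, B = 50, seed = 13)
  expect_length(tr0$selected, 0)
  # selected size never exceeds steps with ForwardStop <= alpha
  expect_lte(length(tr$selected), sum(tr$steps$forwardstop <= 0.05))
  # no markers -> empty trace
  tr_empty <- forward_stepwise(y, V[, 0, drop = FALSE], alpha = 0.05)
  expect_length(tr_empty$selected, 0)
})

test_that("re-localization never decreases the model likelihood", {
  cr <- make_cross(n = 300, m = 120, n_chroms = 3, seed = 14)
  cols <- seg_cols(cr)
  V <- cr$values[, cols, drop = FALSE]
  mk <- cr$markers[match(colnames(V), cr$markers$id), ]
  G <- list(values = V, markers = mk)
  # two linked planted QTL on one chromosome
  j1 <- which(mk$chrom == 2)[3]
  j2 <- which(mk$chrom == 2)[12]
  set.seed(15)
  y <- 0.4 * rrqtl:::.std(V[, j1]) + 0.3 * rrqtl:::.std(V[, j2]) +
    stats::rnorm(300, 0, sqrt(0.7))
  tr <- forward_stepwise(y, V, alpha = 0.05, B = 200, seed = 16)
  skip_if(length(tr$selected) < 1, "nothing selected in fixture")
  rss_of <- function(sel) {
    sum(stats::lm.fit(cbind(1, V[, sel, drop = FALSE]), y)$residuals^2)
  }
  before <- rss_of(tr$selected)
  tr2 <- relocalize_peaks(y, G, tr)
  expect_lte(rss_of(tr2$selected), before + 1e-12)
  # re-localizing an already optimal peak set is a fixed point
  tr3 <- relocalize_peaks(y, G, tr2)
  expect_identical(tr3$selected, tr2$selected)
})

test_that("noiseless single-QTL traits re-localize to the causal marker", {
  cr <- make_cross(n = 200, m = 100, n_chroms = 2, seed = 17)
  cols <- seg_cols(cr)
  V <- cr$values[, cols, drop = FALSE]
  mk <- cr$markers[match(colnames(V), cr$markers$id), ]
  j <- 10
  y <- rrqtl:::.std(V[, j])  # no noise
  tr <- structure(list(selected = 15L,
                       steps = data.frame(step = 1, marker = colnames(V)[15],
                                          index = 15L, stat = NA, p = NA,
                                          forwardstop = NA, selected = TRUE)),
                  class = "qtl_trace")
  tr2 <- relocalize_peaks(y, list(values = V, markers = mk), tr)
  # the causal marker (or a perfect-LD copy) maximizes the likelihood
  expect_equal(stats::cor(V[, tr2$selected], V[, j])^2, 1, tolerance = 1e-12)
})

test_that("LOD-drop intervals behave at their limits and cover the QTL", {
  cr <- make_cross(n = 400, m = 200, n_chroms = 2, seed = 18)
  cols <- seg_cols(cr)
  V <- cr$values[, cols, drop = FALSE]
  mk <- cr$markers[match(colnames(V), cr$markers$id), ]
  G <- list(values = V, markers = mk)
  j <- which(mk$chrom == 1)[10]
  # infinite drop spans the whole chromosome
  y <- planted_trait(list(values = V), j, 0.4, seed = 19)
  ci <- lod_drop_interval(y, G, peak = j, drop = Inf)
  chr1 <- which(mk$chrom == 1)
  expect_equal(ci$left, min(chr1))
  expect_equal(ci$right, max(chr1))
  expect_error(lod_drop_interval(y, G, peak = 10 * ncol(V)), "peak")
  # coverage of the causal marker across replicates
  hit <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    yr <- planted_trait(list(values = V), j, 0.3, seed = 100 + r)
    scr <- genome_scan_r2(yr, V)
    cir <- lod_drop_interval(yr, G, peak = scr$best_index, drop = 1.5)
    hit <- hit + (cir$left <= j && j <= cir$right &&
                    mk$chrom[scr$best_index] == mk$chrom[j])
  }
  expect_gte(hit / n_rep, 0.9)
})

test_that("cross-validated variance explained is calibrated at the extremes", {
  cr <- make_cross(n = 200, m = 100, n_chroms = 2, seed = 21)
  cols <- seg_cols(cr)
  V <- cr$values[, cols, drop = FALSE]
  # noiseless oligogenic trait: nearly all variance explained out of fold
  set.seed(22)
  jj <- round(c(0.1, 0.5, 0.9) * ncol(V))
  y <- rrqtl:::.std(V[, jj[1]]) + 0.8 * rrqtl:::.std(V[, jj[2]]) +
    0.6 * rrqtl:::.std(V[, jj[3]])
  cv <- crossval_variance_explained(y, V, folds = 5, B = 100, seed = 23)
  expect_gte(cv$r2_cv, 0.98)
  expect_error(crossval_variance_explained(y[1:30], V[1:30, ], folds = 5),
               "fewer than 10")
  # null traits give R2 near zero on average
  r2s <- vapply(1:20, function(r) {
    yn <- stats::rnorm(200)
    crossval_variance_explained(yn, V, folds = 5, B = 100,
                                seed = 300 + r)$r2_cv
  }, numeric(1))
  expect_lt(abs(mean(r2s)), 0.05)
})
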