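# Internal helpers shared across modules.

# Population-moment standardization of a numeric vector: mean 0, variance 1
# with variance computed as mean of squared deviations (divides by n, not n-1).
# This convention makes MM'/m have average diagonal exactly 1.
.std <- function(x) {
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 <= 0) stop("cannot standardize a constant vector")
  (x - mu) / sqrt(s2)
}

# Column-wise population-moment standardization of a matrix (no missing values).
.std_cols <- function(M) {
  mu <- colMeans(M)
  Mc <- sweep(M, 2L, mu, "-")
  s <- sqrt(colMeans(Mc^2))
  if (any(s <= 0)) stop("constant column encountered during standardization")
  sweep(Mc, 2L, s, "/")
}

# Residualize y on the columns of X (with intercept); returns the residual.
.resid_on <- function(y, X = NULL) {
  if (is.null(X) || NCOL(X) == 0L) return(y - mean(y))
  stats::lm.fit(cbind(1, as.matrix(X)), y)$residuals
}

# Draw a seed for a sub-stream from a parent seed, staying inside 32-bit range.
.subseed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L
}

.is_wholenumber <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

# Unwrap a genotype container: accepts a geno_matrix, any list carrying a
# $values matrix, or a plain matrix.
.geno_values <- function(G) {
  if (is.list(G) && !is.null(G$values)) G$values else G
}

# Remove per-cross means: pooled correlations must not be driven by
# between-cross location differences, and the within-cross permutation null
# becomes invariant to cross-specific shifts.
.center_by_cross <- function(y, cross) {
  for (cr in levels(cross)) {
    rows <- which(cross == cr)
    y[rows] <- y[rows] - mean(y[rows])
  }
  y
}
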