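#' Restricted maximum likelihood estimation of variance components
#'
#' Fits the linear mixed model y = X beta + sum_i u_i + e with
#' u_i ~ N(0, sigma2_i K_i) by Newton iterations on the restricted
#' likelihood, using expected (Fisher) information updates with step halving.
#' The final kernel is always the identity on observations (the residual).
#' Variances are constrained non-negative by projection: a component pinned
#' at zero with a negative score stays at zero. Standard errors are the
#' square roots of the diagonal of the inverse Fisher information at the
#' final iteration.
#'
#' Kernels defined on segregants can be expanded to replicated observations
#' via the incidence matrix \code{Z} (L observations x n segregants); a
#' kernel given as the character \code{"segregant"} becomes the identity on
#' segregants, i.e. Z Z', which models segregant-level repeatability.
#'
#' @param y observation vector of length L.
#' @param kernels named list of n x n (or L x L) PSD covariance kernels; a
#'   residual identity component is appended automatically.
#' @param X fixed-effect design matrix (default: intercept).
#' @param Z optional L x n incidence matrix mapping observations to
#'   segregants; required when L exceeds the kernel dimension.
#' @param tol convergence tolerance on the scaled score.
#' @param max_iter maximum Newton iterations.
#' @param constrain if FALSE, variances may go negative (unconstrained REML).
#' @param verbose print iteration progress.
#' @return object of class \code{vc_fit}: list with \code{sigma2}, \code{se},
#'   \code{loglik} (restricted, up to an additive constant), \code{converged},
#'   \code{n_iter}, \code{fisher} (information matrix), and bookkeeping.
#' @export
reml_fit <- function(y, kernels, X = NULL, Z = NULL, tol = 1e-6,
                     max_iter = 100L, constrain = TRUE, verbose = FALSE) {
  L <- length(y)
  if (is.null(X)) X <- matrix(1, L, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design")
  Ks <- lapply(kernels, function(K) {
    if (is.character(K) && identical(K, "segregant")) {
      if (is.null(Z)) stop("'segregant' kernel needs an incidence matrix Z")
      return(tcrossprod(Z))
    }
    K <- unclass(as.matrix(K))
    if (nrow(K) != L) {
      if (is.null(Z) || nrow(K) != ncol(Z))
        stop("kernel dimension inconsistent with observations/Z")
      K <- Z %*% K %*% t(Z)
    }
    K
  })
  Ks <- c(Ks, list(residual = diag(L)))
  k <- length(Ks)
  vy <- stats::var(y)
  sigma2 <- rep(vy / k, k)  # equal split initialization

  restricted_ll <- function(s2) {
    V <- matrix(0, L, L)
    for (i in seq_len(k)) V <- V + s2[i] * Ks[[i]]
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(list(ok = FALSE))
    ldV <- 2 * sum(log(diag(cV)))
    Vi <- chol2inv(cV)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    cXX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cXX)) return(list(ok = FALSE))
    W <- chol2inv(cXX)
    Viy <- Vi %*% y
    Py <- Viy - ViX %*% (W %*% crossprod(ViX, y))
    ll <- -0.5 * (ldV + 2 * sum(log(diag(cXX))) + sum(y * Py))
    list(ok = TRUE, ll = ll, Vi = Vi, ViX = ViX, W = W, Py = Py)
  }

  st <- restricted_ll(sigma2)
  if (!st$ok) { sigma2 <- rep(vy / k, k); st <- restricted_ll(sigma2) }
  if (!st$ok) stop("initial covariance matrix is not positive definite")
  converged <- FALSE
  Fmat <- NULL
  score <- rep(NA_real_, k)
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # P K_i for each kernel: P = Vi - ViX W (ViX)'
    PK <- vector("list", k)
    for (i in seq_len(k)) {
      ViK <- st$Vi %*% Ks[[i]]
      PK[[i]] <- ViK - st$ViX %*% (st$W %*% crossprod(st$ViX, Ks[[i]]))
    }
    u <- as.numeric(st$Py)
    score <- vapply(seq_len(k), function(i)
      -0.5 * (sum(diag(PK[[i]])) - sum(u * (Ks[[i]] %*% u))), numeric(1))
    Fmat <- matrix(0, k, k)
    for (i in seq_len(k)) for (j in i:k) {
      Fmat[i, j] <- Fmat[j, i] <- 0.5 * sum(PK[[i]] * t(PK[[j]]))
    }
    active <- rep(TRUE, k)
    if (constrain) active <- !(sigma2 <= 0 & score < 0)
    sc_a <- score[active]
    if (!length(sc_a) || max(abs(sc_a)) < tol * max(1, L * vy)) {
      converged <- TRUE
      break
    }
    Fa <- Fmat[active, active, drop = FALSE]
    delta <- rep(0, k)
    delta[active] <- tryCatch(solve(Fa + diag(1e-10, nrow(Fa)), sc_a),
                              error = function(e) sc_a / diag(Fa))
    # step halving with non-negativity projection
    step <- 1
    improved <- FALSE
    for (h in 1:30) {
      cand <- sigma2 + step * delta
      if (constrain) cand <- pmax(cand, 0)
      if (sum(cand) <= 0) { step <- step / 2; next }
      st2 <- restricted_ll(cand)
      if (st2$ok && st2$ll >= st$ll - 1e-12) {
        rel <- abs(st2$ll - st$ll) / max(1, abs(st$ll))
        sigma2 <- cand
        st <- st2
        improved <- TRUE
        if (rel < 1e-10 && h == 1) {
          # loglik flat at full step: treat as converged
          converged <- TRUE
        }
        break
      }
      step <- step / 2
    }
    if (verbose)
      cat(sprintf("iter %d  ll %.6f  sigma2 %s\n", iter, st$ll,
                  paste(signif(sigma2, 4), collapse = " ")))
    if (!improved || converged) { converged <- converged || !improved; break }
  }
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations")
  se <- sqrt(pmax(diag(tryCatch(solve(Fmat), error = function(e)
    matrix(NA_real_, k, k))), 0))
  nm <- c(names(kernels), "residual")
  names(sigma2) <- names(se) <- nm
  dimnames(Fmat) <- list(nm, nm)
  structure(list(sigma2 = sigma2, se = se, loglik = st$ll,
                 converged = converged, n_iter = iter, fisher = Fmat,
                 score = stats::setNames(score, nm), n_obs = L,
                 kernels = nm),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("REML variance-component fit (", x$n_obs, " observations, ",
      x$n_iter, " iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  tab <- data.frame(component = names(x$sigma2),
                    sigma2 = round(x$sigma2, 5), se = round(x$se, 5))
  print(tab, row.names = FALSE)
  cat("restricted log-likelihood:", round(x$loglik, 4), "\n")
  invisible(x)
}

#' @export
summary.vc_fit <- function(object, ...) {
  tot <- sum(object$sigma2)
  tab <- data.frame(component = names(object$sigma2),
                    sigma2 = object$sigma2, se = object$se,
                    share = object$sigma2 / tot)
  structure(list(table = tab, loglik = object$loglik,
                 converged = object$converged), class = "summary.vc_fit")
}

#' @export
print.summary.vc_fit <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.vc_fit <- function(object, ...) object$sigma2

#' @export
logLik.vc_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$sigma2), class = "logLik")
}

#' @export
vcov.vc_fit <- function(object, ...) {
  solve(object$fisher)
}
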