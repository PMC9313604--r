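#' EM-REML for mixed models with independent random factors
#'
#' Fits y = X beta + sum_k Z_k u_k + e with u_k ~ N(0, I sigma_k^2) and
#' e ~ N(0, I sigma_e^2) by EM-REML on Henderson's mixed-model equations.
#' Each EM step solves the MME at the current variance ratios and updates
#' sigma_k^2 = (u_k'u_k + sigma_e^2 tr(C_kk)) / q_k and
#' sigma_e^2 = y'(y - X beta - Z u) / (n - rank(X)). The REML log-likelihood
#' is non-decreasing across iterations.
#'
#' @param y response vector
#' @param X fixed-effect design matrix (full column rank; cell-means coding
#'   recommended)
#' @param Z named list of random-factor incidence matrices
#' @param tol convergence tolerance on the max relative variance change
#' @param maxit maximum EM iterations
#' @param loglik compute the REML log-likelihood trace (O(n^3) per iteration;
#'   intended for small problems / diagnostics)
#' @return object of class \code{emreml_fit}: \code{sigma2} (named, includes
#'   \code{residual}), \code{beta}, \code{u}, \code{beta_cov}, \code{loglik},
#'   \code{converged}, \code{iterations}
#' @export
emreml <- function(y, X, Z, tol = 1e-6, maxit = 500, loglik = FALSE) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(Z) >= 1)
  if (is.null(names(Z))) names(Z) <- paste0("u", seq_along(Z))
  Z <- lapply(Z, as.matrix)
  qs <- vapply(Z, ncol, 1L)
  p <- qr(X)$rank
  if (p < ncol(X)) stop("fixed-effect design is rank deficient")
  W <- cbind(X, do.call(cbind, Z))
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  vary <- stats::var(y)
  if (!is.finite(vary) || vary <= 0) vary <- 1
  K <- length(Z)
  s2 <- rep(vary / (K + 1), K)
  se2 <- vary / (K + 1)
  names(s2) <- names(Z)
  off <- ncol(X) + c(0, cumsum(qs))
  lo <- 1e-10 * vary
  ll_trace <- numeric(0)
  conv <- FALSE
  it <- 0
  while (it < maxit) {
    it <- it + 1
    M <- WtW
    for (k in seq_len(K)) {
      idx <- (off[k] + 1):off[k + 1]
      diag(M)[idx] <- diag(WtW)[idx] + se2 / s2[k]
    }
    R <- chol(M)
    sol <- backsolve(R, backsolve(R, Wty, transpose = TRUE))
    Minv <- chol2inv(R)
    beta <- sol[seq_len(ncol(X))]
    resid <- y - W %*% sol
    se2_new <- sum(y * resid) / (n - p)
    se2_new <- max(se2_new, lo)
    s2_new <- s2
    for (k in seq_len(K)) {
      idx <- (off[k] + 1):off[k + 1]
      uk <- sol[idx]
      s2_new[k] <- (sum(uk^2) + se2 * sum(diag(Minv)[idx])) / qs[k]
      s2_new[k] <- max(s2_new[k], lo)
    }
    if (loglik) ll_trace <- c(ll_trace, reml_loglik(y, X, Z, s2_new, se2_new))
    delta <- max(abs(c(s2_new - s2, se2_new - se2)) /
                   pmax(abs(c(s2, se2)), 1e-12))
    s2 <- s2_new; se2 <- se2_new
    if (delta < tol) { conv <- TRUE; break }
  }
  # final solve at converged variances
  M <- WtW
  for (k in seq_len(K)) {
    idx <- (off[k] + 1):off[k + 1]
    diag(M)[idx] <- diag(WtW)[idx] + se2 / s2[k]
  }
  R <- chol(M)
  sol <- backsolve(R, backsolve(R, Wty, transpose = TRUE))
  Minv <- chol2inv(R)
  u <- lapply(seq_len(K), function(k) sol[(off[k] + 1):off[k + 1]])
  names(u) <- names(Z)
  s2[s2 <= 2 * lo] <- 0   # floor vanishing components at zero
  structure(list(sigma2 = c(s2, residual = se2),
                 beta = stats::setNames(sol[seq_len(ncol(X))], colnames(X)),
                 u = u,
                 beta_cov = se2 * Minv[seq_len(ncol(X)), seq_len(ncol(X)),
                                       drop = FALSE],
                 loglik = ll_trace, converged = conv, iterations = it),
            class = "emreml_fit")
}

#' @export
print.emreml_fit <- function(x, ...) {
  cat("EM-REML fit (", x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  print(round(x$sigma2, 6))
  invisible(x)
}

#' REML log-likelihood of an independent-factor mixed model
#'
#' Direct dense evaluation of -0.5 (log|V| + log|X'V^-1 X| + y'Py); meant for
#' small problems and for checking that EM iterations do not decrease the
#' objective.
#'
#' @param y,X,Z as in \code{\link{emreml}}
#' @param sigma2 vector of random-factor variances (in Z order)
#' @param sigma2_e residual variance
#' @return scalar REML log-likelihood (up to an additive constant)
#' @export
reml_loglik <- function(y, X, Z, sigma2, sigma2_e) {
  n <- length(y)
  V <- diag(sigma2_e, n)
  for (k in seq_along(Z)) V <- V + sigma2[k] * tcrossprod(as.matrix(Z[[k]]))
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       crossprod(y, P %*% y)))
}
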