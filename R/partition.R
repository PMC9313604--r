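# symmetric inverse square root via eigendecomposition
inv_sqrt_sym <- function(M, eps = 1e-10) {
  ee <- eigen(M, symmetric = TRUE)
  lam <- pmax(ee$values, eps * max(ee$values))
  ee$vectors %*% (t(ee$vectors) / sqrt(lam))
}

kernel_names <- c(d = "K_d", aa = "K_aa", ad = "K_ad", dd = "K_dd")

#' Multi-kernel Bayesian variance partitioning of MPH
#'
#' Fits y = mu + g_d + g_aa + g_ad + g_dd + e with g_x ~ N(0, K_x sigma_x^2)
#' and e ~ N(0, TT' sigma_e^2) by a Gibbs sampler. The residual covariance is
#' honored by pre-whitening y and the kernels with (TT')^{-1/2}; each kernel is
#' eigendecomposed once so every Gibbs update is a rotation. Variance priors
#' are scaled-inverse-chi-squared with \code{df0} degrees of freedom and scales
#' matched to an equal split of half the sample variance across terms.
#'
#' @param y MPH vector (hybrids)
#' @param kernels a \code{kernel_set} (or any named list of PSD matrices)
#' @param model character subset of c("d","aa","ad","dd") naming the kernels
#'   to include
#' @param TTt residual structure matrix T T' (NULL for i.i.d. residuals)
#' @param n_iter,burn_in,thin chain length, burn-in, thinning
#' @param n_chains independent chains (different starting streams); thinned
#'   draws are pooled. More than one chain stabilizes posterior means when the
#'   kernels are strongly correlated
#' @param df0 prior degrees of freedom
#' @param seed random seed
#' @param verbose print progress
#' @return object of class \code{mk_fit}: posterior means \code{sigma2},
#'   \code{prop_genetic} (fractions of the summed genetic variance),
#'   \code{prop_total} (fractions including the residual), thinned
#'   \code{chains}, split-chain \code{rhat}, and the whitening used
#' @export
fit_multikernel <- function(y, kernels, model = c("d", "aa", "ad", "dd"),
                            TTt = NULL, n_iter = 10000, burn_in = 2000,
                            thin = 5, n_chains = 1, df0 = 5, seed = 1,
                            verbose = FALSE) {
  model <- match.arg(model, c("d", "aa", "ad", "dd"), several.ok = TRUE)
  n <- length(y)
  Ks <- lapply(model, function(m) {
    K <- kernels[[kernel_names[[m]]]]
    if (is.null(K)) K <- kernels[[m]]
    if (is.null(K)) stop("kernel for term '", m, "' not found")
    stopifnot(nrow(K) == n)
    K
  })
  names(Ks) <- model
  # expected variance contributed per unit sigma^2_x across entries:
  # var(g_x) = sigma^2_x (mean diag K - mean K); uncentered kernels carry a
  # large shared mean term, so sigma^2 alone is not on the variance scale
  w_var <- vapply(Ks, function(K) mean(diag(K)) - mean(K), 0)
  whitened <- !is.null(TTt) && max(abs(TTt - diag(n))) > 1e-12
  if (whitened) {
    W <- inv_sqrt_sym(TTt)
    yw <- as.vector(W %*% y)
    one <- as.vector(W %*% rep(1, n))
    Ks <- lapply(Ks, function(K) W %*% K %*% W)
  } else {
    W <- NULL
    yw <- y
    one <- rep(1, n)
  }
  eig <- lapply(Ks, function(K) {
    ee <- eigen((K + t(K)) / 2, symmetric = TRUE)
    keep <- ee$values > 1e-8 * max(ee$values)
    if (!any(keep)) stop("kernel is not positive semi-definite or is zero")
    if (min(ee$values) < -1e-6 * max(ee$values)) {
      stop("kernel has substantially negative eigenvalues")
    }
    list(G = ee$vectors[, keep, drop = FALSE], lam = ee$values[keep])
  })
  K <- length(eig)
  vy <- stats::var(yw)
  S0g <- 0.5 * vy * (df0 - 2) / df0 / K
  S0e <- 0.5 * vy * (df0 - 2) / df0
  oto <- sum(one^2)
  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    s2 <- rep(0.5 * vy / K, K); names(s2) <- model
    se2 <- 0.5 * vy
    b <- lapply(eig, function(e) numeric(length(e$lam)))
    mu <- 0
    e_res <- yw - mu * one
    keep_iter <- seq(burn_in + 1, n_iter, by = thin)
    draws <- matrix(NA_real_, length(keep_iter), K + 1,
                    dimnames = list(NULL, c(model, "residual")))
    ki <- 0
    for (it in seq_len(n_iter)) {
      # intercept
      prec <- oto / se2
      mo <- sum(one * (e_res + mu * one)) / se2
      mu_new <- stats::rnorm(1, mo / prec, sqrt(1 / prec))
      e_res <- e_res + (mu - mu_new) * one
      mu <- mu_new
      for (k in sample.int(K)) {  # random scan order aids mixing on the ridge
        G <- eig[[k]]$G; lam <- eig[[k]]$lam
        t_k <- as.vector(crossprod(G, e_res)) + b[[k]]   # G'G = I
        cvar <- 1 / (1 / se2 + 1 / (lam * s2[k]))
        b_new <- stats::rnorm(length(lam), cvar * t_k / se2, sqrt(cvar))
        e_res <- as.vector(e_res + G %*% (b[[k]] - b_new))
        b[[k]] <- b_new
        ss <- sum(b_new^2 / lam)
        s2[k] <- (ss + df0 * S0g) / stats::rchisq(1, df0 + length(lam))
      }
      se2 <- (sum(e_res^2) + df0 * S0e) / stats::rchisq(1, df0 + n)
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        ki <- ki + 1
        draws[ki, ] <- c(s2, se2)
      }
      if (verbose && it %% 2000 == 0) message("chain iter ", it)
    }
    list(draws = draws, mu = mu)
  }
  chain_fits <- lapply(seq_len(n_chains), function(cc) run_chain(seed + 7919 * (cc - 1)))
  chains <- do.call(rbind, lapply(chain_fits, `[[`, "draws"))
  mu <- mean(vapply(chain_fits, `[[`, 0, "mu"))
  post <- colMeans(chains)
  gen <- post[model]
  rhat <- apply(chains, 2, split_rhat)
  if (any(rhat > 1.2, na.rm = TRUE)) {
    warning("split-chain diagnostic > 1.2 for: ",
            paste(names(rhat)[rhat > 1.2], collapse = ", "))
  }
  gvar <- gen * w_var
  structure(list(sigma2 = post,
                 prop_genetic = gvar / sum(gvar),
                 prop_sigma = gen / sum(gen),
                 prop_total = post / sum(post),
                 var_weights = w_var,
                 chains = chains, rhat = rhat, model = model,
                 mu = mu, whitened = whitened, W = W,
                 df0 = df0, seed = seed),
            class = "mk_fit")
}

# split-half potential-scale-reduction on one chain
split_rhat <- function(x) {
  m <- length(x) %/% 2
  if (m < 4) return(NA_real_)
  h1 <- x[seq_len(m)]; h2 <- x[(m + 1):(2 * m)]
  W <- (stats::var(h1) + stats::var(h2)) / 2
  B <- m * stats::var(c(mean(h1), mean(h2)))
  if (W <= 0) return(NA_real_)
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("multi-kernel fit (", paste(x$model, collapse = "+"),
      if (x$whitened) ", TT'-whitened", ")\n", sep = "")
  cat("posterior-mean variances:\n"); print(round(x$sigma2, 4))
  cat("fractions of genetic variance:\n"); print(round(x$prop_genetic, 3))
  invisible(x)
}

#' @export
summary.mk_fit <- function(object, ...) {
  qs <- apply(object$chains, 2, stats::quantile, c(0.05, 0.5, 0.95))
  out <- rbind(mean = object$sigma2, qs, rhat = object$rhat)
  t(out)
}

#' Bayesian ridge prediction of per-SNP dominance effects
#'
#' Gibbs sampler for y = mu + V beta + e with beta_j ~ N(0, sigma_b^2) i.i.d.
#' (a Bayesian ridge on the dominance covariables) and scaled-inverse-chi-
#' squared priors on both variances. Posterior-mean effects are the dominance
#' weights used by the heterotic genetic distance. Constant covariables get
#' effect 0 by convention.
#'
#' @param y trait or MPH vector
#' @param V dominance coding matrix (entries x SNPs), e.g.
#'   \code{build_codings(g)$V}
#' @param n_iter,burn_in chain length and burn-in
#' @param df0 prior degrees of freedom
#' @param seed random seed
#' @return list: \code{effect} (posterior mean per SNP), \code{mu},
#'   \code{sigma2_b}, \code{sigma2_e}
#' @export
predict_dominance_effects <- function(y, V, n_iter = 2000, burn_in = 500,
                                      df0 = 5, seed = 1) {
  set.seed(seed)
  V <- as.matrix(V)
  n <- length(y)
  stopifnot(nrow(V) == n, ncol(V) >= 1)
  xtx <- colSums(V^2) - n * colMeans(V)^2   # centered ssq to spot constants
  active <- which(xtx > 1e-12)
  ssq <- colSums(V^2)
  p <- length(active)
  if (!p) {
    return(list(effect = numeric(ncol(V)), mu = mean(y),
                sigma2_b = 0, sigma2_e = stats::var(y)))
  }
  vy <- stats::var(y)
  S0e <- 0.5 * vy * (df0 - 2) / df0
  S0b <- 0.5 * vy * (df0 - 2) / df0 / mean(ssq[active])
  beta <- numeric(ncol(V))
  mu <- mean(y)
  sb2 <- max(S0b, 1e-8)
  se2 <- 0.5 * vy
  e <- y - mu
  beta_acc <- numeric(ncol(V))
  n_acc <- 0
  for (it in seq_len(n_iter)) {
    mu_new <- stats::rnorm(1, mu + mean(e), sqrt(se2 / n))
    e <- e + (mu - mu_new)
    mu <- mu_new
    for (j in active) {
      xj <- V[, j]
      rhs <- sum(xj * e) + ssq[j] * beta[j]
      prec <- ssq[j] / se2 + 1 / sb2
      bn <- stats::rnorm(1, rhs / se2 / prec, sqrt(1 / prec))
      e <- e + xj * (beta[j] - bn)
      beta[j] <- bn
    }
    sb2 <- (sum(beta[active]^2) + df0 * S0b) / stats::rchisq(1, df0 + p)
    se2 <- (sum(e^2) + df0 * S0e) / stats::rchisq(1, df0 + n)
    if (it > burn_in) {
      beta_acc <- beta_acc + beta
      n_acc <- n_acc + 1
    }
  }
  list(effect = beta_acc / n_acc, mu = mu, sigma2_b = sb2, sigma2_e = se2)
}

# BLUP-style kernel prediction of held-out entries given variance components
kernel_blup_predict <- function(y_tr, idx_tr, idx_te, Ks, s2, se2, TTt = NULL) {
  n_tr <- length(idx_tr)
  Vtr <- if (is.null(TTt)) diag(se2, n_tr) else se2 * TTt[idx_tr, idx_tr]
  C_te <- matrix(0, length(idx_te), n_tr)
  for (k in seq_along(Ks)) {
    Vtr <- Vtr + s2[k] * Ks[[k]][idx_tr, idx_tr]
    C_te <- C_te + s2[k] * Ks[[k]][idx_te, idx_tr]
  }
  mu <- mean(y_tr)
  as.vector(mu + C_te %*% solve(Vtr, y_tr - mu))
}

#' Cross-validated genomic prediction of MPH
#'
#' k-fold cross-validation repeated \code{n_rep} times: variance components
#' are re-estimated on the training folds (\code{\link{fit_multikernel}}) and
#' held-out hybrids are predicted by kernel BLUP at the posterior-mean
#' components. Reports the per-fold Pearson correlations and their mean; when
#' \code{h2} is supplied, the correlation divided by sqrt(h2) is also reported
#' as the fraction of heritable (genetic) variation captured.
#'
#' @param y MPH vector
#' @param kernels a \code{kernel_set}
#' @param models named list of kernel subsets, e.g.
#'   \code{list(dom = "d", epi_aa = "aa", full = c("d","aa","ad","dd"))}
#' @param TTt residual structure (NULL for i.i.d.)
#' @param k_folds folds per repeat
#' @param n_rep repeats (fresh random split each time)
#' @param h2 optional heritability for the scaled predictive ability
#' @param chain list(n_iter, burn_in, thin) for the training-fold fits
#' @param seed random seed
#' @return object of class \code{cv_result}: data.frame \code{folds} (model,
#'   rep, fold, r) and matrix \code{summary} (mean r per model, and r/sqrt(h2)
#'   when given)
#' @export
cross_validate <- function(y, kernels, models, TTt = NULL, k_folds = 5,
                           n_rep = 100, h2 = NULL,
                           chain = list(n_iter = 1500, burn_in = 500, thin = 5),
                           seed = 1) {
  n <- length(y)
  if (n < 5 * k_folds) stop("need n >= 5 * k_folds hybrids")
  if (is.null(names(models))) {
    names(models) <- vapply(models, paste, "", collapse = "+")
  }
  set.seed(seed)
  rows <- list()
  for (rp in seq_len(n_rep)) {
    repeat {
      fold <- sample(rep_len(seq_len(k_folds), n))
      if (min(table(fold)) >= 2) break
    }
    for (mn in names(models)) {
      mdl <- models[[mn]]
      Ks <- lapply(mdl, function(m) kernels[[kernel_names[[m]]]])
      for (fd in seq_len(k_folds)) {
        te <- which(fold == fd); tr <- which(fold != fd)
        Ks_tr <- lapply(Ks, function(K) K[tr, tr])
        names(Ks_tr) <- mdl
        fit <- fit_multikernel(y[tr], Ks_tr, model = mdl,
                               TTt = if (is.null(TTt)) NULL else TTt[tr, tr],
                               n_iter = chain$n_iter, burn_in = chain$burn_in,
                               thin = chain$thin,
                               seed = seed + 131 * rp + fd)
        pred <- kernel_blup_predict(y[tr], tr, te, Ks,
                                    fit$sigma2[mdl], fit$sigma2[["residual"]],
                                    TTt)
        rows[[length(rows) + 1]] <- data.frame(model = mn, rep = rp, fold = fd,
                                               r = suppressWarnings(
                                                 stats::cor(pred, y[te])),
                                               stringsAsFactors = FALSE)
      }
    }
  }
  folds <- do.call(rbind, rows)
  mean_r <- tapply(folds$r, folds$model, mean, na.rm = TRUE)
  summ <- cbind(r = mean_r)
  if (!is.null(h2)) summ <- cbind(summ, r_scaled = mean_r / sqrt(h2))
  structure(list(folds = folds, summary = summ, k_folds = k_folds,
                 n_rep = n_rep, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cross-validation (", x$k_folds, "-fold x ", x$n_rep, " repeats)\n",
      sep = "")
  print(round(x$summary, 4))
  invisible(x)
}
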