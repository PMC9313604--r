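#' Whitening transform from a fitted null variance model
#'
#' Builds V = sum_x sigma_x^2 K_x + sigma_e^2 TT' from the null-model variance
#' components and returns y* = V^{-1/2} y plus a transformer for covariables,
#' so generalized least squares reduces to ordinary least squares on whitened
#' data. The components are held fixed for all marker tests (the
#' population-parameters-previously-determined scheme). If V is numerically
#' non-PD a ridge of 1e-8 is added (with a message).
#'
#' @param y MPH (or phenotype) vector
#' @param kernels a \code{kernel_set} (ignored for terms absent from
#'   \code{vc})
#' @param vc an \code{mk_fit} from the null model, or a named vector of
#'   variance components (names among d, aa, ad, dd, residual)
#' @param TTt residual structure (NULL for i.i.d. residuals)
#' @return object of class \code{whitener}: \code{y_star}, \code{W}
#'   (the V^{-1/2} matrix), and \code{transform(M)} applying W to covariables
#' @export
whiten <- function(y, kernels, vc, TTt = NULL) {
  s2 <- if (inherits(vc, "mk_fit")) vc$sigma2 else vc
  n <- length(y)
  V <- if (is.null(TTt)) diag(s2[["residual"]], n) else s2[["residual"]] * TTt
  for (m in intersect(names(s2), c("d", "aa", "ad", "dd"))) {
    if (s2[[m]] > 0) V <- V + s2[[m]] * kernels[[kernel_names[[m]]]]
  }
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    message("V not positive definite; ridge 1e-8 added")
    ev$values <- ev$values + 1e-8 * max(ev$values) - min(ev$values, 0)
  }
  W <- ev$vectors %*% (t(ev$vectors) / sqrt(ev$values))
  structure(list(y_star = as.vector(W %*% y), W = W,
                 transform = function(M) W %*% M),
            class = "whitener")
}

# vectorized 1-df F tests: for each column x of X, fit y ~ intercept + x on
# whitened data (w0 = whitened intercept) and test the slope
f_test_columns <- function(y_star, w0, X_star) {
  n <- length(y_star)
  # residualize against the whitened intercept
  w0n <- sum(w0^2)
  py <- y_star - w0 * (sum(w0 * y_star) / w0n)
  pX <- X_star - outer(w0, colSums(w0 * X_star) / w0n)
  xx <- colSums(pX^2)
  xy <- colSums(pX * py)
  ok <- xx > 1e-12
  beta <- ifelse(ok, xy / xx, NA_real_)
  rss0 <- sum(py^2)
  rss1 <- rss0 - ifelse(ok, xy^2 / xx, 0)
  df2 <- n - 2
  Fstat <- ifelse(ok, (rss0 - rss1) / (rss1 / df2), NA_real_)
  p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  data.frame(estimate = beta, Fstat = Fstat, p = p, skipped = !ok)
}

#' Genome-wide scan of dominance and digenic-epistatic component effects
#'
#' Step one of the three-step heterotic-effect scan: each marker's dominance
#' covariable v_i, and each pair's aa, dd (v_i v_j) and ad (v_i u_j, both
#' orientations) covariable, is tested by a 1-df F test in the whitened
#' regression with intercept. With \code{\link{mph_codings}} the aa covariable
#' is -m_i m_j (the derivative of MPH w.r.t. aa_ij), so the estimate is the
#' aa effect itself; with plain \code{\link{build_codings}} it is u_i u_j
#' (hybrid-phenotype analyses). Dominance effects are declared significant at
#' p < alpha / n and pairwise effects at p < alpha / [n(n-1)], the Bonferroni
#' thresholds (alpha = 0.001, with 0.05 as the conventional relaxation for
#' small panels). Constant covariables are skipped.
#'
#' @param wh a \code{whitener} from \code{\link{whiten}}
#' @param codings list with U and V (optionally M) from
#'   \code{\link{build_codings}} or \code{\link{mph_codings}}
#' @param alpha family-wise level before Bonferroni division
#' @param kinds subset of c("D", "AA", "AD", "DD") to test
#' @param keep "significant" (default) or "all" rows
#' @return data.frame of class \code{component_scan} with columns kind, i, j
#'   (NA for D; AD rows are ordered with the dominance covariable at i),
#'   estimate, Fstat, p, threshold, significant; attribute \code{n_markers}
#' @export
scan_components <- function(wh, codings, alpha = 0.001,
                            kinds = c("D", "AA", "AD", "DD"),
                            keep = c("significant", "all")) {
  keep <- match.arg(keep)
  kinds <- match.arg(kinds, c("D", "AA", "AD", "DD"), several.ok = TRUE)
  U <- codings$U; V <- codings$V
  m <- ncol(V)
  if (m < 2) stop("need >= 2 markers")
  w0 <- as.vector(wh$W %*% rep(1, nrow(V)))
  thr_d <- alpha / m
  thr_pair <- alpha / (m * (m - 1))
  out <- list()
  run_block <- function(X, kind, ii, jj, thr) {
    Xs <- wh$W %*% X
    res <- f_test_columns(wh$y_star, w0, Xs)
    res$kind <- kind; res$i <- ii; res$j <- jj; res$threshold <- thr
    res$significant <- !is.na(res$p) & res$p < thr
    res[!res$skipped & (keep == "all" | res$significant),
        c("kind", "i", "j", "estimate", "Fstat", "p", "threshold",
          "significant")]
  }
  if ("D" %in% kinds) {
    out$D <- run_block(V, "D", seq_len(m), NA_integer_, thr_d)
  }
  pair_idx <- utils::combn(m, 2)
  chunk <- 2000L
  run_pairs <- function(kind, M1, M2, ii, jj, thr) {
    res <- list()
    for (s in seq(1, length(ii), by = chunk)) {
      e <- min(s + chunk - 1, length(ii))
      X <- M1[, ii[s:e], drop = FALSE] * M2[, jj[s:e], drop = FALSE]
      res[[length(res) + 1]] <- run_block(X, kind, ii[s:e], jj[s:e], thr)
    }
    do.call(rbind, res)
  }
  if ("AA" %in% kinds) {
    if (!is.null(codings$M)) {
      out$AA <- run_pairs("AA", -codings$M, codings$M,
                          pair_idx[1, ], pair_idx[2, ], thr_pair)
    } else {
      out$AA <- run_pairs("AA", U, U, pair_idx[1, ], pair_idx[2, ], thr_pair)
    }
  }
  if ("DD" %in% kinds) {
    out$DD <- run_pairs("DD", V, V, pair_idx[1, ], pair_idx[2, ], thr_pair)
  }
  if ("AD" %in% kinds) {
    ii <- c(pair_idx[1, ], pair_idx[2, ])
    jj <- c(pair_idx[2, ], pair_idx[1, ])
    out$AD <- run_pairs("AD", V, U, ii, jj, thr_pair)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  rownames(res) <- NULL
  attr(res, "n_markers") <- m
  attr(res, "alpha") <- alpha
  class(res) <- c("component_scan", "data.frame")
  res
}

#' @export
print.component_scan <- function(x, ...) {
  cat("component_scan over", attr(x, "n_markers"), "markers (alpha =",
      attr(x, "alpha"), ")\n")
  print(table(factor(x$kind[x$significant], c("D", "AA", "AD", "DD"))))
  invisible(x)
}

#' Per-locus heterotic effects from component effects
#'
#' Step two: integrates (significant) dominance and epistatic component
#' effects into per-hybrid per-locus heterotic effects h_i. Loci are
#' classified per hybrid by the parental codes (k = female, l = male, both 0
#' or 2) into R_kl. A polymorphic locus (R20 or R02) receives its dominance
#' effect; every digenic effect contributes half to each member locus with
#' sign rules: aa pairs of like polymorphic classes enter negatively, unlike
#' classes positively; ad pairs (dominance covariable at the polymorphic
#' locus) enter positively when the additive locus is in R22 and negatively
#' when in R00; dd pairs between polymorphic loci enter positively. Summing
#' h_i over loci reproduces the hybrid's genetic MPH exactly when all true
#' effects are supplied.
#'
#' @param effects data.frame with columns kind ("D","AA","AD","DD"), i, j
#'   (locus indices; AD ordered dominance-at-i) and estimate; e.g. a
#'   \code{component_scan} (significant rows) or \code{\link{arch_to_effects}}
#'   output
#' @param parents \code{geno} object with homozygous parental genotypes at the
#'   scanned loci
#' @param plan a \code{cross_plan}
#' @param loci optional locus indices the effect table refers to (default: all
#'   loci of \code{parents})
#' @return hybrids x loci matrix of heterotic effects h
#' @export
heterotic_effects <- function(effects, parents, plan, loci = NULL) {
  if (is.null(loci)) loci <- seq_len(ncol(parents$codes))
  pf <- parents$codes[plan$female, loci, drop = FALSE]
  pm <- parents$codes[plan$male, loci, drop = FALSE]
  if (any(pf == 1L | pm == 1L, na.rm = TRUE)) {
    bad <- which(colSums(pf == 1L | pm == 1L, na.rm = TRUE) > 0)[1]
    stop("heterozygous parental call at scanned locus ", loci[bad])
  }
  nh <- nrow(plan); nl <- length(loci)
  h <- matrix(0, nh, nl, dimnames = list(plan$hybrid, colnames(parents$codes)[loci]))
  col_of <- match(seq_len(max(loci)), loci)   # locus index -> column
  r20 <- pf == 2L & pm == 0L
  r02 <- pf == 0L & pm == 2L
  r22 <- pf == 2L & pm == 2L
  r00 <- pf == 0L & pm == 0L
  poly <- r20 | r02
  sgn <- matrix(0, nh, nl)   # +1 in R20, -1 in R02
  sgn[r20] <- 1; sgn[r02] <- -1
  for (r in seq_len(nrow(effects))) {
    kind <- effects$kind[r]
    est <- effects$estimate[r]
    ci <- col_of[effects$i[r]]
    if (kind == "D") {
      h[, ci] <- h[, ci] + est * poly[, ci]
      next
    }
    cj <- col_of[effects$j[r]]
    if (kind == "AA") {
      # like polymorphic classes -> -1/2 each; unlike -> +1/2 each
      w <- -0.5 * est * sgn[, ci] * sgn[, cj]
      h[, ci] <- h[, ci] + w
      h[, cj] <- h[, cj] + w
    } else if (kind == "DD") {
      w <- 0.5 * est * poly[, ci] * poly[, cj]
      h[, ci] <- h[, ci] + w
      h[, cj] <- h[, cj] + w
    } else if (kind == "AD") {
      # dominance covariable at i (must be polymorphic); additive locus j
      # contributes +1 in R22, -1 in R00
      uj <- r22[, cj] - r00[, cj]
      w <- 0.5 * est * poly[, ci] * uj
      h[, ci] <- h[, ci] + w
      h[, cj] <- h[, cj] + w
    } else stop("unknown effect kind: ", kind)
  }
  h
}

#' All true architecture effects as a component-effect table
#'
#' Formats a simulated \code{trait_arch} as the effect table consumed by
#' \code{\link{heterotic_effects}}, treating every effect as significant;
#' used for the exact MPH-decomposition identity.
#'
#' @param arch a \code{trait_arch}
#' @return data.frame with columns kind, i, j, estimate
#' @export
arch_to_effects <- function(arch) {
  rows <- list(
    data.frame(kind = "D", i = arch$qtl, j = NA_integer_,
               estimate = arch$d, stringsAsFactors = FALSE))
  if (nrow(arch$aa)) rows$aa <- data.frame(kind = "AA", i = arch$aa$i,
                                           j = arch$aa$j,
                                           estimate = arch$aa$effect)
  if (nrow(arch$ad)) rows$ad <- data.frame(kind = "AD", i = arch$ad$i,
                                           j = arch$ad$j,
                                           estimate = arch$ad$effect)
  if (nrow(arch$dd)) rows$dd <- data.frame(kind = "DD", i = arch$dd$i,
                                           j = arch$dd$j,
                                           estimate = arch$dd$effect)
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[out$estimate != 0, , drop = FALSE]
}

#' Permutation test of the heterotic-effect MPH prediction
#'
#' Step three: each hybrid's MPH is predicted as the row sum of its heterotic
#' effects; the observed Pearson correlation with actual MPH is compared
#' against its permutation null (actual MPH permuted across hybrids). The
#' permutation p-value is (1 + #\{r_perm >= r_obs\}) / (n_perm + 1); when the
#' observed correlation exceeds every permutation, a normal approximation to
#' the permutation null is also reported for thresholds finer than the raw
#' resolution.
#'
#' @param h heterotic-effect matrix (hybrids x loci) or a prediction vector
#' @param mph actual MPH vector
#' @param n_perm number of permutations
#' @param seed random seed
#' @param absolute correlate absolute values instead of signed MPH
#' @return list: \code{r_obs}, \code{p_perm}, \code{p_normal}, \code{n_perm}
#' @export
permutation_test <- function(h, mph, n_perm = 10000, seed = 1,
                             absolute = FALSE) {
  pred <- if (is.matrix(h)) rowSums(h) else h
  n <- length(mph)
  stopifnot(length(pred) == n, n >= 10, n_perm >= 100)
  if (absolute) { pred <- abs(pred); mph_use <- abs(mph) } else mph_use <- mph
  if (stats::sd(pred) == 0) {
    return(list(r_obs = NA_real_, p_perm = 1, p_normal = 1, n_perm = n_perm))
  }
  set.seed(seed)
  r_obs <- stats::cor(pred, mph_use)
  pc <- pred - mean(pred)
  P <- matrix(mph_use[vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))],
              nrow = n)
  Pc <- P - matrix(colMeans(P), n, n_perm, byrow = TRUE)
  r_perm <- as.vector(crossprod(pc, Pc)) /
    (sqrt(sum(pc^2)) * sqrt(colSums(Pc^2)))
  p_perm <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  z <- (r_obs - mean(r_perm)) / stats::sd(r_perm)
  p_normal <- stats::pnorm(z, lower.tail = FALSE)
  list(r_obs = r_obs, p_perm = p_perm, p_normal = p_normal, n_perm = n_perm)
}

#' Variance of MPH explained by heterotic-effect loci
#'
#' Squared correlation between actual MPH and each locus's heterotic effect,
#' plus the joint R^2 of the summed prediction.
#'
#' @param h heterotic-effect matrix (hybrids x loci)
#' @param mph actual MPH vector
#' @param loci columns to report (default: loci with any nonzero effect)
#' @return list: \code{per_locus} (data.frame locus, r2) and \code{joint}
#' @export
explained_variance <- function(h, mph, loci = NULL) {
  if (is.null(loci)) loci <- which(colSums(h != 0) > 0)
  if (!length(loci)) stop("no locus with a nonzero heterotic effect")
  r2 <- vapply(loci, function(j) {
    if (stats::sd(h[, j]) == 0) return(0)
    stats::cor(h[, j], mph)^2
  }, 0)
  pred <- rowSums(h)
  joint <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, mph)^2
  list(per_locus = data.frame(locus = loci, r2 = r2), joint = joint)
}
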