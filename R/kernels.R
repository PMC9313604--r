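#' F-metric marker codings
#'
#' U = code - 1 (additive covariable, -1/0/1) and V = heterozygote indicator
#' (dominance covariable, 0/1). Columns are deliberately not centered: the
#' non-orthogonal F-metric parametrization is the one under which mid-parent
#' heterosis decomposes into per-locus heterotic effects. Missing codes are
#' mean-imputed per locus beforehand (with a message).
#'
#' @param g a \code{geno} object of hybrids (or any entries)
#' @param center center columns (off by default; exposed for sensitivity
#'   checks only)
#' @return list with matrices \code{U} and \code{V}
#' @export
build_codings <- function(g, center = FALSE) {
  codes <- g$codes
  if (anyNA(codes)) {
    message(sum(is.na(codes)), " missing genotype(s) mean-imputed per locus")
    mu <- colMeans(codes, na.rm = TRUE)
    idx <- which(is.na(codes), arr.ind = TRUE)
    codes[idx] <- mu[idx[, 2]]
  }
  U <- codes - 1
  V <- (g$codes == 1L) * 1
  if (anyNA(V)) {
    muv <- colMeans(V, na.rm = TRUE)
    idx <- which(is.na(V), arr.ind = TRUE)
    V[idx] <- muv[idx[, 2]]
  }
  if (center) {
    U <- scale(U, scale = FALSE)
    V <- scale(V, scale = FALSE)
  }
  list(U = U, V = V)
}

#' MPH-scale marker codings from parents and crossing plan
#'
#' For analyses of mid-parent heterosis the relevant covariables per hybrid
#' are U (hybrid additive, code - 1), V (polymorphism/heterozygosity
#' indicator) and M = (female - male)/2, the signed polymorphism indicator
#' that classifies each locus into the parental classes R_kl. M drives the
#' additive-by-additive component of MPH (its derivative w.r.t. aa_ij is
#' -m_i m_j), which the hybrid's own additive coding cannot see: u = 0 at
#' every polymorphic locus. Products m_i m_j are invariant to swapping the
#' parents of a cross. Missing or heterozygous parental calls propagate to NA
#' and are mean-imputed with a message.
#'
#' @param parents \code{geno} object with homozygous parental genotypes
#' @param plan a \code{cross_plan}
#' @return list with hybrid x locus matrices \code{U}, \code{V}, \code{M}
#' @export
mph_codings <- function(parents, plan) {
  pf <- parents$codes[plan$female, , drop = FALSE]
  pm <- parents$codes[plan$male, , drop = FALSE]
  bad <- is.na(pf) | is.na(pm) | pf == 1L | pm == 1L
  U <- (pf + pm) / 2 - 1
  V <- (pf != pm) * 1
  M <- (pf - pm) / 2
  U[bad] <- NA; V[bad] <- NA; M[bad] <- NA
  imp <- function(X) {
    if (!anyNA(X)) return(X)
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
    X
  }
  if (any(bad)) message(sum(bad), " unusable parental call(s) mean-imputed")
  rn <- plan$hybrid
  out <- lapply(list(U = U, V = V, M = M), function(X) {
    rownames(X) <- rn
    imp(X)
  })
  out
}

norm_kernel <- function(K, label) {
  c0 <- mean(diag(K))
  if (c0 <= 0) stop("kernel ", label, " is identically zero (no heterozygosity?)")
  list(K = K / c0, c = c0)
}

#' Kinship kernels for dominance and digenic epistasis
#'
#' K_d = V V'. The epistatic kernels are the exact pairwise-coding kinships,
#' computed via Hadamard products with the within-locus self-pairs removed:
#' K_aa = [(A A') o (A A') - (A o A)(A o A)'] / 2 over pairs i < j of additive
#' covariables, K_dd analogously from V, and K_ad = (V V') o (U U') -
#' (V o U)(V o U)' over ordered pairs. Each kernel is divided by its mean
#' diagonal so variance components sit on comparable scales. Keeping the
#' self-pairs (\code{exact_pairs = FALSE}) folds a dominance-kernel-like term
#' into K_aa and K_dd and biases the variance split toward the dominance
#' component. For codings from \code{\link{build_codings}} the additive
#' coding A entering K_aa is U itself (hybrid-phenotype analyses); for
#' \code{\link{mph_codings}} it is the signed polymorphism indicator M, the
#' coding that carries the aa component of MPH.
#'
#' With \code{center = TRUE} (the default) each kernel is additionally
#' double-centered (K <- HKH, H = I - 11'/n), which is exactly equivalent to
#' centering every product covariable across entries. The covariables
#' themselves stay on the raw F-metric scale — centering the codings before
#' taking products would discard the main-effect-aligned content that real
#' epistatic covariables carry — but the entry-mean direction, which the
#' model's intercept absorbs anyway, is removed. Uncentered kernels share a
#' large common mean mass that makes the four components nearly
#' unidentifiable in a variance partition.
#'
#' @param codings list with U and V (and optionally M) from
#'   \code{\link{build_codings}} or \code{\link{mph_codings}}
#' @param exact_pairs remove within-locus self-pairs (default TRUE)
#' @param center double-center each kernel (default TRUE)
#' @return object of class \code{kernel_set}: matrices \code{K_d},
#'   \code{K_aa}, \code{K_ad}, \code{K_dd} and the normalization constants
#'   \code{consts}
#' @export
build_kinships <- function(codings, exact_pairs = TRUE, center = TRUE) {
  U <- codings$U; V <- codings$V
  Ma <- if (!is.null(codings$M)) codings$M else U
  A <- tcrossprod(U)
  Aa <- tcrossprod(Ma)
  D <- tcrossprod(V)
  Kaa <- Aa * Aa
  Kad <- A * D
  Kdd <- D * D
  if (exact_pairs) {
    Kaa <- (Kaa - tcrossprod(Ma * Ma)) / 2
    Kad <- Kad - tcrossprod(V * U)
    Kdd <- (Kdd - tcrossprod(V * V)) / 2
  }
  Kd <- D
  if (center) {
    dc <- function(K) {
      rm <- rowMeans(K)
      K <- K - outer(rm, rep(1, ncol(K))) - outer(rep(1, nrow(K)), rm) +
        mean(K)
      (K + t(K)) / 2
    }
    Kd <- dc(Kd); Kaa <- dc(Kaa); Kad <- dc(Kad); Kdd <- dc(Kdd)
  }
  kd <- norm_kernel(Kd, "K_d")
  kaa <- norm_kernel(Kaa, "K_aa")
  kad <- norm_kernel(Kad, "K_ad")
  kdd <- norm_kernel(Kdd, "K_dd")
  structure(list(K_d = kd$K, K_aa = kaa$K, K_ad = kad$K, K_dd = kdd$K,
                 consts = c(d = kd$c, aa = kaa$c, ad = kad$c, dd = kdd$c)),
            class = "kernel_set")
}

#' @export
print.kernel_set <- function(x, ...) {
  cat("kernel_set:", nrow(x$K_d), "entries; normalization constants:\n")
  print(round(x$consts, 3))
  invisible(x)
}

#' MPH transformation matrix T
#'
#' Maps the stacked (hybrid, parent) trait vector to the mid-parent-heterosis
#' vector: each row has +1 at its hybrid and -1/2 at each parent, so
#' y_MPH = T y and the MPH residual covariance is T T' sigma_e^2.
#'
#' @param plan a \code{cross_plan}
#' @param entry_order character vector: the order of entries (hybrids and
#'   parents) in the trait vector
#' @return list: \code{T} (r x (r+s)) and \code{TTt} (r x r)
#' @export
build_T <- function(plan, entry_order) {
  miss <- setdiff(c(plan$hybrid, plan$female, plan$male), entry_order)
  if (length(miss)) stop("entries missing from entry_order: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  r <- nrow(plan)
  Tm <- matrix(0, r, length(entry_order),
               dimnames = list(plan$hybrid, entry_order))
  for (k in seq_len(r)) {
    Tm[k, plan$hybrid[k]] <- 1
    Tm[k, plan$female[k]] <- Tm[k, plan$female[k]] - 0.5
    Tm[k, plan$male[k]] <- Tm[k, plan$male[k]] - 0.5
  }
  list(T = Tm, TTt = tcrossprod(Tm))
}
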