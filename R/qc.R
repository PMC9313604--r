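#' Filter loci on minor allele frequency and missingness
#'
#' Retains loci with MAF strictly greater than \code{maf_min} and missing-call
#' fraction strictly below \code{miss_max}; MAF is computed on non-missing
#' calls. Defaults reproduce the conventional MAF > 5\%, missing < 5\% chip-QC
#' rule.
#'
#' @param g a \code{geno} object
#' @param maf_min minimum MAF (exclusive), in [0, 0.5)
#' @param miss_max maximum missing fraction (exclusive)
#' @return a filtered \code{geno} object
#' @export
filter_maf_missing <- function(g, maf_min = 0.05, miss_max = 0.05) {
  stopifnot(maf_min >= 0, maf_min < 0.5)
  f <- locus_maf(g)
  f <- pmin(f, 1 - f)           # robust to unoriented input
  miss <- colMeans(is.na(g$codes))
  keep <- which(!is.na(f) & f > maf_min & miss < miss_max)
  if (!length(keep)) {
    stop(sprintf("all %d loci removed (maf>%g kept %d, miss<%g kept %d)",
                 ncol(g$codes), maf_min, sum(!is.na(f) & f > maf_min),
                 miss_max, sum(miss < miss_max)))
  }
  geno_subset(g, loci = keep)
}

# squared allele-count correlation between locus columns, pairwise-complete
locus_r2 <- function(codes) {
  suppressWarnings(stats::cor(codes, use = "pairwise.complete.obs"))^2
}

#' LD pruning by sliding-window pairwise r-squared
#'
#' Within each sliding window of \code{window_snps} position-sorted loci, any
#' pair with r-squared above \code{r2_max} loses its lower-MAF member (ties
#' remove the later-positioned locus). The returned locus set has no
#' within-window pair above the threshold. r-squared is the squared allele
#' count correlation, computed pairwise-complete.
#'
#' @param g a \code{geno} object (positions sorted within chromosome)
#' @param window_snps window width in SNPs
#' @param r2_max maximum tolerated r-squared
#' @param step window step in SNPs
#' @return a pruned \code{geno} object
#' @export
ld_prune <- function(g, window_snps = 50, r2_max = 0.5, step = 1) {
  keep <- rep(TRUE, ncol(g$codes))
  maf <- locus_maf(g)
  maf <- pmin(maf, 1 - maf)
  for (ch in unique(g$loci$chrom)) {
    idx <- which(g$loci$chrom == ch)
    start <- 1
    while (start <= length(idx)) {
      win <- idx[seq(start, min(start + window_snps - 1, length(idx)))]
      act <- win[keep[win]]
      if (length(act) > 1) {
        r2 <- locus_r2(g$codes[, act, drop = FALSE])
        repeat {
          r2u <- r2
          r2u[lower.tri(r2u, diag = TRUE)] <- NA
          off <- which(r2u > r2_max, arr.ind = TRUE)
          if (!nrow(off)) break
          # worst offending pair first
          w <- off[which.max(r2u[off]), ]
          i <- act[w[1]]; j <- act[w[2]]
          drop_loc <- if (isTRUE(maf[i] < maf[j])) w[1]
                      else if (isTRUE(maf[j] < maf[i])) w[2]
                      else w[2]  # tie: later position removed
          keep[act[drop_loc]] <- FALSE
          r2 <- r2[-drop_loc, -drop_loc, drop = FALSE]
          act <- act[-drop_loc]
          if (length(act) < 2) break
        }
      }
      start <- start + step
    }
  }
  if (!any(keep)) warning("LD pruning removed every locus")
  geno_subset(g, loci = which(keep))
}

#' Deduce hybrid genotypes from inbred parents
#'
#' Each hybrid's code is the parental mean: 2 x 2 -> 2, 0 x 0 -> 0,
#' 2 x 0 -> 1. A missing or residually heterozygous parental call makes the
#' hybrid call missing at that locus (phase is never guessed).
#'
#' @param parents \code{geno} object of parental lines
#' @param plan a \code{cross_plan}
#' @return \code{geno} object with one row per hybrid, same loci as
#'   \code{parents}
#' @export
derive_hybrid_genotypes <- function(parents, plan) {
  ids <- rownames(parents$codes)
  miss_par <- setdiff(unique(c(plan$female, plan$male)), ids)
  if (length(miss_par)) stop("unknown parent id(s): ", paste(miss_par, collapse = ", "))
  pf <- parents$codes[plan$female, , drop = FALSE]
  pm <- parents$codes[plan$male, , drop = FALSE]
  bad <- is.na(pf) | is.na(pm) | pf == 1L | pm == 1L
  h <- (pf + pm) %/% 2L
  h[bad] <- NA_integer_
  n_het <- sum((pf == 1L | pm == 1L), na.rm = TRUE)
  if (n_het > 0) {
    message(n_het, " heterozygous parental call(s) propagated to missing")
  }
  rownames(h) <- plan$hybrid
  geno_matrix(h, parents$loci)
}
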