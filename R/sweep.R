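#' Per-locus Weir-Cockerham Fst variance components
#'
#' Returns the a (among-population), b (among-individual) and c
#' (within-individual) components of the Weir-Cockerham theta estimator for
#' each locus, for two groups of diploid samples. The per-locus estimate is
#' a/(a+b+c); windowed estimates use the ratio of sums.
#'
#' @param g a \code{geno} object
#' @param group1,group2 sample ids or indices of the two groups (disjoint)
#' @return data.frame with columns a, b, c, one row per locus
#' @export
wc_fst_components <- function(g, group1, group2) {
  idx <- function(s) if (is.character(s)) match(s, rownames(g$codes)) else s
  i1 <- idx(group1); i2 <- idx(group2)
  if (anyNA(i1) || anyNA(i2)) stop("unknown sample id(s)")
  if (length(intersect(i1, i2))) stop("groups overlap")
  if (length(i1) < 2 || length(i2) < 2) stop("both groups need >= 2 samples")
  stats_grp <- function(ii) {
    cc <- g$codes[ii, , drop = FALSE]
    n <- colSums(!is.na(cc))                     # individuals genotyped
    p <- colSums(cc, na.rm = TRUE) / (2 * n)     # alt allele frequency
    h <- colMeans(cc == 1L, na.rm = TRUE)        # observed het frequency
    list(n = n, p = p, h = h)
  }
  s1 <- stats_grp(i1); s2 <- stats_grp(i2)
  r <- 2
  n_tot <- s1$n + s2$n
  nbar <- n_tot / r
  nc <- (n_tot - (s1$n^2 + s2$n^2) / n_tot) / (r - 1)
  pbar <- (s1$n * s1$p + s2$n * s2$p) / n_tot
  s2v <- (s1$n * (s1$p - pbar)^2 + s2$n * (s2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (s1$n * s1$h + s2$n * s2$h) / n_tot
  a <- nbar / nc * (s2v - (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2v - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  out <- data.frame(a = a, b = b, c = cc)
  # loci with no data in a group are undefined
  und <- s1$n == 0 | s2$n == 0 | nbar <= 1
  out[und, ] <- NA_real_
  out
}

# sliding half-open windows [start, start + window_bp) per chromosome,
# starts at 1, 1 + step_bp, ...
make_windows <- function(loci, window_bp, step_bp) {
  out <- list()
  for (ch in unique(loci$chrom)) {
    mx <- max(loci$pos[loci$chrom == ch])
    starts <- seq(1, max(1, mx), by = step_bp)
    starts <- starts[starts <= mx]
    out[[ch]] <- data.frame(chrom = ch, start = starts,
                            end = starts + window_bp, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Windowed Weir-Cockerham Fst between two groups
#'
#' Per-locus Weir-Cockerham components are combined per sliding window by the
#' ratio of sums (sum a / sum(a+b+c)), the VCFtools-style windowed estimator.
#' Windows are half-open [start, end) with 1-based starts at 1, 1+step, ...;
#' windows holding fewer than \code{min_loci} usable loci are flagged
#' (\code{fst = NA}).
#'
#' @param g a \code{geno} object
#' @param group1,group2 sample ids or indices (disjoint, >= 2 each)
#' @param window_bp,step_bp window span and step in bp (defaults 1 Mb / 100 kb)
#' @param min_loci minimum usable loci per window
#' @return data.frame of class \code{sweep_scan}: chrom, start, end, n_loci,
#'   fst
#' @export
windowed_fst <- function(g, group1, group2, window_bp = 1e6, step_bp = 1e5,
                         min_loci = 3) {
  comp <- wc_fst_components(g, group1, group2)
  win <- make_windows(g$loci, window_bp, step_bp)
  win$n_loci <- NA_integer_
  win$fst <- NA_real_
  for (r in seq_len(nrow(win))) {
    sel <- g$loci$chrom == win$chrom[r] &
      g$loci$pos >= win$start[r] & g$loci$pos < win$end[r] & !is.na(comp$a)
    win$n_loci[r] <- sum(sel)
    if (win$n_loci[r] >= min_loci) {
      denom <- sum(comp$a[sel] + comp$b[sel] + comp$c[sel])
      if (abs(denom) > 1e-300) win$fst[r] <- sum(comp$a[sel]) / denom
    }
  }
  class(win) <- c("sweep_scan", "data.frame")
  win
}

# per-locus nucleotide diversity within one group:
# pi = 2 p (1-p) n/(n-1), n = non-missing allele count
locus_pi <- function(codes) {
  n <- 2 * colSums(!is.na(codes))
  p <- colSums(codes, na.rm = TRUE) / n
  pi <- 2 * p * (1 - p) * n / (n - 1)
  pi[n < 2] <- NA_real_
  pi
}

#' Windowed diversity ratio and selective-sweep call
#'
#' Per-window nucleotide diversity pi is the mean of per-locus
#' 2p(1-p)n/(n-1) within each group; pi_ratio = pi_group1 / pi_group2
#' (undefined where the denominator is 0). Sweep windows are those exceeding
#' both the empirical top-5\% Fst cutoff and the top-5\% pi-ratio cutoff.
#'
#' @inheritParams windowed_fst
#' @param top_frac upper tail fraction defining both cutoffs
#' @return data.frame of class \code{sweep_scan}: chrom, start, end, n_loci,
#'   fst, pi1, pi2, pi_ratio, sweep (logical), plus attributes
#'   \code{fst_cutoff} and \code{ratio_cutoff}
#' @export
windowed_pi_ratio <- function(g, group1, group2, window_bp = 1e6,
                              step_bp = 1e5, min_loci = 3, top_frac = 0.05) {
  scan <- windowed_fst(g, group1, group2, window_bp, step_bp, min_loci)
  idx <- function(s) if (is.character(s)) match(s, rownames(g$codes)) else s
  pi1 <- locus_pi(g$codes[idx(group1), , drop = FALSE])
  pi2 <- locus_pi(g$codes[idx(group2), , drop = FALSE])
  scan$pi1 <- NA_real_; scan$pi2 <- NA_real_
  for (r in seq_len(nrow(scan))) {
    sel <- g$loci$chrom == scan$chrom[r] &
      g$loci$pos >= scan$start[r] & g$loci$pos < scan$end[r]
    if (sum(sel) >= min_loci) {
      scan$pi1[r] <- mean(pi1[sel], na.rm = TRUE)
      scan$pi2[r] <- mean(pi2[sel], na.rm = TRUE)
    }
  }
  scan$pi_ratio <- ifelse(!is.na(scan$pi2) & scan$pi2 > 0,
                          scan$pi1 / scan$pi2, NA_real_)
  fst_cut <- stats::quantile(scan$fst, 1 - top_frac, na.rm = TRUE, names = FALSE)
  ratio_cut <- stats::quantile(scan$pi_ratio, 1 - top_frac, na.rm = TRUE,
                               names = FALSE)
  scan$sweep <- !is.na(scan$fst) & !is.na(scan$pi_ratio) &
    scan$fst > fst_cut & scan$pi_ratio > ratio_cut
  attr(scan, "fst_cutoff") <- fst_cut
  attr(scan, "ratio_cutoff") <- ratio_cut
  scan
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat("sweep_scan:", nrow(x), "windows;",
      sum(!is.na(x$fst)), "with Fst; mean Fst",
      round(mean(x$fst, na.rm = TRUE), 4), "\n")
  if (!is.null(x$sweep)) cat("sweep windows:", sum(x$sweep, na.rm = TRUE), "\n")
  invisible(x)
}
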