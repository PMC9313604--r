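#' Rogers' distance between two genotype vectors
#'
#' RD = (1/L) * sum_u sqrt( (1/2) * sum_j (X_uj - Y_uj)^2 ) over loci
#' non-missing in both individuals, where X_uj is the within-individual
#' frequency of allele j at locus u (0, 1/2 or 1 for a diploid biallelic
#' locus). Opposite homozygotes contribute 1 per locus, a heterozygote against
#' a homozygote contributes 1/2.
#'
#' @param x,y genotype code vectors (0/1/2/NA) over the same loci
#' @return Rogers' distance in [0, 1]
#' @export
rogers_distance <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no locus non-missing in both individuals")
  mean(abs(x[ok] - y[ok]) / 2)
}

# per-locus Rogers terms sqrt(0.5 * sum_j (X_uj - Y_uj)^2) = |x - y| / 2
rogers_terms <- function(x, y) abs(x - y) / 2

#' Heterotic genetic distance (dominance-weighted Rogers' distance)
#'
#' The per-locus Rogers terms are weighted by \code{w}, typically the absolute
#' value of predicted SNP dominance effects. Weights are rescaled to sum to the
#' number of loci used, so uniform weights reduce the measure to plain Rogers'
#' distance.
#'
#' @param x,y genotype code vectors (0/1/2/NA)
#' @param w non-negative per-locus weights (e.g.
#'   \code{abs(predict_dominance_effects(...)$effect)})
#' @return weighted distance >= 0
#' @export
heterotic_distance <- function(x, y, w) {
  stopifnot(length(x) == length(y), length(w) == length(x))
  if (any(w < 0, na.rm = TRUE)) stop("weights must be non-negative")
  ok <- !is.na(x) & !is.na(y) & !is.na(w)
  if (!any(ok)) stop("no usable locus")
  L <- sum(ok)
  sw <- sum(w[ok])
  if (sw <= 0) stop("all weights zero")
  wr <- w[ok] * L / sw
  mean(wr * rogers_terms(x[ok], y[ok]))
}

#' Pairwise parental distances for a crossing plan
#'
#' Computes Rogers' distance and, when weights are given, the heterotic
#' genetic distance between the two parents of every hybrid in the plan.
#'
#' @param parents \code{geno} object
#' @param plan a \code{cross_plan}
#' @param w optional per-locus dominance weights
#' @return data.frame (hybrid, female, male, rd, and ird when \code{w} given,
#'   L = shared locus count)
#' @export
plan_distances <- function(parents, plan, w = NULL) {
  out <- data.frame(hybrid = plan$hybrid, female = plan$female,
                    male = plan$male, rd = NA_real_, L = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!is.null(w)) out$ird <- NA_real_
  for (r in seq_len(nrow(plan))) {
    x <- parents$codes[plan$female[r], ]
    y <- parents$codes[plan$male[r], ]
    out$rd[r] <- rogers_distance(x, y)
    out$L[r] <- sum(!is.na(x) & !is.na(y))
    if (!is.null(w)) out$ird[r] <- heterotic_distance(x, y, w)
  }
  out
}
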