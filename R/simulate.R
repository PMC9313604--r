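#' Simulation configuration
#'
#' Parameters of the synthetic multi-hybrid population: two diverged parental
#' pools of fully inbred lines, a crossing design (Griffing-IV diallel and/or
#' NC II factorial), a biallelic QTL architecture with additive, dominance and
#' digenic epistatic (aa/ad/dd) effects, and plot-level phenotypes with
#' environment / replicate / incomplete-block structure.
#'
#' @param n_pool1,n_pool2 number of parents in each pool
#' @param n_loci total SNP count
#' @param fst_target divergence between the pools in [0, 0.9] (Balding-Nichols)
#' @param n_chrom number of chromosomes
#' @param design "diallel", "NCII" or "both"
#' @param n_qtl number of QTL
#' @param prop_var length-5 numeric (f_a, f_d, f_aa, f_ad, f_dd): target
#'   fractions of genetic variance by effect class; must sum to 1
#' @param h2_plot plot-level heritability in (0, 1]
#' @param n_env,n_rep,n_block environments, replicates per environment,
#'   incomplete blocks per replicate
#' @param spacing_bp distance between adjacent loci on a chromosome
#' @param seed random seed
#' @return an object of class \code{sim_config} (a validated list)
#' @export
sim_config <- function(n_pool1 = 28, n_pool2 = 23, n_loci = 1000,
                       fst_target = 0.3, n_chrom = 10,
                       design = c("NCII", "diallel", "both"),
                       n_qtl = 20,
                       prop_var = c(f_a = 0.4, f_d = 0.3, f_aa = 0.1,
                                    f_ad = 0.1, f_dd = 0.1),
                       h2_plot = 0.7, n_env = 2, n_rep = 2, n_block = 2,
                       spacing_bp = 2e5, seed = 1L) {
  design <- match.arg(design)
  prop_var <- unname(prop_var)
  stopifnot(length(prop_var) == 5, all(prop_var >= 0))
  if (abs(sum(prop_var) - 1) > 1e-9) stop("prop_var must sum to 1")
  counts <- c(n_pool1, n_pool2, n_loci, n_chrom, n_qtl, n_env, n_rep, n_block)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (fst_target < 0 || fst_target > 0.9) stop("fst_target must be in [0, 0.9]")
  if (h2_plot <= 0 || h2_plot > 1) stop("h2_plot must be in (0, 1]")
  structure(list(n_pool1 = n_pool1, n_pool2 = n_pool2, n_loci = n_loci,
                 fst_target = fst_target, n_chrom = n_chrom, design = design,
                 n_qtl = n_qtl,
                 prop_var = stats::setNames(prop_var,
                                            c("f_a", "f_d", "f_aa", "f_ad", "f_dd")),
                 h2_plot = h2_plot, n_env = n_env, n_rep = n_rep,
                 n_block = n_block, spacing_bp = spacing_bp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_pool1, "+", x$n_pool2, "parents,", x$n_loci, "loci,",
      "Fst", x$fst_target, ", design", x$design, "\n")
  invisible(x)
}

# deterministic sub-seed so each stage is individually reproducible
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.integer(seed) * 1009L + as.integer(h %% 104729)) %% 2147483587L
}

#' Simulate two diverged pools of fully inbred parents
#'
#' Ancestral allele frequencies are Uniform(0.1, 0.9); each pool's frequency is
#' drawn from the Balding-Nichols beta distribution at divergence
#' \code{fst_target} (at 0 both pools share the ancestral frequency). Parents
#' are fully inbred: a single allele is drawn per line and doubled, so codes
#' are 0 or 2 only. Loci are split evenly across chromosomes with uniformly
#' spaced positions. Monomorphic loci can occur and are kept.
#'
#' @param config a \code{\link{sim_config}}
#' @return a \code{geno} object with pool labels "pool1"/"pool2"
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, "parents"))
  L <- config$n_loci
  p_anc <- stats::runif(L, 0.1, 0.9)
  Fst <- config$fst_target
  draw_pool <- function() {
    if (Fst <= 0) return(p_anc)
    shp <- (1 - Fst) / Fst
    stats::rbeta(L, p_anc * shp, (1 - p_anc) * shp)
  }
  p1 <- draw_pool()
  p2 <- draw_pool()
  n1 <- config$n_pool1; n2 <- config$n_pool2
  codes1 <- matrix(2L * stats::rbinom(n1 * L, 1, rep(p1, each = n1)), nrow = n1)
  codes2 <- matrix(2L * stats::rbinom(n2 * L, 1, rep(p2, each = n2)), nrow = n2)
  codes <- rbind(codes1, codes2)
  rownames(codes) <- c(sprintf("P1_%02d", seq_len(n1)),
                       sprintf("P2_%02d", seq_len(n2)))
  if (all(apply(codes, 2, function(z) length(unique(z)) == 1L))) {
    stop("degenerate simulation: all parents identical at every locus")
  }
  per <- diff(round(seq(0, L, length.out = config$n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(config$n_chrom)), per)
  pos <- unlist(lapply(per, function(k) seq_len(k) * config$spacing_bp))
  loci <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                     stringsAsFactors = FALSE)
  geno_matrix(codes, loci,
              pool = rep(c("pool1", "pool2"), c(n1, n2)))
}

#' Build a crossing plan
#'
#' A Griffing-IV diallel takes all p(p-1)/2 pairwise crosses among the parents
#' (no selfs, no reciprocals); an NC II design crosses every pool-1 parent
#' (female side) with every pool-2 parent.
#'
#' @param parents a \code{geno} object of parental lines
#' @param scheme "diallel" or "NCII"
#' @return a data.frame of class \code{cross_plan} with columns
#'   \code{female}, \code{male}, \code{hybrid}, \code{design}
#' @export
make_crossing_design <- function(parents, scheme = c("diallel", "NCII")) {
  scheme <- match.arg(scheme)
  ids <- rownames(parents$codes)
  if (length(ids) < 2) stop("need at least 2 parents")
  if (scheme == "diallel") {
    idx <- utils::combn(length(ids), 2)
    plan <- data.frame(female = ids[idx[1, ]], male = ids[idx[2, ]],
                       stringsAsFactors = FALSE)
  } else {
    if (is.null(parents$pool)) stop("NCII requires pool labels")
    f <- ids[parents$pool == "pool1"]
    m <- ids[parents$pool == "pool2"]
    if (!length(f) || !length(m)) stop("NCII requires both pools non-empty")
    plan <- expand.grid(male = m, female = f, stringsAsFactors = FALSE)[, 2:1]
  }
  plan$hybrid <- paste(plan$female, plan$male, sep = "x")
  plan$design <- scheme
  rownames(plan) <- NULL
  class(plan) <- c("cross_plan", "data.frame")
  plan
}

#' @export
print.cross_plan <- function(x, ...) {
  cat("cross_plan:", nrow(x), "crosses (", unique(x$design), ")\n")
  print.data.frame(utils::head(x, 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Simulate a trait architecture with digenic epistasis
#'
#' Draws \code{n_qtl} QTL with additive (a) and dominance (d) effects plus
#' additive-by-additive (aa), additive-by-dominance (ad) and
#' dominance-by-dominance (dd) pairwise effects among them, then rescales each
#' effect class so the realized variance fractions on the supplied population
#' match \code{config$prop_var}. Calibration is empirical (on the realized
#' genotypes) because epistatic variance depends on realized genotype
#' frequencies.
#'
#' @param config a \code{\link{sim_config}}
#' @param geno \code{geno} object holding the calibration population (parents
#'   plus hybrids, or hybrids)
#' @param plan optional \code{cross_plan}; required for \code{scale = "mph"}
#' @param scale calibrate variance fractions on entry genotypic values
#'   ("genotypic") or on mid-parent heterosis over the plan's hybrids ("mph").
#'   With "mph" the additive fraction must be 0 (additive effects cancel in
#'   MPH).
#' @param n_pairs number of epistatic pairs per class (default \code{n_qtl})
#' @param total_var target total genetic variance (trait units squared)
#' @return an object of class \code{trait_arch}: fields \code{qtl} (locus
#'   indices), \code{a}, \code{d}, and data.frames \code{aa}, \code{ad},
#'   \code{dd} with columns i, j, effect (ad rows are ordered: dominance
#'   covariable at i, additive at j), and intercept \code{mu}
#' @export
simulate_architecture <- function(config, geno, plan = NULL,
                                  scale = c("genotypic", "mph"),
                                  n_pairs = NULL, total_var = 100) {
  stopifnot(inherits(config, "sim_config"))
  scale <- match.arg(scale)
  set.seed(sub_seed(config$seed, "architecture"))
  L <- ncol(geno$codes)
  q <- config$n_qtl
  if (q > L) stop("n_qtl exceeds locus count")
  if (is.null(n_pairs)) n_pairs <- q
  qtl <- sort(sample.int(L, q))
  pv <- config$prop_var
  rand_pairs <- function(n, ordered = FALSE) {
    if (q < 2 || n == 0) {
      return(data.frame(i = integer(), j = integer(), effect = numeric()))
    }
    all_p <- utils::combn(qtl, 2)
    if (ordered) all_p <- cbind(all_p, all_p[2:1, , drop = FALSE])
    k <- min(n, ncol(all_p))
    sel <- all_p[, sample.int(ncol(all_p), k), drop = FALSE]
    data.frame(i = sel[1, ], j = sel[2, ], effect = stats::rnorm(k))
  }
  arch <- structure(list(qtl = qtl,
                         a = stats::rnorm(q), d = stats::rnorm(q),
                         aa = rand_pairs(n_pairs),
                         ad = rand_pairs(n_pairs, ordered = TRUE),
                         dd = rand_pairs(n_pairs),
                         mu = 0),
                    class = "trait_arch")
  if (pv[["f_a"]] == 0) arch$a[] <- 0
  if (pv[["f_d"]] == 0) arch$d[] <- 0
  if (pv[["f_aa"]] == 0) arch$aa$effect[] <- 0
  if (pv[["f_ad"]] == 0) arch$ad$effect[] <- 0
  if (pv[["f_dd"]] == 0) arch$dd$effect[] <- 0

  if (scale == "mph") {
    if (pv[["f_a"]] > 0) stop("additive effects cancel in MPH; f_a must be 0 for scale='mph'")
    if (is.null(plan)) stop("scale='mph' requires a cross plan")
    comp <- mph_components(geno, plan, arch)
  } else {
    codes <- geno$codes
    if (!is.null(plan) && !all(plan$hybrid %in% rownames(codes))) {
      hyb <- (codes[plan$female, , drop = FALSE] +
                codes[plan$male, , drop = FALSE]) / 2L
      rownames(hyb) <- plan$hybrid
      codes <- rbind(codes, hyb)   # calibrate on parents plus hybrids
    }
    comp <- genotypic_components(codes, arch)
  }
  targ <- c(a = pv[["f_a"]], d = pv[["f_d"]], aa = pv[["f_aa"]],
            ad = pv[["f_ad"]], dd = pv[["f_dd"]]) * total_var
  for (cls in names(targ)) {
    v <- stats::var(comp[[cls]])
    if (targ[[cls]] > 0) {
      if (v < 1e-12) {
        warning("no realized variance for class ", cls, "; effects left as drawn")
        next
      }
      s <- sqrt(targ[[cls]] / v)
    } else {
      s <- 0
    }
    if (cls %in% c("a", "d")) {
      arch[[cls]] <- arch[[cls]] * s
    } else {
      arch[[cls]]$effect <- arch[[cls]]$effect * s
    }
  }
  arch
}

#' @export
print.trait_arch <- function(x, ...) {
  cat("trait_arch:", length(x$qtl), "QTL;",
      nrow(x$aa), "aa,", nrow(x$ad), "ad,", nrow(x$dd), "dd pairs\n")
  invisible(x)
}

# per-entry genetic value split by effect class (F-metric codings
# u = code - 1 in {-1,0,1}, v = heterozygote indicator)
genotypic_components <- function(codes, arch) {
  codes_q <- codes[, arch$qtl, drop = FALSE]
  if (anyNA(codes_q)) stop("missing genotype at a QTL locus")
  U <- codes_q - 1
  V <- (codes_q == 1) * 1
  colnames(U) <- colnames(V) <- as.character(arch$qtl)
  qpos <- stats::setNames(seq_along(arch$qtl), as.character(arch$qtl))
  pair_sum <- function(df, M1, M2) {
    out <- numeric(nrow(codes_q))
    if (!nrow(df)) return(out)
    ii <- qpos[as.character(df$i)]
    jj <- qpos[as.character(df$j)]
    chunk <- 10000L
    for (s in seq(1, nrow(df), by = chunk)) {
      e <- min(s + chunk - 1, nrow(df))
      out <- out + as.vector((M1[, ii[s:e], drop = FALSE] *
                                M2[, jj[s:e], drop = FALSE]) %*% df$effect[s:e])
    }
    out
  }
  list(a = as.vector(U %*% arch$a),
       d = as.vector(V %*% arch$d),
       aa = pair_sum(arch$aa, U, U),
       ad = pair_sum(arch$ad, V, U),   # dominance covariable at i
       dd = pair_sum(arch$dd, V, V))
}

#' Genotypic value under the F-metric digenic model
#'
#' value = mu + sum_i a_i u_i + sum_i d_i v_i + sum_{i<j} aa_ij u_i u_j +
#' sum_{(i,j)} ad_ij v_i u_j + sum_{i<j} dd_ij v_i v_j, with u = code - 1 and
#' v the heterozygote indicator. This is the parametrization under which a
#' hybrid's mid-parent heterosis decomposes exactly into per-locus heterotic
#' effects.
#'
#' @param codes genotype codes: a vector (one entry) or entries x loci matrix
#'   covering all \code{arch$qtl} columns
#' @param arch a \code{trait_arch}
#' @return numeric vector of genotypic values, one per entry
#' @export
genotypic_value <- function(codes, arch) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1)
  comp <- genotypic_components(codes, arch)
  arch$mu + comp$a + comp$d + comp$aa + comp$ad + comp$dd
}

# class-wise MPH decomposition over a plan's hybrids: each class's
# F1 minus mid-parent contribution
mph_components <- function(geno, plan, arch) {
  ids <- rownames(geno$codes)
  need <- c(plan$female, plan$male)
  if (!all(need %in% ids)) stop("plan parents missing from genotype matrix")
  if (all(plan$hybrid %in% ids)) {
    hyb_codes <- geno$codes[plan$hybrid, , drop = FALSE]
  } else {
    hyb_codes <- (geno$codes[plan$female, , drop = FALSE] +
                  geno$codes[plan$male, , drop = FALSE]) / 2L
  }
  cf <- genotypic_components(hyb_codes, arch)
  cp1 <- genotypic_components(geno$codes[plan$female, , drop = FALSE], arch)
  cp2 <- genotypic_components(geno$codes[plan$male, , drop = FALSE], arch)
  stats::setNames(lapply(names(cf), function(k) cf[[k]] - (cp1[[k]] + cp2[[k]]) / 2),
                  names(cf))
}

#' True mid-parent heterosis of genotypic values
#'
#' Ground-truth MPH per hybrid: genotypic value of the F1 minus the mean of its
#' parents' genotypic values.
#'
#' @param geno \code{geno} object containing all parents (and optionally the
#'   hybrids; otherwise hybrid codes are deduced as the parental mean)
#' @param plan a \code{cross_plan}
#' @param arch a \code{trait_arch}
#' @return numeric vector of MPH values, named by hybrid id
#' @export
true_mph <- function(geno, plan, arch) {
  comp <- mph_components(geno, plan, arch)
  stats::setNames(comp$a + comp$d + comp$aa + comp$ad + comp$dd, plan$hybrid)
}

#' Simulate plot-level phenotypes
#'
#' value = genotypic value + environment effect + replicate effect + incomplete
#' block effect + plot residual. Noise variances are calibrated so the
#' plot-level heritability (entry variance over entry + rep + block + residual
#' variance within an environment) equals \code{config$h2_plot}; environment
#' main-effect variance is half the total noise variance, and the noise splits
#' 15\% replicate, 15\% block, 70\% residual. At \code{h2_plot = 1} all noise
#' terms (including environment) are zero.
#'
#' @param geno \code{geno} object with one row per entry (parents and hybrids)
#' @param arch a \code{trait_arch}
#' @param config a \code{\link{sim_config}}
#' @param trait trait label
#' @return data.frame (entry, env, rep, block, trait, value) with attribute
#'   \code{truth} holding genotypic values and the variance bookkeeping
#' @export
simulate_phenotypes <- function(geno, arch, config, trait = "trait") {
  stopifnot(inherits(config, "sim_config"))
  if (config$h2_plot <= 0 || config$h2_plot > 1) stop("h2_plot must be in (0,1]")
  set.seed(sub_seed(config$seed, "phenotypes"))
  G <- genotypic_value(geno$codes, arch)
  entries <- rownames(geno$codes)
  names(G) <- entries
  var_g <- stats::var(G)
  var_noise <- var_g * (1 - config$h2_plot) / config$h2_plot
  s_env <- sqrt(0.5 * var_noise)
  s_rep <- sqrt(0.15 * var_noise)
  s_blk <- sqrt(0.15 * var_noise)
  s_e <- sqrt(0.70 * var_noise)
  rows <- vector("list", config$n_env * config$n_rep)
  k <- 0
  for (ev in seq_len(config$n_env)) {
    e_env <- stats::rnorm(1, 0, s_env)
    for (rp in seq_len(config$n_rep)) {
      e_rep <- stats::rnorm(1, 0, s_rep)
      blk <- sample(rep_len(seq_len(config$n_block), length(entries)))
      e_blk <- stats::rnorm(config$n_block, 0, s_blk)
      k <- k + 1
      rows[[k]] <- data.frame(entry = entries,
                              env = paste0("env", ev),
                              rep = rp, block = blk, trait = trait,
                              value = G + e_env + e_rep + e_blk[blk] +
                                stats::rnorm(length(entries), 0, s_e),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(G = G, var_g = var_g,
                             sd = c(env = s_env, rep = s_rep,
                                    block = s_blk, plot = s_e))
  out
}
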