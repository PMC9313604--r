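# small fixture builders shared across test files

# hand-built inbred parents: codes 0/2 only
toy_parents <- function(codes, chrom = NULL, pos = NULL, pool = NULL) {
  L <- ncol(codes)
  if (is.null(chrom)) chrom <- rep("chr1", L)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  geno_matrix(codes, data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T"),
              pool = pool)
}

# a small NCII population with derived hybrids and kernels
small_ncii <- function(seed = 1, n1 = 8, n2 = 7, n_loci = 120, n_qtl = 12,
                       prop_var = c(0, 0.4, 0.2, 0.2, 0.2), fst = 0.25) {
  cfg <- sim_config(n_pool1 = n1, n_pool2 = n2, n_loci = n_loci,
                    fst_target = fst, n_qtl = n_qtl, prop_var = prop_var,
                    seed = seed)
  par <- simulate_parents(cfg)
  plan <- make_crossing_design(par, "NCII")
  arch <- simulate_architecture(cfg, par, plan, scale = "mph")
  list(cfg = cfg, parents = par, plan = plan, arch = arch,
       hybrids = derive_hybrid_genotypes(par, plan))
}

# balanced phenotype table: every entry in every rep/block cell
balanced_pheno <- function(values, n_rep = 2, n_block = 2, env = "e1",
                           noise_sd = 0) {
  entries <- names(values)
  d <- expand.grid(entry = entries, rep = seq_len(n_rep),
                   block = seq_len(n_block), stringsAsFactors = FALSE)
  d$env <- env
  d$value <- values[d$entry] + stats::rnorm(nrow(d), 0, noise_sd)
  d
}

# direct dense GLS solve, used as the whitening oracle
gls_direct <- function(y, X, V) {
  Vi <- solve(V)
  solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
}
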