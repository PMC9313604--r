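#' Pipeline run configuration
#'
#' Bundles a \code{\link{sim_config}} with the stage toggles and method
#' defaults of the full simulate -> QC -> heterosis -> kernels -> partition ->
#' scan pipeline. A single global seed is fanned out into named sub-seeds so
#' each stage is individually reproducible. Round-trips through YAML.
#'
#' @param sim a \code{\link{sim_config}} (or a list of its arguments)
#' @param stages character subset of
#'   c("qc", "heterosis", "kernels", "partition", "scan")
#' @param maf_min,miss_max,ld_window,ld_r2 QC thresholds
#' @param alpha scan family-wise level before Bonferroni division
#' @param n_perm permutations for the MPH-correlation test
#' @param chain list(n_iter, burn_in, thin) for the multi-kernel fit
#' @param seed global seed (overrides the sim seed)
#' @return list of class \code{run_config}
#' @export
run_config <- function(sim = sim_config(),
                       stages = c("qc", "heterosis", "kernels", "partition",
                                  "scan"),
                       maf_min = 0.05, miss_max = 0.05,
                       ld_window = 50, ld_r2 = 0.5,
                       alpha = 0.001, n_perm = 1000,
                       chain = list(n_iter = 4000, burn_in = 1000, thin = 5),
                       seed = 1L) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, stages = stages, maf_min = maf_min,
                 miss_max = miss_max, ld_window = ld_window, ld_r2 = ld_r2,
                 alpha = alpha, n_perm = n_perm, chain = chain,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Save / load a run configuration as YAML
#' @param config a \code{run_config}
#' @param path file path
#' @return \code{read_run_config} returns a \code{run_config}
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$prop_var <- as.list(x$sim$prop_var)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim_args <- x$sim
  sim_args$prop_var <- unlist(sim_args$prop_var)
  run_config(sim = sim_args, stages = x$stages, maf_min = x$maf_min,
             miss_max = x$miss_max, ld_window = x$ld_window, ld_r2 = x$ld_r2,
             alpha = x$alpha, n_perm = x$n_perm, chain = x$chain,
             seed = x$seed)
}

#' Run the full heterosis-dissection pipeline on simulated data
#'
#' Simulates the multi-hybrid population, then (per the stage toggles) applies
#' genotype QC, computes two-stage adjusted means and heterosis statistics,
#' builds the epistatic kernel set, partitions MPH variance, and runs the
#' three-step heterotic-effect scan. Outputs (CSV/JSON) and a manifest with
#' sub-seeds and checksums are written under \code{out_dir}.
#'
#' @param config a \code{\link{run_config}}
#' @param out_dir output directory (created if needed)
#' @param verbose print stage progress
#' @return invisibly, a list with the in-memory stage results
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  res <- list(config = config)
  sim <- config$sim

  say("stage: simulate")
  parents <- simulate_parents(sim)
  scheme <- if (sim$design == "both") "NCII" else sim$design
  plan <- make_crossing_design(parents, scheme)
  arch <- simulate_architecture(sim, parents, plan)
  hybrids <- derive_hybrid_genotypes(parents, plan)
  all_geno <- geno_matrix(rbind(parents$codes, hybrids$codes), parents$loci,
                          pool = c(parents$pool, rep(NA, nrow(plan))))
  pheno <- simulate_phenotypes(all_geno, arch, sim)
  write_genotypes(parents, file.path(out_dir, "parents.csv"), "csv")
  utils::write.csv(pheno, file.path(out_dir, "phenotypes.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(plan), file.path(out_dir, "plan.csv"),
                   row.names = FALSE)
  res$parents <- parents; res$plan <- plan; res$arch <- arch
  res$pheno <- pheno

  qc_geno <- parents
  if ("qc" %in% config$stages) {
    say("stage: qc")
    qc_geno <- filter_maf_missing(parents, config$maf_min, config$miss_max)
    qc_geno <- ld_prune(qc_geno, config$ld_window, config$ld_r2)
    res$qc <- qc_geno
  }
  hyb_qc <- derive_hybrid_genotypes(qc_geno, plan)

  if ("heterosis" %in% config$stages) {
    say("stage: heterosis")
    s1 <- stage1_adjusted_means(pheno)
    s2 <- stage2_blues(s1)
    het <- heterosis(s2, plan)
    utils::write.csv(het, file.path(out_dir, "heterosis.csv"),
                     row.names = FALSE)
    res$stage1 <- s1; res$blues <- s2; res$het <- het
  }

  if (any(c("kernels", "partition", "scan") %in% config$stages)) {
    say("stage: kernels")
    cod <- mph_codings(qc_geno, plan)
    kern <- build_kinships(cod)
    Tm <- build_T(plan, c(plan$hybrid, rownames(parents$codes)))
    res$codings <- cod; res$kernels <- kern; res$T <- Tm
  }

  mph <- if (!is.null(res$het)) {
    stats::setNames(res$het$mph, res$het$hybrid)[plan$hybrid]
  } else {
    true_mph(parents, plan, arch)
  }

  if ("partition" %in% config$stages) {
    say("stage: partition")
    fit <- fit_multikernel(mph, res$kernels, TTt = res$T$TTt,
                           n_iter = config$chain$n_iter,
                           burn_in = config$chain$burn_in,
                           thin = config$chain$thin,
                           seed = sub_seed(config$seed, "partition"))
    jsonlite::write_json(list(sigma2 = as.list(fit$sigma2),
                              prop_genetic = as.list(fit$prop_genetic)),
                         file.path(out_dir, "variance_components.json"),
                         auto_unbox = TRUE, digits = NA)
    res$partition <- fit
  }

  if ("scan" %in% config$stages) {
    say("stage: scan")
    vc <- if (!is.null(res$partition)) res$partition else {
      fit_multikernel(mph, res$kernels, TTt = res$T$TTt,
                      n_iter = config$chain$n_iter,
                      burn_in = config$chain$burn_in, thin = config$chain$thin,
                      seed = sub_seed(config$seed, "scan-null"))
    }
    wh <- whiten(mph, res$kernels, vc, TTt = res$T$TTt)
    sig <- scan_components(wh, res$codings, alpha = config$alpha)
    h <- heterotic_effects(sig, qc_geno, plan)
    perm <- permutation_test(h, mph, n_perm = config$n_perm,
                             seed = sub_seed(config$seed, "perm"))
    utils::write.csv(as.data.frame(sig), file.path(out_dir, "scan_effects.csv"),
                     row.names = FALSE)
    jsonlite::write_json(perm, file.path(out_dir, "mph_correlation.json"),
                         auto_unbox = TRUE, digits = NA)
    res$scan <- sig; res$h <- h; res$perm <- perm
  }

  manifest <- list(
    package = as.character(utils::packageVersion("heterokit")),
    seed = config$seed,
    sub_seeds = list(parents = sub_seed(config$seed, "parents"),
                     architecture = sub_seed(config$seed, "architecture"),
                     phenotypes = sub_seed(config$seed, "phenotypes"),
                     partition = sub_seed(config$seed, "partition"),
                     perm = sub_seed(config$seed, "perm")),
    stages = config$stages,
    checksums = vapply(list.files(out_dir, full.names = TRUE)[
      !grepl("manifest", list.files(out_dir))],
      function(f) unname(as.character(tools::md5sum(f))), ""))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
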