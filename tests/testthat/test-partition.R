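# single-kernel REML by profiled eigendecomposition; oracle for the sampler
reml_single_kernel <- function(y, K) {
  ee <- eigen(K, symmetric = TRUE)
  U <- ee$vectors; lam <- pmax(ee$values, 0)
  yt <- crossprod(U, y - mean(y))
  nll <- function(lr) {
    r <- exp(lr)               # sigma_g^2 / sigma_e^2
    w <- 1 + r * lam
    s2e <- mean(yt^2 / w)
    0.5 * (sum(log(w)) + length(y) * log(s2e))
  }
  o <- stats::optimize(nll, c(-10, 10))
  exp(o$minimum)
}

test_that("single-kernel variance ratio tracks the REML oracle", {
  set.seed(41)
  s <- small_ncii(seed = 41, n1 = 12, n2 = 10, n_loci = 200, n_qtl = 20)
  kern <- build_kinships(mph_codings(s$parents, s$plan))
  n <- nrow(s$plan)
  ratios <- sapply(1:6, function(sd) {
    set.seed(sd)
    ee <- eigen(kern$K_d, symmetric = TRUE)
    g <- ee$vectors %*% (sqrt(pmax(ee$values, 0)) * stats::rnorm(n)) * sqrt(2)
    y <- as.vector(g) + stats::rnorm(n)
    fit <- suppressWarnings(fit_multikernel(y, kern, model = "d",
                                            n_iter = 3000, burn_in = 1000,
                                            seed = sd))
    c(bayes = fit$sigma2[["d"]] / fit$sigma2[["residual"]],
      reml = reml_single_kernel(y, kern$K_d))
  })
  # posterior-mean ratio within 40% of the REML estimate on the same data
  expect_lt(mean(abs(ratios["bayes", ] / ratios["reml", ] - 1)), 0.4)
})

test_that("pure-noise MPH yields small genetic shares of total variance", {
  s <- small_ncii(seed = 43, n1 = 12, n2 = 10, n_loci = 200, n_qtl = 20)
  kern <- build_kinships(mph_codings(s$parents, s$plan))
  n <- nrow(s$plan)
  props <- sapply(1:3, function(sd) {
    set.seed(100 + sd)
    fit <- suppressWarnings(fit_multikernel(stats::rnorm(n), kern,
                                            n_iter = 3000, burn_in = 1000,
                                            seed = sd))
    fit$prop_total[c("d", "aa", "ad", "dd")]
  })
  expect_true(all(rowMeans(props) < 0.15))
})

test_that("dominance-dominated MPH puts the largest share on the d kernel", {
  wins <- sapply(1:10, function(sd) {
    s <- small_ncii(seed = 600 + sd, n1 = 10, n2 = 10, n_loci = 150,
                    n_qtl = 150, prop_var = c(0, 0.85, 0.05, 0.05, 0.05))
    kern <- build_kinships(mph_codings(s$parents, s$plan))
    mph_g <- true_mph(s$parents, s$plan, s$arch)
    vg <- stats::var(mph_g)
    set.seed(sd)
    y <- mph_g + stats::rnorm(length(mph_g), 0, sqrt(vg * 0.25))
    fit <- suppressWarnings(fit_multikernel(y, kern, n_iter = 2500,
                                            burn_in = 800, seed = sd))
    names(which.max(fit$prop_genetic)) == "d"
  })
  expect_gte(sum(wins), 8)
})

test_that("whitening with TTt = I equals the unwhitened path exactly", {
  s <- small_ncii(seed = 44, n1 = 6, n2 = 6, n_loci = 80, n_qtl = 8)
  kern <- build_kinships(mph_codings(s$parents, s$plan))
  y <- true_mph(s$parents, s$plan, s$arch)
  f1 <- suppressWarnings(fit_multikernel(y, kern, TTt = diag(length(y)),
                                         n_iter = 500, burn_in = 100, seed = 3))
  f2 <- suppressWarnings(fit_multikernel(y, kern, TTt = NULL,
                                         n_iter = 500, burn_in = 100, seed = 3))
  expect_identical(f1$sigma2, f2$sigma2)
})

test_that("posterior proportions are stable across sampler seeds", {
  s <- small_ncii(seed = 46, n1 = 12, n2 = 10, n_loci = 150, n_qtl = 150)
  kern <- build_kinships(mph_codings(s$parents, s$plan))
  mph_g <- true_mph(s$parents, s$plan, s$arch)
  set.seed(5)
  y <- mph_g + stats::rnorm(length(mph_g), 0, stats::sd(mph_g) * 0.5)
  f1 <- suppressWarnings(fit_multikernel(y, kern, n_iter = 6000,
                                         burn_in = 2000, n_chains = 2, seed = 11))
  f2 <- suppressWarnings(fit_multikernel(y, kern, n_iter = 6000,
                                         burn_in = 2000, n_chains = 2, seed = 99))
  expect_lt(max(abs(f1$prop_total - f2$prop_total)), 0.05)
  # fitted variance roughly accounts for var(y)
  tot <- sum(f1$sigma2[c("d", "aa", "ad", "dd")] * f1$var_weights) +
    f1$sigma2[["residual"]]
  expect_lt(abs(tot / stats::var(y) - 1), 0.2)
})

test_that("Bayesian ridge recovers planted dominance signals and shrinks noise", {
  set.seed(47)
  s <- small_ncii(seed = 47, n1 = 10, n2 = 9, n_loci = 150, n_qtl = 15)
  V <- build_codings(s$hybrids)$V
  n <- nrow(V)
  j0 <- which(apply(V, 2, stats::sd) > 0.3)[3]
  y <- 4 * V[, j0] + stats::rnorm(n)
  fit <- predict_dominance_effects(y, V, n_iter = 1500, burn_in = 400, seed = 2)
  expect_equal(unname(which.max(abs(fit$effect))), unname(j0))
  y0 <- stats::rnorm(n)
  fit0 <- predict_dominance_effects(y0, V, n_iter = 1500, burn_in = 400,
                                    seed = 2)
  expect_lt(max(abs(fit0$effect)), max(abs(fit$effect)) / 5)
})

test_that("ridge posterior means agree with the GBLUP backsolve", {
  set.seed(48)
  s <- small_ncii(seed = 48, n1 = 13, n2 = 12, n_loci = 400, n_qtl = 40)
  V <- build_codings(s$hybrids)$V
  n <- nrow(V)
  y <- as.vector(V %*% stats::rnorm(ncol(V), 0, 0.3)) + stats::rnorm(n)
  fit <- predict_dominance_effects(y, V, n_iter = 2500, burn_in = 800,
                                   seed = 3)
  lam <- fit$sigma2_e / fit$sigma2_b
  Vc <- scale(V, scale = FALSE)
  gb <- crossprod(Vc, solve(tcrossprod(Vc) + lam * diag(n), y - mean(y)))
  expect_gt(stats::cor(fit$effect, as.vector(gb)), 0.95)
})

test_that("cross-validation finds no signal in unrelated data", {
  s <- small_ncii(seed = 49, n1 = 16, n2 = 15, n_loci = 150, n_qtl = 15)
  kern <- build_kinships(mph_codings(s$parents, s$plan))
  set.seed(9)
  y <- stats::rnorm(nrow(s$plan))
  cv <- suppressWarnings(cross_validate(
    y, kern, models = list(dom = "d"), k_folds = 5, n_rep = 2,
    chain = list(n_iter = 800, burn_in = 200, thin = 5), seed = 4))
  expect_lt(abs(cv$summary["dom", "r"]), 0.15)
})

test_that("duplicating a kernel does not change predictive ability", {
  s <- small_ncii(seed = 50, n1 = 12, n2 = 10, n_loci = 150, n_qtl = 150,
                  prop_var = c(0, 0.9, 0.1, 0, 0))
  kern <- build_kinships(mph_codings(s$parents, s$plan))
  kern2 <- kern; kern2$K_aa <- kern$K_d   # duplicate dominance kernel
  mph_g <- true_mph(s$parents, s$plan, s$arch)
  set.seed(10)
  y <- mph_g + stats::rnorm(length(mph_g), 0, stats::sd(mph_g) * 0.5)
  cv <- suppressWarnings(cross_validate(
    y, kern2, models = list(single = "d", doubled = c("d", "aa")),
    k_folds = 5, n_rep = 2,
    chain = list(n_iter = 800, burn_in = 200, thin = 5), seed = 4))
  expect_lt(abs(cv$summary["single", "r"] - cv$summary["doubled", "r"]), 0.05)
})
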