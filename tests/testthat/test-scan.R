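test_that("whitening handles scalar covariance trivially", {
  y <- c(1, 2, 3, 4)
  wh1 <- whiten(y, NULL, c(residual = 1), TTt = NULL)
  expect_equal(wh1$y_star, y)
  wh4 <- whiten(y, NULL, c(residual = 4), TTt = NULL)
  expect_equal(wh4$y_star, y / 2)
})

test_that("whitened OLS equals direct generalized least squares", {
  set.seed(51)
  n <- 6
  K <- tcrossprod(matrix(stats::rnorm(n * 3), n, 3)) / 3
  TTt <- diag(n) + 0.25
  vc <- c(d = 0.7, residual = 1.3)
  kern <- list(K_d = K)
  y <- stats::rnorm(n)
  x <- stats::rnorm(n)
  wh <- whiten(y, kern, vc, TTt = TTt)
  X <- cbind(1, x)
  Xs <- wh$transform(X)
  beta_whiten <- stats::coef(stats::lm.fit(Xs, wh$y_star))
  V <- vc[["d"]] * K + vc[["residual"]] * TTt
  beta_gls <- gls_direct(y, X, V)
  expect_equal(unname(beta_whiten), unname(as.vector(beta_gls)),
               tolerance = 1e-10)
})

test_that("whitened scan with V = sigma^2 I matches an OLS scan", {
  set.seed(52)
  s <- small_ncii(seed = 52, n1 = 6, n2 = 6, n_loci = 30, n_qtl = 6)
  cod <- mph_codings(s$parents, s$plan)
  n <- nrow(s$plan)
  y <- stats::rnorm(n)
  wh <- whiten(y, NULL, c(residual = 2.5), TTt = NULL)
  sc <- scan_components(wh, cod, alpha = 0.05, kinds = "D", keep = "all")
  for (r in sample(nrow(sc), 5)) {
    f <- stats::lm(y ~ cod$V[, sc$i[r]])
    expect_equal(sc$p[r], summary(f)$coefficients[2, 4], tolerance = 1e-9)
    expect_equal(sc$estimate[r], unname(stats::coef(f)[2]), tolerance = 1e-9)
  }
})

test_that("the pairwise scan evaluates the full test inventory", {
  s <- small_ncii(seed = 53, n1 = 5, n2 = 5, n_loci = 12, n_qtl = 5)
  cod <- mph_codings(s$parents, s$plan)
  y <- stats::rnorm(nrow(s$plan))
  wh <- whiten(y, NULL, c(residual = 1), TTt = NULL)
  sc <- scan_components(wh, cod, alpha = 0.05, keep = "all")
  m <- ncol(cod$V)
  counts <- table(sc$kind)
  skipped_ok <- function(kind, target) counts[[kind]] <= target
  # m D tests, m(m-1)/2 AA and DD, m(m-1) AD (minus skipped constants)
  expect_true(skipped_ok("D", m))
  expect_true(skipped_ok("AA", m * (m - 1) / 2))
  expect_true(skipped_ok("DD", m * (m - 1) / 2))
  expect_true(skipped_ok("AD", m * (m - 1)))
  expect_gt(counts[["AD"]], counts[["DD"]])
  # Bonferroni monotonicity: stricter alpha yields a subset
  sc1 <- scan_components(wh, cod, alpha = 0.05)
  sc2 <- scan_components(wh, cod, alpha = 0.001)
  key <- function(x) paste(x$kind, x$i, x$j)
  expect_true(all(key(sc2) %in% key(sc1)))
})

test_that("heterotic effects follow the parental-class sign rules", {
  par <- toy_parents(rbind(P1 = c(2L, 2L, 2L, 0L), P2 = c(0L, 0L, 2L, 0L)))
  plan <- data.frame(female = "P1", male = "P2", hybrid = "H", design = "NCII")
  class(plan) <- c("cross_plan", "data.frame")
  # single significant dominance effect at a polymorphic locus
  eff_d <- data.frame(kind = "D", i = 1L, j = NA_integer_, estimate = 3)
  h <- heterotic_effects(eff_d, par, plan)
  expect_equal(unname(h["H", ]), c(3, 0, 0, 0))
  # aa pair with both loci in R20: -1/2 each, summing to -aa
  eff_aa <- data.frame(kind = "AA", i = 1L, j = 2L, estimate = 4)
  h2 <- heterotic_effects(eff_aa, par, plan)
  expect_equal(unname(h2["H", 1:2]), c(-2, -2))
  # ad with dominance at the polymorphic locus and additive partner in R22
  eff_ad <- data.frame(kind = "AD", i = 1L, j = 3L, estimate = 2)
  h3 <- heterotic_effects(eff_ad, par, plan)
  expect_equal(unname(h3["H", c(1, 3)]), c(1, 1))
  # additive partner in R00 flips the sign
  eff_ad0 <- data.frame(kind = "AD", i = 1L, j = 4L, estimate = 2)
  h4 <- heterotic_effects(eff_ad0, par, plan)
  expect_equal(unname(h4["H", c(1, 4)]), c(-1, -1))
  # heterozygous parent at a scanned locus is an error
  parh <- toy_parents(rbind(P1 = c(1L, 2L), P2 = c(0L, 0L)))
  expect_error(heterotic_effects(eff_d, parh, plan), "heterozygous")
})

test_that("summed heterotic effects reproduce genetic MPH exactly", {
  # the master identity that pins every sign and class rule
  for (sd in 1:8) {
    s <- small_ncii(seed = 700 + sd, n1 = 6, n2 = 6, n_loci = 60, n_qtl = 12,
                    prop_var = c(0, .25, .25, .25, .25))
    mph_g <- true_mph(s$parents, s$plan, s$arch)
    h <- heterotic_effects(arch_to_effects(s$arch), s$parents, s$plan)
    expect_lt(max(abs(rowSums(h) - mph_g)), 1e-10)
  }
})

test_that("aa scan estimates recover the architecture effect sign", {
  # a planted aa pair strongly polymorphic between pools is estimated with
  # its own sign and magnitude by the -m_i m_j covariable
  set.seed(55)
  par <- toy_parents(matrix(sample(c(0L, 2L), 80, TRUE), 20, 4),
                     pool = rep(c("pool1", "pool2"), each = 10))
  plan <- make_crossing_design(par, "NCII")
  cod <- mph_codings(par, plan)
  arch <- structure(list(qtl = 1:4, a = rep(0, 4), d = rep(0, 4),
                         aa = data.frame(i = 1L, j = 2L, effect = 3),
                         ad = data.frame(i = integer(), j = integer(),
                                         effect = numeric()),
                         dd = data.frame(i = integer(), j = integer(),
                                         effect = numeric()),
                         mu = 0), class = "trait_arch")
  y <- true_mph(par, plan, arch)
  wh <- whiten(y, NULL, c(residual = 1), TTt = NULL)
  sc <- scan_components(wh, cod, alpha = 0.05, kinds = "AA", keep = "all")
  hit <- sc[sc$i == 1 & sc$j == 2, ]
  expect_equal(hit$estimate, 3, tolerance = 1e-8)
})

test_that("permutation test is exact on identity predictions and degenerate h", {
  s <- small_ncii(seed = 56, n1 = 6, n2 = 6, n_loci = 60, n_qtl = 10,
                  prop_var = c(0, .4, .2, .2, .2))
  mph_g <- true_mph(s$parents, s$plan, s$arch)
  h <- heterotic_effects(arch_to_effects(s$arch), s$parents, s$plan)
  pt <- permutation_test(h, mph_g, n_perm = 499, seed = 1)
  expect_equal(pt$r_obs, 1, tolerance = 1e-10)
  expect_equal(pt$p_perm, 1 / 500)
  h0 <- h * 0
  pt0 <- permutation_test(h0, mph_g, n_perm = 499, seed = 1)
  expect_equal(pt0$p_perm, 1)
})

test_that("explained variance splits between independent causal loci", {
  set.seed(57)
  n <- 400
  h <- cbind(l1 = stats::rnorm(n), l2 = stats::rnorm(n))
  mph <- rowSums(h)
  ev <- explained_variance(h, mph)
  expect_equal(ev$joint, 1, tolerance = 1e-10)
  expect_equal(ev$per_locus$r2, c(0.5, 0.5), tolerance = 0.1)
  # single causal locus, noiseless
  ev1 <- explained_variance(h[, 1, drop = FALSE], h[, 1])
  expect_equal(ev1$per_locus$r2, 1, tolerance = 1e-10)
  # noise-only locus
  h2 <- cbind(h, l3 = stats::rnorm(n) * 1e-6)
  ev3 <- explained_variance(h2, mph, loci = 3)
  expect_lt(ev3$per_locus$r2, 0.05)
})
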