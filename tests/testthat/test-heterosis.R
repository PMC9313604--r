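test_that("stage-1 adjusted means equal raw means for balanced designs", {
  set.seed(1)
  vals <- stats::setNames(c(10, 12, 14, 16, 18), paste0("g", 1:5))
  d <- balanced_pheno(vals, noise_sd = 0.5)
  s1 <- stage1_adjusted_means(d)
  raw <- tapply(d$value, d$entry, mean)
  expect_equal(s1$blue, as.numeric(raw[s1$entry]), tolerance = 1e-8)
  # data with no rep/block effects reduce to one-way means too
  d0 <- balanced_pheno(vals, noise_sd = 0.3)
  s0 <- stage1_adjusted_means(d0)
  raw0 <- tapply(d0$value, d0$entry, mean)
  expect_equal(s0$blue, as.numeric(raw0[s0$entry]), tolerance = 1e-8)
})

test_that("stage-1 matches an independent mixed-model solve when unbalanced", {
  skip_if_not_installed("lme4")
  set.seed(13)
  d <- expand.grid(entry = paste0("g", 1:4), rep = 1:2, block = 1:2,
                   stringsAsFactors = FALSE)
  d <- d[-c(3, 8, 11), ]
  d$env <- "e1"
  d$rb <- interaction(d$rep, d$block)
  re <- stats::rnorm(2, 0, 1.5); be <- stats::rnorm(4, 0, 1)
  d$value <- as.numeric(factor(d$entry)) * 3 + re[d$rep] +
    be[as.integer(d$rb)] + stats::rnorm(nrow(d), 0, 0.5)
  s1 <- stage1_adjusted_means(d)
  fm <- suppressWarnings(lme4::lmer(
    value ~ 0 + entry + (1 | rep) + (1 | rb), data = d,
    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.rankZ = "ignore")))
  expect_equal(s1$blue, unname(lme4::fixef(fm)), tolerance = 1e-4)
})

test_that("EM-REML log-likelihood is non-decreasing", {
  set.seed(21)
  d <- balanced_pheno(stats::setNames(stats::rnorm(6, 10, 2), paste0("g", 1:6)),
                      noise_sd = 1)
  X <- stats::model.matrix(~ 0 + entry, d)
  Z <- list(rep = stats::model.matrix(~ 0 + factor(rep), d),
            blk = stats::model.matrix(~ 0 + interaction(rep, block), d))
  f <- emreml(d$value, X, Z, loglik = TRUE)
  expect_true(all(diff(f$loglik) > -1e-6))
  expect_true(f$converged)
})

test_that("stage-2 BLUEs combine environments as expected", {
  set.seed(12)
  s1 <- data.frame(entry = rep(paste0("g", 1:4), 2),
                   env = rep(c("e1", "e2"), each = 4),
                   blue = c(1, 2, 3, 4, 3, 4, 5, 6) +
                     stats::rnorm(8, 0, 0.2), se = 0.1)
  class(s1) <- c("blue_table", "data.frame")
  s2 <- stage2_blues(s1)
  raw <- tapply(s1$blue, s1$entry, mean)
  # balanced layout: the GLS estimate equals the per-entry mean
  expect_equal(s2$blue, as.numeric(raw[s2$entry]), tolerance = 1e-6)
  one <- s1[s1$env == "e1", ]
  expect_equal(stage2_blues(one)$blue, one$blue)   # single env: identity
})

test_that("MPH and BPH arithmetic is exact, signs admissible", {
  plan <- data.frame(female = c("P1", "P3"), male = c("P2", "P4"),
                     hybrid = c("H1", "H2"), design = "NCII",
                     stringsAsFactors = FALSE)
  class(plan) <- c("cross_plan", "data.frame")
  blues <- data.frame(entry = c("P1", "P2", "P3", "P4", "H1", "H2"),
                      blue = c(100, 50, 50, 60, 150, 40))
  h <- heterosis(blues, plan)
  expect_equal(h$mp, c(75, 55))
  expect_equal(h$mph, c(75, -15))
  expect_equal(h$mph_pct, c(100, -15 / 55 * 100))
  expect_equal(h$bph, c(50, -20))
  expect_equal(h$bph_pct, c(50, -20 / 60 * 100))
  # F1 = MP gives zero heterosis
  b0 <- blues; b0$blue[5] <- 75
  expect_equal(heterosis(b0, plan)$mph[1], 0)
  # zero mid-parent flags the relative form only
  bz <- data.frame(entry = c("P1", "P2", "H1"), blue = c(5, -5, 3))
  pz <- plan[1, ]; class(pz) <- class(plan)
  hz <- heterosis(bz, pz)
  expect_true(is.na(hz$mph_pct))
  expect_equal(hz$mph, 3)
})

test_that("heterosis is shift-invariant in absolute columns only", {
  set.seed(31)
  s <- small_ncii(seed = 31, n1 = 5, n2 = 4, n_loci = 50, n_qtl = 5)
  ent <- c(s$plan$hybrid, rownames(s$parents$codes))
  blues <- data.frame(entry = ent, blue = stats::rnorm(length(ent), 20, 3))
  h1 <- heterosis(blues, s$plan)
  blues2 <- blues; blues2$blue <- blues2$blue + 100
  h2 <- heterosis(blues2, s$plan)
  expect_equal(h1$mph, h2$mph)
  expect_equal(h1$bph, h2$bph)
  expect_false(isTRUE(all.equal(h1$mph_pct, h2$mph_pct)))
  # complete diallel: mean MP over crosses equals mean parental value
  pg <- geno_subset(s$parents, samples = 1:5)
  dia <- make_crossing_design(pg, "diallel")
  bl <- data.frame(entry = c(dia$hybrid, rownames(pg$codes)),
                   blue = stats::rnorm(nrow(dia) + 5, 50, 5))
  hh <- heterosis(bl, dia)
  pv <- bl$blue[match(rownames(pg$codes), bl$entry)]
  expect_equal(mean(hh$mp), mean(pv))
})

test_that("GCA/SCA variance components are recovered in a balanced NCII", {
  sim_gca <- function(seed, nf = 12, nm = 10, E = 2,
                      s2 = c(gf = 4, gm = 4, sca = 2, e = 4)) {
    set.seed(seed)
    fem <- sprintf("F%02d", 1:nf); mal <- sprintf("M%02d", 1:nm)
    plan <- expand.grid(male = mal, female = fem,
                        stringsAsFactors = FALSE)[, 2:1]
    plan$hybrid <- paste(plan$female, plan$male, sep = "x")
    plan$design <- "NCII"
    class(plan) <- c("cross_plan", "data.frame")
    gf <- stats::setNames(stats::rnorm(nf, 0, sqrt(s2["gf"])), fem)
    gm <- stats::setNames(stats::rnorm(nm, 0, sqrt(s2["gm"])), mal)
    sca <- stats::rnorm(nrow(plan), 0, sqrt(s2["sca"]))
    d <- do.call(rbind, lapply(1:E, function(ev)
      data.frame(entry = plan$hybrid, env = paste0("e", ev),
                 value = gf[plan$female] + gm[plan$male] + sca +
                   stats::rnorm(nrow(plan), 0, sqrt(s2["e"])))))
    list(d = d, plan = plan,
         realized = c(gf = stats::var(gf), gm = stats::var(gm),
                      sca = stats::var(sca)))
  }
  res <- sapply(1:5, function(sd) {
    x <- sim_gca(sd)
    fit <- gca_sca_variance(x$d, x$plan)
    fit$sigma2[c("gca_f", "gca_m", "sca", "residual")] /
      c(x$realized, e = 4)
  })
  # each component recovered within 30% on the 5-seed average,
  # relative to the realized effect variances
  expect_true(all(abs(rowMeans(res) - 1) < 0.3))
})

test_that("pure-noise data yields near-zero genetic components", {
  # GCA terms have clean replication across crosses and must vanish; SCA has
  # only two observations per cross and separates weakly from the residual
  # under the null, so it gets a looser sanity bound
  props <- sapply(1:5, function(sd) {
    set.seed(1000 + sd)
    fem <- paste0("F", 1:12); mal <- paste0("M", 1:10)
    plan <- expand.grid(male = mal, female = fem,
                        stringsAsFactors = FALSE)[, 2:1]
    plan$hybrid <- paste(plan$female, plan$male, sep = "x")
    plan$design <- "NCII"
    class(plan) <- c("cross_plan", "data.frame")
    d <- do.call(rbind, lapply(1:2, function(ev)
      data.frame(entry = plan$hybrid, env = paste0("e", ev),
                 value = stats::rnorm(nrow(plan)))))
    fit <- gca_sca_variance(d, plan)
    fit$sigma2[c("gca_f", "gca_m", "sca")] / sum(fit$sigma2)
  })
  expect_true(all(props[c("gca_f", "gca_m"), ] < 0.05))
  expect_true(all(props["sca", ] < 0.2))
  expect_lt(mean(props["sca", ]), 0.1)
  # non-identifiable layouts error
  p1 <- data.frame(female = "A", male = "B", hybrid = "AxB", design = "NCII")
  class(p1) <- c("cross_plan", "data.frame")
  expect_error(gca_sca_variance(
    data.frame(entry = "AxB", env = "e1", value = 1), p1), "non-identifiable")
})

test_that("heritability follows the entry-mean formula", {
  expect_equal(heritability(c(sigma2_g = 4, sigma2_ge = 2, sigma2_e = 4),
                            E = 2, R = 2), 2 / 3)
  expect_equal(heritability(c(sigma2_g = 4, sigma2_ge = 0, sigma2_e = 0),
                            E = 3, R = 2), 1)
  expect_equal(heritability(c(sigma2_g = 0, sigma2_ge = 2, sigma2_e = 4),
                            E = 2, R = 2), 0)
  expect_error(heritability(c(sigma2_g = 0, sigma2_ge = 0, sigma2_e = 0),
                            E = 1, R = 1), "denominator")
})

test_that("heterosis-distance regression behaves at the extremes", {
  set.seed(17)
  d <- stats::runif(300, 0.1, 0.5)
  f <- relate_heterosis_to_distance(3 + 10 * d + stats::rnorm(300, 0, 1e-3), d)
  expect_equal(f$r2, 1, tolerance = 1e-5)
  expect_equal(f$slope, 10, tolerance = 1e-2)
  f0 <- relate_heterosis_to_distance(stats::rnorm(500), stats::runif(500))
  expect_lt(f0$r2, 0.05)
  expect_error(relate_heterosis_to_distance(stats::rnorm(20), rep(0.3, 20)),
               "constant")
})
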