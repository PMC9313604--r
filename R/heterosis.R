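#' Stage-1 adjusted entry means within environments
#'
#' For each environment, fits entry (genotype) as fixed cell means with
#' replicate and incomplete-block (replicate:block) as independent random
#' effects by EM-REML, and returns the adjusted means (BLUEs). For a complete
#' balanced design the adjusted mean equals the raw entry mean.
#'
#' @param pheno data.frame with columns entry, env, rep, block, value (a
#'   \code{trait} column is carried along if unique)
#' @param environment optional subset of environments to process
#' @return data.frame of class \code{blue_table}: entry, env, blue, se
#' @export
stage1_adjusted_means <- function(pheno, environment = NULL) {
  stopifnot(all(c("entry", "env", "value") %in% names(pheno)))
  envs <- if (is.null(environment)) unique(pheno$env) else environment
  out <- list()
  for (ev in envs) {
    d <- pheno[pheno$env == ev & !is.na(pheno$value), , drop = FALSE]
    if (!nrow(d)) next
    d$entry <- factor(d$entry)
    X <- stats::model.matrix(~ 0 + entry, d)
    colnames(X) <- levels(d$entry)
    Z <- list()
    if (!is.null(d$rep) && length(unique(d$rep)) > 1) {
      Z$rep <- stats::model.matrix(~ 0 + factor(rep), d)
    }
    if (!is.null(d$block)) {
      bf <- interaction(d$rep, d$block, drop = TRUE)
      if (nlevels(bf) > 1) Z$block <- stats::model.matrix(~ 0 + bf, d)
    }
    if (!length(Z)) {
      mu <- tapply(d$value, d$entry, mean)
      nn <- tapply(d$value, d$entry, length)
      sdp <- stats::sd(d$value)
      out[[ev]] <- data.frame(entry = names(mu), env = ev,
                              blue = as.numeric(mu),
                              se = sdp / sqrt(as.numeric(nn)),
                              stringsAsFactors = FALSE)
      next
    }
    fit <- tryCatch(emreml(d$value, X, Z),
                    error = function(e) {
                      bad <- names(which(table(d$entry) == 0))
                      stop("stage-1 model failed in ", ev,
                           if (length(bad)) paste0("; entries without data: ",
                                                   paste(bad, collapse = ", ")),
                           "; ", conditionMessage(e))
                    })
    out[[ev]] <- data.frame(entry = names(fit$beta), env = ev,
                            blue = as.numeric(fit$beta),
                            se = sqrt(pmax(diag(fit$beta_cov), 0)),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  class(res) <- c("blue_table", "data.frame")
  res
}

#' Stage-2 across-environment BLUEs
#'
#' Combines stage-1 environment means per entry with genotype fixed and
#' environment random (EM-REML). With a single environment this is the
#' identity; for balanced data it is the per-entry mean of the stage-1 values.
#' Entries absent from every environment are dropped with a warning.
#'
#' @param stage1 a \code{blue_table} from \code{\link{stage1_adjusted_means}}
#' @return data.frame of class \code{blue_table}: entry, blue, se
#' @export
stage2_blues <- function(stage1) {
  d <- stage1[!is.na(stage1$blue), , drop = FALSE]
  lost <- setdiff(unique(stage1$entry), unique(d$entry))
  if (length(lost)) warning("entries dropped (no data): ",
                            paste(lost, collapse = ", "))
  d$entry <- factor(d$entry)
  if (length(unique(d$env)) == 1) {
    res <- data.frame(entry = as.character(d$entry), blue = d$blue, se = d$se,
                      stringsAsFactors = FALSE)
    class(res) <- c("blue_table", "data.frame")
    return(res)
  }
  X <- stats::model.matrix(~ 0 + entry, d)
  colnames(X) <- levels(d$entry)
  Z <- list(env = stats::model.matrix(~ 0 + factor(env), d))
  fit <- emreml(d$blue, X, Z)
  res <- data.frame(entry = names(fit$beta), blue = as.numeric(fit$beta),
                    se = sqrt(pmax(diag(fit$beta_cov), 0)),
                    stringsAsFactors = FALSE)
  class(res) <- c("blue_table", "data.frame")
  res
}

#' Mid-parent and better-parent heterosis
#'
#' MP = (P1 + P2)/2; MPH = F1 - MP; MPH\% = 100 MPH / MP;
#' BPH = F1 - max(P1, P2); BPH\% = 100 BPH / max(P1, P2). Negative values are
#' admissible (e.g. days-to-flowering traits). Relative forms are NA (flagged)
#' when their denominator is 0.
#'
#' @param blues a \code{blue_table} with across-environment values (columns
#'   entry, blue), or any data.frame with those columns
#' @param plan a \code{cross_plan}
#' @return data.frame of class \code{heterosis_table}: hybrid, f1, p1, p2, mp,
#'   p_better, mph, mph_pct, bph, bph_pct
#' @export
heterosis <- function(blues, plan) {
  v <- stats::setNames(blues$blue, blues$entry)
  need <- c(plan$hybrid, plan$female, plan$male)
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("missing BLUEs for: ", paste(utils::head(miss, 5),
                                                      collapse = ", "))
  f1 <- v[plan$hybrid]; p1 <- v[plan$female]; p2 <- v[plan$male]
  mp <- (p1 + p2) / 2
  pb <- pmax(p1, p2)
  mph <- f1 - mp
  bph <- f1 - pb
  out <- data.frame(hybrid = plan$hybrid, f1 = f1, p1 = p1, p2 = p2,
                    mp = mp, p_better = pb,
                    mph = mph,
                    mph_pct = ifelse(mp == 0, NA_real_, 100 * mph / mp),
                    bph = bph,
                    bph_pct = ifelse(pb == 0, NA_real_, 100 * bph / pb),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("heterosis_table", "data.frame")
  out
}

#' @export
print.heterosis_table <- function(x, ...) {
  cat("heterosis_table:", nrow(x), "hybrids\n")
  cat(sprintf("mean MPH %.3f (MPH%% %.2f), mean BPH %.3f (BPH%% %.2f)\n",
              mean(x$mph), mean(x$mph_pct, na.rm = TRUE),
              mean(x$bph), mean(x$bph_pct, na.rm = TRUE)))
  invisible(x)
}

#' GCA/SCA variance decomposition
#'
#' EM-REML variance components of the combining-ability model: value =
#' group (fixed) + env + [rep within env] + GCA(female) + GCA(male) + SCA +
#' GCA x env + SCA x env + residual, all non-group effects random. In a
#' diallel, where the female and male parent sets coincide, a single GCA term
#' with summed incidence (one effect per parent, entering through both the
#' female and male side) replaces the two separate GCA factors. Interaction
#' terms are included only when the layout identifies them (more than one
#' environment; SCA x env additionally needs replicates within environment).
#'
#' @param data data.frame with columns entry, env, value and optionally rep;
#'   entries are hybrid ids from the plan and optionally parental-line ids
#' @param plan a \code{cross_plan}
#' @return object of class \code{gca_sca_fit}: the \code{emreml_fit} plus
#'   design bookkeeping (E = environment count, R = mean replicate count)
#' @export
gca_sca_variance <- function(data, plan) {
  stopifnot(all(c("entry", "env", "value") %in% names(data)))
  d <- data[!is.na(data$value), , drop = FALSE]
  is_hyb <- d$entry %in% plan$hybrid
  is_line <- !is_hyb
  fem <- ifelse(is_hyb, plan$female[match(d$entry, plan$hybrid)], d$entry)
  mal <- ifelse(is_hyb, plan$male[match(d$entry, plan$hybrid)], d$entry)
  if (length(unique(d$entry[is_hyb])) < 2) stop("non-identifiable layout: need >= 2 crosses")
  if (length(unique(fem[is_hyb])) < 2 || length(unique(mal[is_hyb])) < 2) {
    stop("non-identifiable layout: need >= 2 females and >= 2 males")
  }
  X <- if (any(is_line)) {
    stats::model.matrix(~ factor(ifelse(is_hyb, "hybrid", "line")))
  } else {
    matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
  }
  n_env <- length(unique(d$env))
  has_rep <- !is.null(d$rep) && any(tapply(d$rep, interaction(d$entry, d$env),
                                           function(z) length(unique(z))) > 1)
  diallel <- length(intersect(unique(fem[is_hyb]), unique(mal[is_hyb]))) > 0
  Z <- list()
  if (n_env > 1) Z$env <- stats::model.matrix(~ 0 + factor(env), d)
  if (has_rep) {
    Z$rep_env <- stats::model.matrix(~ 0 + interaction(env, rep, drop = TRUE), d)
  }
  inc <- function(f) {
    f <- factor(f)
    m <- stats::model.matrix(~ 0 + f)
    colnames(m) <- levels(f)
    m
  }
  if (diallel) {
    par_lev <- sort(unique(c(fem, mal)))
    Zf <- inc(factor(fem, levels = par_lev))
    Zm <- inc(factor(mal, levels = par_lev))
    Z$gca <- Zf + Zm   # lines (i = j) load their parent column twice
  } else {
    Z$gca_f <- inc(fem)
    Z$gca_m <- inc(mal)
  }
  Z$sca <- inc(d$entry)
  if (n_env > 1) {
    if (diallel) {
      Z$gca_env <- stats::model.matrix(~ 0 + interaction(fem, d$env, drop = TRUE)) +
        stats::model.matrix(~ 0 + interaction(mal, d$env, drop = TRUE))
    } else {
      Z$gca_f_env <- inc(interaction(fem, d$env, drop = TRUE))
      Z$gca_m_env <- inc(interaction(mal, d$env, drop = TRUE))
    }
    if (has_rep) Z$sca_env <- inc(interaction(d$entry, d$env, drop = TRUE))
  }
  if (!has_rep && n_env == 1) {
    stop("non-identifiable layout: SCA is confounded with the residual ",
         "(need replicates or >= 2 environments)")
  }
  fit <- emreml(d$value, X, Z)
  R_mean <- if (has_rep) {
    mean(tapply(d$rep, interaction(d$entry, d$env, drop = TRUE),
                function(z) length(unique(z))))
  } else 1
  structure(list(fit = fit, sigma2 = fit$sigma2, E = n_env, R = R_mean,
                 diallel = diallel),
            class = "gca_sca_fit")
}

#' @export
print.gca_sca_fit <- function(x, ...) {
  cat("GCA/SCA variance components (", if (x$diallel) "diallel" else "NCII",
      ", E = ", x$E, ")\n", sep = "")
  print(round(x$sigma2, 5))
  invisible(x)
}

#' Entry-mean heritability
#'
#' H^2 = sigma2_G / (sigma2_G + sigma2_GE / E + sigma2_e / (E R)), the
#' genotypic-to-phenotypic variance ratio on an entry-mean basis. For a
#' \code{gca_sca_fit}, sigma2_G pools the GCA and SCA components and
#' sigma2_GE pools their environment interactions.
#'
#' @param vc a \code{gca_sca_fit}, or a list/vector with elements
#'   \code{sigma2_g}, \code{sigma2_ge}, \code{sigma2_e}
#' @param E environment count (default from the fit)
#' @param R mean replicate count per entry and environment
#' @return heritability in [0, 1]
#' @export
heritability <- function(vc, E = NULL, R = NULL) {
  if (inherits(vc, "gca_sca_fit")) {
    s <- vc$sigma2
    g_terms <- intersect(names(s), c("gca", "gca_f", "gca_m", "sca"))
    ge_terms <- intersect(names(s), c("gca_env", "gca_f_env", "gca_m_env",
                                      "sca_env"))
    sg <- sum(s[g_terms]); sge <- sum(s[ge_terms]); se <- s[["residual"]]
    if (is.null(E)) E <- vc$E
    if (is.null(R)) R <- vc$R
  } else {
    sg <- vc[["sigma2_g"]]; sge <- vc[["sigma2_ge"]]; se <- vc[["sigma2_e"]]
  }
  stopifnot(E >= 1, R >= 1)
  denom <- sg + sge / E + se / (E * R)
  if (denom <= 0) stop("zero phenotypic variance denominator")
  as.numeric(sg / denom)
}

#' Relate heterosis to parental genetic distance
#'
#' Linear fit (R^2, slope) and a locally weighted (tri-cube kernel, degree-1)
#' smooth of MPH on a genetic distance, the standard way to display how hybrid
#' vigor grows with parental divergence.
#'
#' @param mph numeric vector of per-hybrid MPH values
#' @param distance numeric vector of matching distances (RD or the
#'   dominance-weighted form)
#' @param span loess span
#' @return list: \code{r2}, \code{slope}, \code{intercept}, \code{lm} fit,
#'   \code{smooth} (data.frame distance, fitted, ordered by distance)
#' @export
relate_heterosis_to_distance <- function(mph, distance, span = 0.75) {
  stopifnot(length(mph) == length(distance))
  ok <- is.finite(mph) & is.finite(distance)
  if (sum(ok) < 10) stop("need >= 10 hybrid pairs")
  if (stats::sd(distance[ok]) == 0) stop("distance is constant")
  d <- data.frame(mph = mph[ok], distance = distance[ok])
  lf <- stats::lm(mph ~ distance, data = d)
  lo <- stats::loess(mph ~ distance, data = d, span = span, degree = 1,
                     family = "gaussian")
  ord <- order(d$distance)
  list(r2 = summary(lf)$r.squared,
       slope = unname(stats::coef(lf)[2]),
       intercept = unname(stats::coef(lf)[1]),
       lm = lf,
       smooth = data.frame(distance = d$distance[ord],
                           fitted = stats::fitted(lo)[ord]))
}
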