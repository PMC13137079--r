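# Validation statistics: SNP-bias bootstrap screening, Spearman concordance,
# permutation ANCOVA (Freedman-Lane), profile bias and variance tests,
# Bland-Altman agreement, and the biomass-correction comparison. All deviations
# are hi_obs - hi_exp in HI units; positive values mean a shift toward the
# B (T. macedonicus) lineage.

#' Per-SNP systematic bias with bootstrap retention decision
#'
#' For each SNP, the systematic bias is the median deviation
#' (`hi_obs - hi_exp`) over swab samples with confirmed genotypes. A
#' percentile bootstrap (B resamples with replacement) gives a 95% CI for
#' this median; the SNP is retained only when the entire CI lies within
#' `[-tol, +tol]` (default 0.05 HI units, a 5% allowable deviation on the HI
#' scale).
#'
#' @param deviations data.frame with `snp_id` and `deviation`.
#' @param B Number of bootstrap resamples (default 2000).
#' @param tol Retention half-band in HI units (default 0.05).
#' @param seed Optional integer seed for the resampling.
#' @param conf Confidence level of the percentile interval.
#' @return data.frame with one row per SNP: `median_bias`, `ci_low`,
#'   `ci_high`, `n`, `retained` (`NA` when fewer than 2 deviations).
#' @export
snp_bias <- function(deviations, B = 2000, tol = 0.05, seed = NULL,
                     conf = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  snps <- sort(unique(deviations$snp_id))
  out <- do.call(rbind, lapply(snps, function(snp) {
    d <- deviations$deviation[deviations$snp_id == snp]
    d <- d[!is.na(d)]
    if (length(d) < 2) {
      return(data.frame(snp_id = snp, n = length(d),
                        median_bias = if (length(d)) stats::median(d) else NA,
                        ci_low = NA_real_, ci_high = NA_real_,
                        retained = NA))
    }
    boots <- vapply(seq_len(B), function(i) {
      stats::median(sample(d, length(d), replace = TRUE))
    }, numeric(1))
    ci <- unname(stats::quantile(boots, probs))
    data.frame(snp_id = snp, n = length(d), median_bias = stats::median(d),
               ci_low = ci[1], ci_high = ci[2],
               retained = ci[1] >= -tol & ci[2] <= tol)
  }))
  rownames(out) <- NULL
  out
}

#' Spearman concordance between observed and expected HI per regime
#'
#' @param hi_obs,hi_exp Numeric vectors of paired HI values.
#' @param regime Factor/character of sampling-regime labels.
#' @return data.frame per regime with `n`, `rho`, `p_value` (`NA` with a
#'   note when `hi_exp` is constant and the rank correlation is undefined).
#' @export
concordance <- function(hi_obs, hi_exp, regime) {
  regimes <- sort(unique(as.character(regime)))
  out <- do.call(rbind, lapply(regimes, function(r) {
    i <- regime == r & !is.na(hi_obs) & !is.na(hi_exp)
    n <- sum(i)
    if (n < 3 || length(unique(hi_exp[i])) < 2 ||
        length(unique(hi_obs[i])) < 2) {
      return(data.frame(regime = r, n = n, rho = NA_real_,
                        p_value = NA_real_,
                        note = "undefined: constant input or n < 3"))
    }
    ct <- suppressWarnings(
      stats::cor.test(hi_obs[i], hi_exp[i], method = "spearman"))
    data.frame(regime = r, n = n, rho = unname(ct$estimate),
               p_value = ct$p.value, note = "")
  }))
  rownames(out) <- NULL
  out
}

# Residual-maker and fitted values for a model matrix (QR based).
.lm_proj <- function(X, y) {
  qr_x <- qr(X)
  fitted <- qr.fitted(qr_x, y)
  list(qr = qr_x, fitted = fitted, resid = y - fitted,
       rank = qr_x$rank)
}

#' Permutation ANCOVA for HI_obs ~ HI_exp x regime
#'
#' Linear model of observed on expected HI with sampling regime and their
#' interaction. Term p-values come from Freedman-Lane permutation: for each
#' term, the reduced model without it is fitted, its residuals are permuted
#' and added back to its fitted values, the full model is refitted on each
#' pseudo-response, and the term's F statistic is compared with the observed
#' one; p = (1 + #\{F* >= F_obs\}) / (n_perm + 1).
#'
#' @param hi_obs,hi_exp Numeric vectors.
#' @param regime Two-level regime labels.
#' @param n_perm Number of permutations (default 5000; at least 999 is
#'   recommended for stable tail estimates).
#' @param seed Optional integer seed.
#' @return data.frame with one row per term (`hi_exp`, `regime`,
#'   `hi_exp:regime`): observed `F`, degrees of freedom and permutation
#'   `p_value`.
#' @export
permutation_ancova <- function(hi_obs, hi_exp, regime, n_perm = 5000,
                               seed = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  ok <- !is.na(hi_obs) & !is.na(hi_exp) & !is.na(regime)
  y <- hi_obs[ok]; xe <- hi_exp[ok]
  g <- factor(regime[ok])
  if (nlevels(g) < 2) stop("both sampling regimes must be represented")
  mf <- stats::model.frame(~ xe * g)
  X <- stats::model.matrix(~ xe * g, mf)
  n <- length(y)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  assign <- attr(X, "assign")
  terms <- c("hi_exp", "regime", "hi_exp:regime")
  full <- .lm_proj(X, y)
  rss_full <- sum(full$resid^2)
  df_res <- n - ncol(X)
  out <- do.call(rbind, lapply(seq_along(terms), function(j) {
    keep <- assign != j
    Xr <- X[, keep, drop = FALSE]
    red <- .lm_proj(Xr, y)
    df_j <- sum(assign == j)
    f_obs <- ((sum(red$resid^2) - rss_full) / df_j) / (rss_full / df_res)
    # Freedman-Lane: permute reduced-model residuals
    f_star <- vapply(seq_len(n_perm), function(p) {
      ystar <- red$fitted + red$resid[sample.int(n)]
      full_s <- .lm_proj(X, ystar)
      rss_f <- sum(full_s$resid^2)
      red_s <- .lm_proj(Xr, ystar)
      ((sum(red_s$resid^2) - rss_f) / df_j) / (rss_f / df_res)
    }, numeric(1))
    data.frame(term = terms[j], df = df_j, df_res = df_res, F = f_obs,
               p_value = (1 + sum(f_star >= f_obs)) / (n_perm + 1))
  }))
  rownames(out) <- NULL
  out
}

#' Profile-wise bias tests
#'
#' Within each sampling regime: a Kruskal-Wallis test of the deviations
#' across genotypic profiles, then per-profile one-sample Wilcoxon
#' signed-rank tests against zero with Holm correction across the profiles
#' of that regime. Profiles whose deviations are all exactly zero are
#' degenerate for the signed-rank statistic and reported with p = 1.
#'
#' @param deviations Numeric vector of `hi_obs - hi_exp` values.
#' @param profile Genotypic-profile labels (expected HI of the population).
#' @param regime Sampling-regime labels.
#' @return List with `kruskal` (one row per regime) and `wilcoxon` (one row
#'   per regime x profile with `median_bias`, `p_value`, `p_adj`).
#' @export
profile_bias_tests <- function(deviations, profile, regime) {
  regimes <- sort(unique(as.character(regime)))
  kw <- list(); wx <- list()
  for (r in regimes) {
    i <- regime == r & !is.na(deviations)
    d <- deviations[i]; pr <- factor(profile[i])
    usable <- nlevels(droplevels(pr)) >= 2 &&
      all(table(droplevels(pr)) >= 2)
    if (usable) {
      k <- stats::kruskal.test(d, droplevels(pr))
      kw[[r]] <- data.frame(regime = r, statistic = unname(k$statistic),
                            df = unname(k$parameter), p_value = k$p.value)
    } else {
      kw[[r]] <- data.frame(regime = r, statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_)
    }
    profs <- sort(unique(as.character(pr)))
    rows <- do.call(rbind, lapply(profs, function(p) {
      dp <- d[pr == p]
      pval <- if (all(dp == 0)) 1 else
        suppressWarnings(stats::wilcox.test(dp, mu = 0)$p.value)
      data.frame(regime = r, profile = p, n = length(dp),
                 median_bias = stats::median(dp), p_value = pval)
    }))
    rows$p_adj <- stats::p.adjust(rows$p_value, method = "holm")
    wx[[r]] <- rows
  }
  list(kruskal = do.call(rbind, kw), wilcoxon = do.call(rbind, wx))
}

#' Pairwise variance homogeneity across genotypic profiles
#'
#' Fligner-Killeen tests for every pair of profiles, Holm-adjusted across
#' the set of pairs. Pairs with fewer than 2 observations per group or a
#' constant pooled response are reported as untestable.
#'
#' @param deviations Numeric vector of deviations.
#' @param profile Profile labels.
#' @return data.frame with one row per profile pair: `statistic`,
#'   `p_value`, `p_adj`, `testable`.
#' @export
variance_homogeneity <- function(deviations, profile) {
  profile <- as.character(profile)
  profs <- sort(unique(profile))
  if (length(profs) < 2) stop("need at least two profiles")
  pairs <- utils::combn(profs, 2)
  rows <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    p1 <- pairs[1, j]; p2 <- pairs[2, j]
    i <- profile %in% c(p1, p2) & !is.na(deviations)
    d <- deviations[i]; g <- factor(profile[i])
    testable <- all(table(g) >= 2) && length(unique(d)) > 1
    if (testable) {
      ft <- stats::fligner.test(d, g)
      data.frame(profile_1 = p1, profile_2 = p2,
                 statistic = unname(ft$statistic), p_value = ft$p.value,
                 testable = TRUE)
    } else {
      data.frame(profile_1 = p1, profile_2 = p2, statistic = NA_real_,
                 p_value = NA_real_, testable = FALSE)
    }
  }))
  rows$p_adj <- NA_real_
  rows$p_adj[rows$testable] <- stats::p.adjust(rows$p_value[rows$testable],
                                               method = "holm")
  rownames(rows) <- NULL
  rows
}

#' Bland-Altman agreement summary
#'
#' Mean bias and 95% limits of agreement (mean +/- z x SD, z = 1.96 by
#' default) of a set of paired differences, the interval expected to contain
#' ~95% of differences. The SD uses the n-1 denominator.
#'
#' @param differences Numeric vector of paired differences (HI units).
#' @param z LoA multiplier.
#' @return List of class `"bland_altman"` with `mean_bias`, `sd`,
#'   `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(differences, z = 1.96) {
  differences <- differences[!is.na(differences)]
  n <- length(differences)
  if (n < 2) stop("Bland-Altman needs at least 2 differences")
  m <- mean(differences); s <- stats::sd(differences)
  structure(list(mean_bias = m, sd = s, loa_low = m - z * s,
                 loa_high = m + z * s, n = n, z = z),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean bias %.4f, SD %.4f, %s LoA [%.4f, %.4f]\n",
              x$n, x$mean_bias, x$sd,
              paste0(round(100 * (2 * stats::pnorm(x$z) - 1)), "%"),
              x$loa_low, x$loa_high))
  invisible(x)
}

#' Effect of biomass correction on absolute deviations
#'
#' For each mixed-genotype profile, compares `|hi_obs - hi_exp|` under the
#' uncorrected versus biomass-corrected expectation with a paired Wilcoxon
#' signed-rank test; Holm adjustment across the profiles tested. All-tie
#' inputs (corrected identical to uncorrected) are degenerate and reported
#' with p = 1; single pairs are untestable.
#'
#' @param abs_dev_uncorrected,abs_dev_corrected Equal-length numeric vectors
#'   of absolute deviations, paired by observation.
#' @param profile Profile label per observation.
#' @return data.frame per profile: `n`, `median_diff`
#'   (uncorrected - corrected; positive means correction helps), `p_value`,
#'   `p_adj`, `testable`.
#' @export
biomass_effect_test <- function(abs_dev_uncorrected, abs_dev_corrected,
                                profile) {
  stopifnot(length(abs_dev_uncorrected) == length(abs_dev_corrected))
  profs <- sort(unique(as.character(profile)))
  rows <- do.call(rbind, lapply(profs, function(p) {
    i <- profile == p & !is.na(abs_dev_uncorrected) &
      !is.na(abs_dev_corrected)
    u <- abs_dev_uncorrected[i]; v <- abs_dev_corrected[i]
    n <- length(u)
    if (n < 2) {
      return(data.frame(profile = p, n = n,
                        median_diff = if (n) stats::median(u - v) else NA,
                        p_value = NA_real_, testable = FALSE))
    }
    pval <- if (all(u == v)) 1 else
      suppressWarnings(stats::wilcox.test(u, v, paired = TRUE)$p.value)
    data.frame(profile = p, n = n, median_diff = stats::median(u - v),
               p_value = pval, testable = TRUE)
  }))
  rows$p_adj <- NA_real_
  rows$p_adj[rows$testable] <- stats::p.adjust(rows$p_value[rows$testable],
                                               method = "holm")
  rownames(rows) <- NULL
  rows
}
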