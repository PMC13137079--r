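# Angle -> hybrid index mapping and HI aggregation. The hybrid index is the
# proportion of B-diagnostic (T. macedonicus) alleles: 0 = pure A lineage,
# 1 = pure B lineage, 0.5 = balanced (F1-like) composition.

#' Map a fluorescence angle to the hybrid index
#'
#' Piecewise-linear interpolation along the arc defined by the three
#' genotype centroids of a SNP: HI = 0 at `alpha_A`, 0.5 at `alpha_AB` and
#' 1 at `alpha_B`. Outside `[alpha_B, alpha_A]` the adjacent segment is
#' extrapolated linearly rather than truncated, preserving linearity and
#' allowing minor excursions beyond \[0, 1\] (residual fluorescence in the
#' opposite channel makes the anchors themselves sit short of 0/90 degrees).
#'
#' @param alpha Sample angle(s) in degrees (see [angle_of()]).
#' @param cal One calibration row (or equal-length vectors via `alpha_A`,
#'   `alpha_AB`, `alpha_B` columns) with strictly ordered angles
#'   `alpha_B < alpha_AB < alpha_A`.
#' @return Hybrid-index value(s); strictly decreasing and continuous in
#'   `alpha`, not truncated to \[0, 1\].
#' @examples
#' cal <- data.frame(alpha_A = 82, alpha_AB = 46.6, alpha_B = 12.9)
#' angle_to_hi(c(82, 46.6, 12.9, 64.3), cal)
#' @export
angle_to_hi <- function(alpha, cal) {
  aA <- cal$alpha_A; aAB <- cal$alpha_AB; aB <- cal$alpha_B
  if (any(!(aB < aAB & aAB < aA))) {
    stop("invalid calibration: need alpha_B < alpha_AB < alpha_A")
  }
  upper <- 0.5 * (aA - alpha) / (aA - aAB)
  lower <- 0.5 + 0.5 * (aAB - alpha) / (aAB - aB)
  ifelse(alpha >= aAB, upper, lower)
}

#' Inverse of the angle-to-HI map
#'
#' Returns the angle at which [angle_to_hi()] yields the given hybrid-index
#' value; used by the simulator to place eDNA signals at a latent allele
#' proportion.
#'
#' @param hi Hybrid-index value(s).
#' @inheritParams angle_to_hi
#' @return Angle(s) in degrees.
#' @export
hi_to_angle <- function(hi, cal) {
  aA <- cal$alpha_A; aAB <- cal$alpha_AB; aB <- cal$alpha_B
  if (any(!(aB < aAB & aAB < aA))) {
    stop("invalid calibration: need alpha_B < alpha_AB < alpha_A")
  }
  upper <- aA - (hi / 0.5) * (aA - aAB)
  lower <- aAB - ((hi - 0.5) / 0.5) * (aAB - aB)
  ifelse(hi <= 0.5, upper, lower)
}

#' Expected hybrid index per population and SNP
#'
#' The expected HI of a population at a SNP is the mean genotype
#' contribution (A -> 0, AB -> 0.5, B -> 1) over its member animals, using
#' only verified genotypes: a (population, SNP) pair in which any member's
#' genotype could not be verified (a mismatched call) is marked unavailable
#' so the exclusion propagates downstream.
#'
#' @param design Member-level design table.
#' @param snp_ids Character vector of SNP identifiers in the panel.
#' @param excluded Optional data.frame of unverified calls with columns
#'   `animal_id` (or `sample_id`) and `snp_id`; `snp_id = NA` marks an
#'   animal excluded at every SNP.
#' @return data.frame with `population_id`, `snp_id`, `hi_exp`, `available`.
#' @export
expected_hi <- function(design, snp_ids, excluded = NULL) {
  design <- as_design_table(design)
  if (!is.null(excluded) && nrow(excluded)) {
    idcol <- if ("animal_id" %in% names(excluded)) "animal_id" else "sample_id"
    excluded <- data.frame(animal_id = excluded[[idcol]],
                           snp_id = excluded$snp_id)
  } else {
    excluded <- data.frame(animal_id = character(), snp_id = character())
  }
  grid <- expand.grid(population_id = unique(design$population_id),
                      snp_id = snp_ids, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    pop <- grid$population_id[i]; snp <- grid$snp_id[i]
    members <- design[design$population_id == pop, , drop = FALSE]
    bad <- members$animal_id %in%
      excluded$animal_id[is.na(excluded$snp_id) | excluded$snp_id == snp]
    if (any(bad)) {
      data.frame(population_id = pop, snp_id = snp, hi_exp = NA_real_,
                 available = FALSE)
    } else {
      data.frame(population_id = pop, snp_id = snp,
                 hi_exp = mean(genotype_hi(members$expected_genotype)),
                 available = TRUE)
    }
  })
  out <- do.call(rbind, res)
  out[order(out$population_id, out$snp_id), ]
}

#' Biomass-corrected expected hybrid index
#'
#' Weights each member's genotype contribution by its body mass, so that a
#' heavier animal (presumed to shed more DNA) moves the expectation toward
#' its own ancestry: `hi_exp_bio = sum(mass_i * hi_i) / sum(mass_i)`. With
#' equal masses this reduces to the unweighted mean.
#'
#' @param design Member-level design table with a positive `body_mass`
#'   column (grams).
#' @return data.frame with `population_id`, `hi_exp`, `hi_exp_bio`.
#' @export
biomass_corrected_hi <- function(design) {
  design <- as_design_table(design)
  if (!"body_mass" %in% names(design)) stop("design has no body_mass column")
  mass <- as.numeric(design$body_mass)
  if (any(is.na(mass) | mass <= 0)) {
    stop("all member body masses must be present and strictly positive")
  }
  hi <- genotype_hi(design$expected_genotype)
  pops <- unique(design$population_id)
  out <- do.call(rbind, lapply(pops, function(p) {
    i <- design$population_id == p
    data.frame(population_id = p,
               hi_exp = mean(hi[i]),
               hi_exp_bio = sum(mass[i] * hi[i]) / sum(mass[i]))
  }))
  out[order(out$population_id), ]
}

#' Aggregate per-SNP hybrid-index values for one sample
#'
#' The overall HI of a sample is the arithmetic mean of its available
#' per-SNP HI estimates; excluded SNPs simply do not enter the mean.
#'
#' @param hi_values Numeric vector of per-SNP `hi_obs` values (`NA` for
#'   excluded SNPs).
#' @return List with `hi_obs` (the mean) and `n_snps` used.
#' @export
population_hi <- function(hi_values) {
  ok <- !is.na(hi_values)
  if (!any(ok)) stop("no available SNP estimates to aggregate")
  list(hi_obs = mean(hi_values[ok]), n_snps = sum(ok))
}
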