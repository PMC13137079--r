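# Synthetic fluorescence-data generator. Emulates the mesocosm validation
# design: per-SNP genotype clusters at genotype-specific angles in the
# (FAM, HEX) plane, replicate-level angular noise, allelic dropout and false
# heterozygotes in swab PCRs, low-fluorescence failures, and eDNA signals
# whose angle reflects the population's latent allele proportion under
# individual shedding weights, with regime-dependent noise.

#' Simulation configuration
#'
#' Defaults encode the validated mesocosm study conditions: nine diagnostic
#' SNPs whose homozygous centroid angles concentrate near 82 degrees
#' (A cluster, SD 1.13) and 12.9 degrees (B cluster, SD 1.46) with the
#' heterozygous cluster more variable (46.6 degrees, SD 6.05) owing to
#' allele-specific primer competition; a 3.5% allelic-dropout rate and a
#' 1.27% false-heterozygote rate at the sample x SNP level; ~4.5% of PCRs
#' failing into the low-fluorescence triangle; four PCR replicates; five
#' genotypic profiles (expected HI 0, 0.25, 0.5, 0.75, 1) with 3/3/6/3/3
#' replicate populations of two animals each, each population sampled under
#' a low-concentration (30 L) and a high-concentration (6 L) regime.
#'
#' @param n_snps Number of SNPs in the panel.
#' @param alpha_A_mean,alpha_A_sd,alpha_AB_mean,alpha_AB_sd,alpha_B_mean,alpha_B_sd
#'   Normal distributions (degrees) from which per-SNP true centroid angles
#'   are drawn.
#' @param radius_meanlog,radius_sdlog Log-normal radius distribution of
#'   successful amplifications (arbitrary fluorescence units).
#' @param swab_angle_sd Replicate-level angular noise SD for swab PCRs
#'   (degrees).
#' @param edna_angle_sd Baseline angular noise SD for eDNA PCRs, scaled per
#'   regime by `regime_noise`.
#' @param regime_noise Named multipliers for `low_conc` and `high_conc`
#'   sampling regimes; low concentration is noisier.
#' @param dropout_rate Probability that a heterozygous swab sample renders
#'   at a random homozygote angle at a SNP (allelic dropout).
#' @param false_het_rate Probability that a homozygous swab sample renders
#'   at the heterozygote angle.
#' @param low_signal_rate Per-PCR probability of a low-fluorescence failure
#'   (point drawn inside the triangle).
#' @param shedding_concentration Dirichlet concentration for individual
#'   shedding weights; `Inf` means exactly equal contributions.
#' @param replicates PCR replicates per sample x SNP.
#' @param read_cycle Cycle at which simulated fluorescence is read.
#' @param n_profile_reps Named integer vector: replicate populations per
#'   profile.
#' @param n_ntc,n_lab_negative Control wells per SNP (each with
#'   `replicates` PCRs).
#' @param field_contamination_rate Per-PCR probability that a field-negative
#'   reading falls outside the triangle (contamination).
#' @param mass_meanlog,mass_sdlog Log-normal body-mass distribution (grams).
#' @param triangle Low-fluorescence triangle vertices.
#' @param seed Optional integer seed used by [simulate_experiment()].
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_snps = 9,
                       alpha_A_mean = 82.0, alpha_A_sd = 1.13,
                       alpha_AB_mean = 46.6, alpha_AB_sd = 6.05,
                       alpha_B_mean = 12.9, alpha_B_sd = 1.46,
                       radius_meanlog = log(3), radius_sdlog = 0.15,
                       swab_angle_sd = 2, edna_angle_sd = 5,
                       regime_noise = c(low_conc = 1.25, high_conc = 1),
                       dropout_rate = 0.035,
                       false_het_rate = 0.0127,
                       low_signal_rate = 0.045,
                       shedding_concentration = 5,
                       replicates = 4,
                       read_cycle = 48,
                       n_profile_reps = c("0" = 3, "0.25" = 3, "0.5" = 6,
                                          "0.75" = 3, "1" = 3),
                       n_ntc = 6, n_lab_negative = 6,
                       field_contamination_rate = 0,
                       mass_meanlog = log(10), mass_sdlog = 0.15,
                       triangle = rbind(c(0, 0), c(2, 0), c(0, 2)),
                       seed = NULL) {
  cfg <- as.list(environment())
  rate_vals <- c(dropout_rate, false_het_rate, low_signal_rate,
                 field_contamination_rate)
  if (any(rate_vals < 0 | rate_vals > 1)) stop("all rates must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

# Uniform points inside the low-fluorescence triangle (slightly shrunk so
# simulated failures are unambiguously interior).
runif_triangle <- function(n, triangle) {
  u <- stats::runif(n); v <- stats::runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
  # shrink toward the barycenter so failures are strictly interior
  u <- 1 / 3 + 0.94 * (u - 1 / 3); v <- 1 / 3 + 0.94 * (v - 1 / 3)
  a <- triangle[1, ]; b <- triangle[2, ]; d <- triangle[3, ]
  cbind(fam = a[1] + u * (b[1] - a[1]) + v * (d[1] - a[1]),
        hex = a[2] + u * (b[2] - a[2]) + v * (d[2] - a[2]))
}

polar_point <- function(alpha_deg, radius) {
  cbind(fam = radius * cos(alpha_deg * pi / 180),
        hex = radius * sin(alpha_deg * pi / 180))
}

#' Simulate a per-SNP true calibration panel
#'
#' Draws true centroid angles for each SNP from the configured normal
#' distributions, resampling any SNP violating the strict ordering
#' `alpha_B < alpha_AB < alpha_A`.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return data.frame with `snp_id`, `alpha_A`, `alpha_AB`, `alpha_B`.
#' @export
simulate_snp_panel <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_snps
  stopifnot(n >= 1)
  draw <- function(m) data.frame(
    alpha_A = stats::rnorm(m, config$alpha_A_mean, config$alpha_A_sd),
    alpha_AB = stats::rnorm(m, config$alpha_AB_mean, config$alpha_AB_sd),
    alpha_B = stats::rnorm(m, config$alpha_B_mean, config$alpha_B_sd))
  panel <- draw(n)
  bad <- which(!(panel$alpha_B < panel$alpha_AB &
                   panel$alpha_AB < panel$alpha_A))
  while (length(bad)) {
    panel[bad, ] <- draw(length(bad))
    bad <- bad[!(panel$alpha_B[bad] < panel$alpha_AB[bad] &
                   panel$alpha_AB[bad] < panel$alpha_A[bad])]
  }
  cbind(snp_id = sprintf("snp%02d", seq_len(n)), panel)
}

# Shared reading assembler: one row per PCR.
.readings_df <- function(sample_id, snp_id, replicate, fam, hex, dataset,
                         config, extra = NULL) {
  out <- data.frame(sample_id = sample_id, snp_id = snp_id,
                    fam = fam, hex = hex, replicate = replicate,
                    read_cycle = config$read_cycle, dataset = dataset)
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

#' Simulate swab validation PCRs
#'
#' Each animal x SNP x replicate reading is placed at the animal's genotype
#' angle for that SNP plus angular noise, at a log-normally drawn radius.
#' Genotyping error modes act at the sample x SNP level (they are template
#' properties shared by replicates): with probability `dropout_rate` a
#' heterozygote renders at a random homozygote angle; with probability
#' `false_het_rate` a homozygote renders at the heterozygote angle.
#' Individual PCRs fail into the low-fluorescence triangle with probability
#' `low_signal_rate`.
#'
#' @param animals data.frame with `animal_id` and `genotype` (true
#'   genotype).
#' @param panel Output of [simulate_snp_panel()].
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return Fluorescence data.frame (`dataset = "swab"`).
#' @export
simulate_swabs <- function(animals, panel, config = sim_config(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  combos <- expand.grid(animal_id = animals$animal_id,
                        snp_id = panel$snp_id,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  combos$genotype <- animals$genotype[match(combos$animal_id,
                                            animals$animal_id)]
  eff <- combos$genotype
  is_het <- eff == "AB"
  drop_mask <- is_het & stats::runif(nrow(combos)) < config$dropout_rate
  eff[drop_mask] <- sample(c("A", "B"), sum(drop_mask), replace = TRUE)
  fh_mask <- !is_het & stats::runif(nrow(combos)) < config$false_het_rate
  eff[fh_mask] <- "AB"
  prow <- match(combos$snp_id, panel$snp_id)
  alpha_true <- ifelse(eff == "A", panel$alpha_A[prow],
                       ifelse(eff == "AB", panel$alpha_AB[prow],
                              panel$alpha_B[prow]))
  R <- config$replicates
  idx <- rep(seq_len(nrow(combos)), each = R)
  n <- length(idx)
  # fluorescence is non-negative, so observable angles live in [0, 90]
  alpha <- pmin(90, pmax(0, alpha_true[idx] +
                           stats::rnorm(n, 0, config$swab_angle_sd)))
  radius <- stats::rlnorm(n, config$radius_meanlog, config$radius_sdlog)
  pts <- polar_point(alpha, radius)
  low <- stats::runif(n) < config$low_signal_rate
  if (any(low)) pts[low, ] <- runif_triangle(sum(low), config$triangle)
  .readings_df(combos$animal_id[idx], combos$snp_id[idx],
               replicate = rep(seq_len(R), nrow(combos)),
               fam = pts[, "fam"], hex = pts[, "hex"],
               dataset = "swab", config = config)
}

#' Simulate eDNA PCRs for a set of populations
#'
#' For each population x regime (one eDNA sample), individual shedding
#' weights are drawn from a Dirichlet distribution over the members and the
#' latent allele proportion is the weight-averaged member HI. Each SNP's
#' reading angle is the inverse piecewise-linear HI map evaluated at that
#' proportion, plus regime-scaled angular noise per replicate; PCRs fail
#' into the triangle with `low_signal_rate`.
#'
#' @param design Member-level design table with true genotypes in
#'   `expected_genotype` (use the truth when simulating).
#' @param panel Output of [simulate_snp_panel()].
#' @param config A [sim_config()].
#' @param regimes Regimes to sample (default both).
#' @param seed Optional integer seed.
#' @return List with `readings` (fluorescence data.frame,
#'   `dataset = "edna"`, metadata columns `population_id` and `regime`) and
#'   `truth`: per sample the profile and realized latent allele proportion.
#' @export
simulate_edna <- function(design, panel, config = sim_config(),
                          regimes = names(config$regime_noise),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- unique(design$population_id)
  truth <- list(); readings <- list()
  for (pop in pops) {
    members <- design[design$population_id == pop, , drop = FALSE]
    hi_i <- genotype_hi(members$expected_genotype)
    for (reg in regimes) {
      if (is.infinite(config$shedding_concentration)) {
        w <- rep(1 / nrow(members), nrow(members))
      } else {
        g <- stats::rgamma(nrow(members), config$shedding_concentration)
        w <- g / sum(g)
      }
      p_latent <- sum(w * hi_i)
      sid <- paste(pop, reg, sep = "_")
      truth[[sid]] <- data.frame(sample_id = sid, population_id = pop,
                                 regime = reg, profile = mean(hi_i),
                                 p_latent = p_latent)
      alpha_center <- vapply(seq_len(nrow(panel)), function(s) {
        hi_to_angle(p_latent, panel[s, ])
      }, numeric(1))
      R <- config$replicates
      n <- nrow(panel) * R
      noise_sd <- config$edna_angle_sd * config$regime_noise[[reg]]
      alpha <- pmin(90, pmax(0, rep(alpha_center, each = R) +
                               stats::rnorm(n, 0, noise_sd)))
      radius <- stats::rlnorm(n, config$radius_meanlog, config$radius_sdlog)
      pts <- polar_point(alpha, radius)
      low <- stats::runif(n) < config$low_signal_rate
      if (any(low)) pts[low, ] <- runif_triangle(sum(low), config$triangle)
      readings[[sid]] <- .readings_df(
        sample_id = sid, snp_id = rep(panel$snp_id, each = R),
        replicate = rep(seq_len(R), nrow(panel)),
        fam = pts[, "fam"], hex = pts[, "hex"], dataset = "edna",
        config = config,
        extra = data.frame(population_id = pop, regime = reg))
    }
  }
  list(readings = do.call(rbind, readings),
       truth = do.call(rbind, truth))
}

#' Simulate control PCRs
#'
#' No-template and lab-negative wells produce background points inside the
#' low-fluorescence triangle; field negatives do too unless
#' `field_contamination_rate` > 0, in which case individual PCRs escape the
#' triangle at a random angle (mimicking contamination). One positive
#' control per homozygous genotype and SNP is placed at the corresponding
#' centroid angle.
#'
#' @inheritParams simulate_swabs
#' @return Fluorescence data.frame with `ntc`, `lab_negative`,
#'   `field_negative` and `positive` rows.
#' @export
simulate_controls <- function(panel, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- config$replicates
  blocks <- list()
  bg_block <- function(ids, dataset) {
    grid <- expand.grid(sample_id = ids, snp_id = panel$snp_id,
                        replicate = seq_len(R), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    pts <- runif_triangle(nrow(grid), config$triangle)
    .readings_df(grid$sample_id, grid$snp_id, grid$replicate,
                 pts[, "fam"], pts[, "hex"], dataset, config)
  }
  if (config$n_ntc > 0) {
    blocks$ntc <- bg_block(sprintf("NTC%02d", seq_len(config$n_ntc)), "ntc")
  }
  if (config$n_lab_negative > 0) {
    blocks$lab <- bg_block(sprintf("LNEG%02d",
                                   seq_len(config$n_lab_negative)),
                           "lab_negative")
  }
  fc <- bg_block(c("FNC_low_conc", "FNC_high_conc"), "field_negative")
  contam <- stats::runif(nrow(fc)) < config$field_contamination_rate
  if (any(contam)) {
    alpha <- stats::runif(sum(contam), 5, 85)
    radius <- stats::rlnorm(sum(contam), config$radius_meanlog,
                            config$radius_sdlog)
    pts <- polar_point(alpha, radius)
    fc$fam[contam] <- pts[, "fam"]; fc$hex[contam] <- pts[, "hex"]
  }
  blocks$field <- fc
  pos <- expand.grid(sample_id = c("POS_A", "POS_B"), snp_id = panel$snp_id,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  prow <- match(pos$snp_id, panel$snp_id)
  alpha <- ifelse(pos$sample_id == "POS_A", panel$alpha_A[prow],
                  panel$alpha_B[prow])
  radius <- stats::rlnorm(nrow(pos), config$radius_meanlog,
                          config$radius_sdlog)
  pts <- polar_point(alpha, radius)
  blocks$pos <- .readings_df(pos$sample_id, pos$snp_id, 1L,
                             pts[, "fam"], pts[, "hex"], "positive", config)
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Build the study's animal set and population design
#'
#' Lays out the mesocosm design: two-animal populations in five genotypic
#' profiles with the configured replicate counts (default 3/3/6/3/3 = 18
#' populations), drawing the required number of A- and B-homozygotes and F1
#' hybrids (default 9 + 9 + 18 = 36 animals) with log-normal body masses.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (masses only).
#' @return List with `animals` (`animal_id`, `genotype`, `body_mass`) and
#'   `design` (member-level table with `profile`).
#' @export
simulate_design <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pair_for <- list("0" = c("A", "A"), "0.25" = c("A", "AB"),
                   "0.5" = c("AB", "AB"), "0.75" = c("B", "AB"),
                   "1" = c("B", "B"))
  reps <- config$n_profile_reps
  need <- table(factor(unlist(rep(pair_for[names(reps)],
                                  times = reps)),
                       levels = GENOTYPE_LEVELS))
  ids <- list(A = sprintf("TI%02d", seq_len(need[["A"]])),
              AB = sprintf("F1%02d", seq_len(need[["AB"]])),
              B = sprintf("TM%02d", seq_len(need[["B"]])))
  animals <- data.frame(
    animal_id = unlist(ids, use.names = FALSE),
    genotype = rep(GENOTYPE_LEVELS, times = vapply(ids[GENOTYPE_LEVELS],
                                                   length, integer(1))))
  animals$body_mass <- round(stats::rlnorm(nrow(animals),
                                           config$mass_meanlog,
                                           config$mass_sdlog), 2)
  pool <- split(animals$animal_id, animals$genotype)
  design <- list(); p <- 0
  for (prof in names(reps)) {
    for (r in seq_len(reps[[prof]])) {
      p <- p + 1
      members <- vapply(pair_for[[prof]], function(g) {
        a <- pool[[g]][1]; pool[[g]] <<- pool[[g]][-1]; a
      }, character(1))
      design[[p]] <- data.frame(population_id = sprintf("P%02d", p),
                                animal_id = members,
                                expected_genotype = pair_for[[prof]])
    }
  }
  design <- do.call(rbind, design)
  design$body_mass <- animals$body_mass[match(design$animal_id,
                                              animals$animal_id)]
  design <- as_design_table(design)
  list(animals = animals, design = design)
}

#' Simulate a complete experiment
#'
#' Generates the full study layout: SNP panel, animals and populations,
#' swab validation PCRs, eDNA PCRs under both sampling regimes, and all
#' controls, together with the ground-truth table. With the default
#' configuration this yields 1296 swab PCRs (36 animals x 9 SNPs x 4
#' replicates), 1296 eDNA PCRs (36 samples x 9 x 4), 72 field-negative, 432
#' lab-negative/no-template and 18 positive-control PCRs.
#'
#' @param config A [sim_config()]; its `seed` (if any) is set first.
#' @return List with `fluorescence` (all PCR rows), `design`, `animals`,
#'   `truth` (per eDNA sample: profile and realized latent proportion),
#'   `panel` (true calibration) and `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  panel <- simulate_snp_panel(config)
  layout <- simulate_design(config)
  swabs <- simulate_swabs(layout$animals, panel, config)
  edna <- simulate_edna(layout$design, panel, config)
  controls <- simulate_controls(panel, config)
  pad <- function(x) {
    x$population_id <- if ("population_id" %in% names(x)) x$population_id
      else NA_character_
    x$regime <- if ("regime" %in% names(x)) x$regime else NA_character_
    x
  }
  fluorescence <- rbind(pad(swabs), pad(edna$readings), pad(controls))
  rownames(fluorescence) <- NULL
  list(fluorescence = fluorescence, design = layout$design,
       animals = layout$animals, truth = edna$truth, panel = panel,
       config = config)
}
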