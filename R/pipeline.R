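# Pipeline orchestration: simulate -> calibrate -> estimate -> validate.
# These functions are the package's top-level surface; a thin command-line
# wrapper over them ships in inst/cli/kasphi.R.

#' Simulate an experiment and write its tables
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param delim Field delimiter for the emitted tables.
#' @return Invisibly, the paths of the written files (`fluorescence.csv`,
#'   `design.csv`, `truth.csv`, `config.txt`).
#' @export
run_simulate <- function(config = sim_config(), out_dir, delim = ",") {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  sim <- simulate_experiment(config)
  paths <- c(fluorescence = file.path(out_dir, "fluorescence.csv"),
             design = file.path(out_dir, "design.csv"),
             truth = file.path(out_dir, "truth.csv"),
             config = file.path(out_dir, "config.txt"))
  write_fluorescence_table(sim$fluorescence, paths[["fluorescence"]], delim)
  write_design_table(sim$design, paths[["design"]], delim)
  utils::write.table(sim$truth, paths[["truth"]], sep = delim,
                     row.names = FALSE, quote = FALSE)
  scalars <- Filter(function(v) is.atomic(v) && length(v) <= 2, sim$config)
  writeLines(c("# kaspHI simulation config",
               vapply(names(scalars), function(k) {
                 paste0(k, " = ", paste(scalars[[k]], collapse = ", "))
               }, character(1))),
             paths[["config"]])
  invisible(paths)
}

# Shared QC front end: cycle selection, triangle filtering, field-control
# screening, replicate averaging.
.qc_front <- function(fluorescence, config) {
  cycles <- sort(unique(fluorescence$read_cycle))
  if (length(cycles) > 1) {
    cycle <- select_read_cycle(fluorescence, cycles, config$triangle)
  } else {
    cycle <- structure(cycles, dimer_free = NULL)
  }
  at_cycle <- fluorescence[fluorescence$read_cycle == as.integer(cycle), ,
                           drop = FALSE]
  filt <- filter_low_fluorescence(at_cycle, config$triangle)
  controls <- screen_field_controls(at_cycle, config$triangle)
  avg <- average_replicates(filt$retained, original = at_cycle)
  list(cycle = as.integer(cycle), filter = filt, field_controls = controls,
       signals = avg$signals, dropped = avg$dropped)
}

#' Calibrate the SNP panel from swab data
#'
#' Runs the QC front end (read-cycle selection, low-fluorescence filtering,
#' field-control screening, replicate averaging) and then the swab-based
#' calibration sequence ([calibrate_snps()]).
#'
#' @param fluorescence Fluorescence data.frame (all datasets).
#' @param design Member-level design table.
#' @param config A [qc_config()].
#' @return List with `calibration`, `qc` (cycle, filter summary,
#'   field-control report, dropped groups), `mismatch`, `outliers`,
#'   `thresholds`, `counts` and the averaged `signals`.
#' @export
run_calibrate <- function(fluorescence, design, config = qc_config()) {
  fluorescence <- as_fluorescence_table(fluorescence)
  design <- as_design_table(design)
  qc <- .qc_front(fluorescence, config)
  swab <- qc$signals[qc$signals$dataset == "swab", , drop = FALSE]
  if (!nrow(swab)) stop("no swab signals available for calibration")
  expected <- unique(design[, c("animal_id", "expected_genotype")])
  cal <- calibrate_snps(swab, expected, design = design, config = config)
  c(cal,
    list(qc = list(cycle = qc$cycle, filter_summary = qc$filter$summary,
                   field_controls = qc$field_controls,
                   dropped = qc$dropped),
         signals = qc$signals))
}

#' Estimate hybrid indices for all samples
#'
#' Applies QC, maps every retained swab and eDNA signal's angle to the HI
#' scale with the per-SNP calibration, honors the mismatch-derived exclusion
#' propagation, and aggregates eDNA samples across SNPs.
#'
#' @param fluorescence Fluorescence data.frame.
#' @param calibration Either the result of [run_calibrate()] or a bare
#'   calibration data.frame ([centroid_angles()]).
#' @param design Member-level design table.
#' @param config A [qc_config()].
#' @param mismatch Optional [flag_mismatches()] result; taken from
#'   `calibration` when that is a [run_calibrate()] result.
#' @return List with `per_snp` (one row per retained sample x SNP with
#'   `alpha`, `hi_obs`, `hi_exp`, `deviation`) and `population` (one row per
#'   eDNA sample with the SNP-averaged `hi_obs`, `hi_exp`, `n_snps`).
#' @export
run_estimate <- function(fluorescence, calibration, design,
                         config = qc_config(), mismatch = NULL) {
  fluorescence <- as_fluorescence_table(fluorescence)
  design <- as_design_table(design)
  if (is.list(calibration) && !is.data.frame(calibration) &&
      !is.null(calibration$calibration)) {
    if (is.null(mismatch)) mismatch <- calibration$mismatch
    calibration <- calibration$calibration
  }
  qc <- .qc_front(fluorescence, config)
  sig <- qc$signals[qc$signals$dataset %in% c("swab", "edna"), , drop = FALSE]
  unknown <- setdiff(unique(sig$snp_id), calibration$snp_id)
  if (length(unknown)) {
    stop("SNP(s) present in data but absent from calibration: ",
         paste(unknown, collapse = ", "))
  }
  crow <- match(sig$snp_id, calibration$snp_id)
  sig$alpha <- angle_of(sig$fam_mean, sig$hex_mean)
  sig$hi_obs <- vapply(seq_len(nrow(sig)), function(i) {
    angle_to_hi(sig$alpha[i], calibration[crow[i], ])
  }, numeric(1))

  expected <- unique(design[, c("animal_id", "expected_genotype")])
  meta <- fluorescence[!duplicated(paste(fluorescence$sample_id,
                                         fluorescence$snp_id)),
                       intersect(c("sample_id", "snp_id", "population_id",
                                   "regime"), names(fluorescence)),
                       drop = FALSE]

  # exclusion propagation from genotype verification
  excluded_calls <- data.frame(animal_id = character(),
                               snp_id = character())
  edna_excl <- data.frame(population_id = character(), snp_id = character())
  if (!is.null(mismatch)) {
    if (nrow(mismatch$mismatches)) {
      excluded_calls <- data.frame(animal_id = mismatch$mismatches$sample_id,
                                   snp_id = mismatch$mismatches$snp_id)
    }
    if (length(mismatch$animals_excluded)) {
      excluded_calls <- rbind(excluded_calls,
                              data.frame(animal_id = mismatch$animals_excluded,
                                         snp_id = NA_character_))
    }
    edna_excl <- mismatch$edna_exclusions
  }

  # swab estimates: expected HI is the animal's own genotype contribution
  swab <- sig[sig$dataset == "swab", , drop = FALSE]
  swab <- merge(swab, expected, by.x = "sample_id", by.y = "animal_id")
  swab$hi_exp <- genotype_hi(swab$expected_genotype)
  drop_key <- paste(excluded_calls$animal_id, excluded_calls$snp_id)
  full_drop <- excluded_calls$animal_id[is.na(excluded_calls$snp_id)]
  swab_keep <- !(paste(swab$sample_id, swab$snp_id) %in% drop_key) &
    !(swab$sample_id %in% full_drop)
  swab <- swab[swab_keep, , drop = FALSE]

  # eDNA estimates: expected HI from verified member genotypes
  edna <- sig[sig$dataset == "edna", , drop = FALSE]
  if (nrow(edna)) {
    if (!"population_id" %in% names(meta)) {
      stop("eDNA rows need population_id metadata to join the design")
    }
    edna <- merge(edna, meta, by = c("sample_id", "snp_id"), all.x = TRUE)
    exp_tab <- expected_hi(design, unique(calibration$snp_id),
                           excluded = excluded_calls)
    edna <- merge(edna, exp_tab, by = c("population_id", "snp_id"),
                  all.x = TRUE)
    pop_drop <- edna_excl$population_id[is.na(edna_excl$snp_id)]
    pair_drop <- paste(edna_excl$population_id, edna_excl$snp_id)
    keep <- edna$available &
      !(edna$population_id %in% pop_drop) &
      !(paste(edna$population_id, edna$snp_id) %in% pair_drop)
    edna <- edna[keep & !is.na(keep), , drop = FALSE]
  }

  per_snp <- rbind(
    data.frame(sample_id = swab$sample_id, snp_id = swab$snp_id,
               dataset = "swab", population_id = NA_character_,
               regime = NA_character_, alpha = swab$alpha,
               hi_obs = swab$hi_obs, hi_exp = swab$hi_exp),
    if (nrow(edna)) data.frame(
      sample_id = edna$sample_id, snp_id = edna$snp_id, dataset = "edna",
      population_id = edna$population_id, regime = edna$regime,
      alpha = edna$alpha, hi_obs = edna$hi_obs, hi_exp = edna$hi_exp))
  per_snp$deviation <- per_snp$hi_obs - per_snp$hi_exp
  per_snp <- per_snp[order(per_snp$dataset, per_snp$sample_id,
                           per_snp$snp_id), ]
  rownames(per_snp) <- NULL

  pop <- NULL
  ed <- per_snp[per_snp$dataset == "edna", , drop = FALSE]
  if (nrow(ed)) {
    ids <- unique(ed$sample_id)
    pop <- do.call(rbind, lapply(ids, function(s) {
      rows <- ed[ed$sample_id == s, ]
      agg <- population_hi(rows$hi_obs)
      data.frame(sample_id = s, population_id = rows$population_id[1],
                 regime = rows$regime[1], hi_obs = agg$hi_obs,
                 hi_exp = mean(rows$hi_exp), n_snps = agg$n_snps,
                 deviation = agg$hi_obs - mean(rows$hi_exp))
    }))
    rownames(pop) <- NULL
  }
  list(per_snp = per_snp, population = pop,
       exclusions = list(calls = excluded_calls, edna = edna_excl))
}

#' Run the full validation-statistics battery
#'
#' Computes, from hybrid-index estimates: per-SNP bias with bootstrap
#' retention, Spearman concordance per regime, the permutation ANCOVA
#' `hi_obs ~ hi_exp x regime`, Kruskal-Wallis and Holm-corrected Wilcoxon
#' profile-bias tests, pairwise Fligner-Killeen variance comparisons, two
#' Bland-Altman analyses (per-regime deviations; between-regime differences
#' paired by population) and the paired biomass-correction comparison for
#' mixed-genotype profiles.
#'
#' @param estimates Result of [run_estimate()].
#' @param design Member-level design table (with `body_mass` for the
#'   biomass analysis).
#' @param config A [qc_config()] (bootstrap/permutation sizes, LoA z,
#'   seed).
#' @return List of class `"kasphi_validation"`.
#' @export
run_validate <- function(estimates, design, config = qc_config()) {
  design <- as_design_table(design)
  per_snp <- estimates$per_snp
  if (is.null(per_snp) || !nrow(per_snp)) stop("empty estimates")
  pop <- estimates$population
  swab <- per_snp[per_snp$dataset == "swab", , drop = FALSE]
  ed <- per_snp[per_snp$dataset == "edna", , drop = FALSE]
  seed <- config$seed

  bias <- if (nrow(swab)) {
    snp_bias(data.frame(snp_id = swab$snp_id, deviation = swab$deviation),
             B = config$bootstrap_reps, tol = config$bias_tolerance,
             seed = seed)
  }

  conc <- ancova <- profiles <- variance <- ba_regime <- ba_paired <-
    biomass <- NULL
  if (nrow(ed)) {
    conc <- concordance(ed$hi_obs, ed$hi_exp, ed$regime)
    if (length(unique(ed$regime)) >= 2) {
      ancova <- permutation_ancova(ed$hi_obs, ed$hi_exp, ed$regime,
                                   n_perm = config$permutations, seed = seed)
    }
    prof_lab <- population_profiles(design)
    ed$profile <- prof_lab$profile[match(ed$population_id,
                                         prof_lab$population_id)]
    profiles <- profile_bias_tests(ed$deviation, ed$profile, ed$regime)
    variance <- lapply(split(ed, ed$regime), function(part) {
      variance_homogeneity(part$deviation, part$profile)
    })
  }
  if (!is.null(pop) && nrow(pop)) {
    ba_regime <- lapply(split(pop, pop$regime), function(part) {
      bland_altman(part$deviation, z = config$loa_z)
    })
    regimes <- sort(unique(pop$regime))
    if (length(regimes) == 2) {
      a <- pop[pop$regime == "low_conc", ]
      b <- pop[pop$regime == "high_conc", ]
      common <- intersect(a$population_id, b$population_id)
      diffs <- a$hi_obs[match(common, a$population_id)] -
        b$hi_obs[match(common, b$population_id)]
      if (length(diffs) >= 2) {
        ba_paired <- bland_altman(diffs, z = config$loa_z)
      }
    }
    if ("body_mass" %in% names(design)) {
      bio <- biomass_corrected_hi(design)
      mixed <- bio$population_id[!bio$hi_exp %in% c(0, 0.5, 1)]
      part <- pop[pop$population_id %in% mixed, , drop = FALSE]
      if (nrow(part) >= 2) {
        idx <- match(part$population_id, bio$population_id)
        biomass <- biomass_effect_test(
          abs(part$hi_obs - bio$hi_exp[idx]),
          abs(part$hi_obs - bio$hi_exp_bio[idx]),
          profile = bio$hi_exp[idx])
      }
    }
  }
  structure(list(snp_bias = bias, concordance = conc, ancova = ancova,
                 profile_tests = profiles, variance = variance,
                 bland_altman_regime = ba_regime,
                 bland_altman_between = ba_paired,
                 biomass = biomass, config = config),
            class = "kasphi_validation")
}

#' @export
print.kasphi_validation <- function(x, ...) {
  cat("kaspHI validation report\n")
  if (!is.null(x$snp_bias)) {
    cat(sprintf("  SNP bias: %d/%d SNPs retained (band +/-%g HI)\n",
                sum(x$snp_bias$retained, na.rm = TRUE), nrow(x$snp_bias),
                x$config$bias_tolerance))
  }
  if (!is.null(x$concordance)) {
    for (i in seq_len(nrow(x$concordance))) {
      cat(sprintf("  Spearman (%s): rho = %.3f, p = %.3g\n",
                  x$concordance$regime[i], x$concordance$rho[i],
                  x$concordance$p_value[i]))
    }
  }
  if (!is.null(x$ancova)) {
    for (i in seq_len(nrow(x$ancova))) {
      cat(sprintf("  ANCOVA %s: F = %.2f, p = %.3g\n", x$ancova$term[i],
                  x$ancova$F[i], x$ancova$p_value[i]))
    }
  }
  if (!is.null(x$bland_altman_regime)) {
    for (r in names(x$bland_altman_regime)) {
      b <- x$bland_altman_regime[[r]]
      cat(sprintf("  Bland-Altman (%s): bias %.4f, LoA [%.3f, %.3f]\n",
                  r, b$mean_bias, b$loa_low, b$loa_high))
    }
  }
  invisible(x)
}

#' Write a validation report to delimited files
#'
#' One CSV per analysis plus a plain-text summary echoing the seed and
#' configuration.
#'
#' @param report A `"kasphi_validation"` object.
#' @param out_dir Output directory.
#' @param delim Field delimiter.
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(report, out_dir, delim = ",") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()
  put <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.table(df, p, sep = delim, row.names = FALSE, quote = FALSE)
    paths[[name]] <<- p
  }
  put(report$snp_bias, "snp_bias")
  put(report$concordance, "concordance")
  put(report$ancova, "ancova")
  if (!is.null(report$profile_tests)) {
    put(report$profile_tests$kruskal, "kruskal")
    put(report$profile_tests$wilcoxon, "wilcoxon")
  }
  if (!is.null(report$variance)) {
    vr <- do.call(rbind, lapply(names(report$variance), function(r) {
      cbind(regime = r, report$variance[[r]])
    }))
    put(vr, "variance_homogeneity")
  }
  ba_df <- function(b) data.frame(mean_bias = b$mean_bias, sd = b$sd,
                                  loa_low = b$loa_low, loa_high = b$loa_high,
                                  n = b$n)
  if (!is.null(report$bland_altman_regime)) {
    put(do.call(rbind, lapply(names(report$bland_altman_regime), function(r) {
      cbind(regime = r, ba_df(report$bland_altman_regime[[r]]))
    })), "bland_altman_regime")
  }
  if (!is.null(report$bland_altman_between)) {
    put(ba_df(report$bland_altman_between), "bland_altman_between")
  }
  put(report$biomass, "biomass_effect")
  summary_path <- file.path(out_dir, "summary.txt")
  con <- file(summary_path, "w")
  sink(con); on.exit({ sink(); close(con) })
  cat("kaspHI validation run\n")
  cat("seed:", if (is.null(report$config$seed)) "none" else
    report$config$seed, "\n")
  print(report$config)
  print(report)
  sink(); close(con); on.exit(NULL)
  paths[["summary"]] <- summary_path
  invisible(paths)
}
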