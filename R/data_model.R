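#' kaspHI: hybrid-index estimation from KASP end-point fluorescence
#'
#' Tools to turn raw FAM/HEX end-point fluorescence from Kompetitive
#' Allele-Specific PCR (KASP) assays into a hybrid index (HI), the proportion
#' of one parental species' diagnostic alleles in a sample or population.
#' The workflow is: quality control ([select_read_cycle()],
#' [filter_low_fluorescence()], [average_replicates()]), per-SNP calibration
#' from swab samples with known genotypes ([calibrate_snps()]), angle-to-HI
#' mapping ([angle_to_hi()]), aggregation ([population_hi()]), and a
#' validation-statistics battery ([run_validate()]). A simulator
#' ([simulate_experiment()]) generates synthetic swab and eDNA fluorescence
#' with the error structure the pipeline assumes.
#'
#' @keywords internal
"_PACKAGE"

# Dataset labels a fluorescence table may carry. "swab" rows are individual
# skin-swab validation PCRs, "edna" rows environmental samples; the rest are
# controls (no-template, lab water negative, field negative, per-species
# positive).
DATASET_LEVELS <- c("swab", "edna", "ntc", "lab_negative", "field_negative",
                    "positive")

GENOTYPE_LEVELS <- c("A", "AB", "B")

#' Hybrid-index contribution of a genotype
#'
#' Maps diploid genotype calls to their individual hybrid-index contribution:
#' the A homozygote (here, *T. ivanbureschi*) contributes 0, the F1
#' heterozygote 0.5, and the B homozygote (*T. macedonicus*) 1.
#'
#' @param genotype Character vector with values in `"A"`, `"AB"`, `"B"`.
#' @return Numeric vector of the same length with values in \{0, 0.5, 1\}.
#' @examples
#' genotype_hi(c("A", "AB", "B"))
#' @export
genotype_hi <- function(genotype) {
  contrib <- c(A = 0, AB = 0.5, B = 1)
  bad <- !genotype %in% names(contrib)
  if (any(bad)) {
    stop("unknown genotype value(s): ",
         paste(unique(genotype[bad]), collapse = ", "))
  }
  unname(contrib[genotype])
}

#' Quality-control and analysis configuration
#'
#' Bundles every tunable threshold of the pipeline with its default. All
#' defaults follow the calibration framework the package implements: the
#' low-fluorescence triangle with vertices (0,0), (2,0), (0,2) in (FAM, HEX)
#' space; outliers at distance >= median + 3 x MAD with the normal-consistency
#' MAD constant 1.4826; a +/-0.05 HI-unit SNP-bias retention band checked
#' against a 2000-resample bootstrap CI; 95% Bland-Altman limits of agreement
#' (z = 1.96); 5000 permutations for the permutation ANCOVA.
#'
#' @param triangle 3x2 numeric matrix of triangle vertices (FAM, HEX).
#' @param mad_multiplier Multiplier k in the outlier threshold median + k*MAD.
#' @param mad_scale_constant Consistency constant applied inside the MAD.
#' @param bias_tolerance Half-width of the SNP retention band, HI units.
#' @param bootstrap_reps Bootstrap resamples for the median-bias CI.
#' @param loa_z z-multiplier for Bland-Altman limits of agreement.
#' @param permutations Permutations for the permutation ANCOVA.
#' @param seed Optional integer seed echoed into reports.
#' @return A list of class `"qc_config"`.
#' @examples
#' cfg <- qc_config(seed = 1)
#' cfg$mad_multiplier
#' @export
qc_config <- function(triangle = rbind(c(0, 0), c(2, 0), c(0, 2)),
                      mad_multiplier = 3,
                      mad_scale_constant = 1.4826,
                      bias_tolerance = 0.05,
                      bootstrap_reps = 2000,
                      loa_z = 1.96,
                      permutations = 5000,
                      seed = NULL) {
  triangle <- as.matrix(triangle)
  if (!identical(dim(triangle), c(3L, 2L)) || !is.numeric(triangle)) {
    stop("`triangle` must be a 3x2 numeric matrix of (fam, hex) vertices")
  }
  scalars <- c(mad_multiplier = mad_multiplier,
               mad_scale_constant = mad_scale_constant,
               bias_tolerance = bias_tolerance,
               bootstrap_reps = bootstrap_reps,
               loa_z = loa_z,
               permutations = permutations)
  if (any(!is.finite(scalars)) || any(scalars <= 0)) {
    stop("all qc_config thresholds must be strictly positive and finite")
  }
  structure(list(triangle = unname(triangle),
                 mad_multiplier = mad_multiplier,
                 mad_scale_constant = mad_scale_constant,
                 bias_tolerance = bias_tolerance,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 loa_z = loa_z,
                 permutations = as.integer(permutations),
                 seed = seed),
            class = "qc_config")
}

#' @export
print.qc_config <- function(x, ...) {
  cat("kaspHI QC configuration\n")
  cat("  triangle vertices: ",
      paste(sprintf("(%g, %g)", x$triangle[, 1], x$triangle[, 2]),
            collapse = " "), "\n")
  cat(sprintf("  outlier rule: d >= median + %g x (%g x MAD)\n",
              x$mad_multiplier, x$mad_scale_constant))
  cat(sprintf("  SNP bias band: +/-%g HI units (B = %d bootstrap)\n",
              x$bias_tolerance, x$bootstrap_reps))
  cat(sprintf("  LoA z: %g; ANCOVA permutations: %d\n",
              x$loa_z, x$permutations))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

required_fluor_cols <- c("sample_id", "snp_id", "fam", "hex", "replicate",
                         "read_cycle", "dataset")

#' Read a raw fluorescence table
#'
#' Reads a delimited text file with one row per PCR reaction: sample and SNP
#' identifiers, raw FAM and HEX intensities, replicate index, the PCR cycle
#' at which fluorescence was read, and a dataset label. Extra columns (e.g.
#' `population_id`, `regime`, expected-HI metadata) are preserved untouched.
#'
#' @param path Path to a CSV/TSV file with a header.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @param col_map Optional named character vector mapping the canonical
#'   column names (`sample_id`, `snp_id`, `fam`, `hex`, `replicate`,
#'   `read_cycle`, `dataset`) to the names used in the file.
#' @return A data.frame of fluorescence readings, row count equal to the
#'   file's data rows.
#' @seealso [write_fluorescence_table()], [read_design_table()]
#' @export
read_fluorescence_table <- function(path, delim = ",", col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      idx <- match(col_map[[canon]], names(raw))
      if (!is.na(idx)) names(raw)[idx] <- canon
    }
  }
  missing_cols <- setdiff(required_fluor_cols, names(raw))
  if (length(missing_cols)) {
    stop("fluorescence table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  as_fluorescence_table(raw)
}

#' Validate and type a fluorescence data.frame
#'
#' Coerces intensity and index columns, rejecting non-numeric or negative
#' intensities with the offending row index, checking dataset labels, and
#' enforcing uniqueness of (sample, SNP, replicate, read cycle).
#'
#' @param x data.frame with at least the canonical fluorescence columns.
#' @return The validated data.frame with numeric `fam`/`hex` and integer
#'   `replicate`/`read_cycle`.
#' @export
as_fluorescence_table <- function(x) {
  missing_cols <- setdiff(required_fluor_cols, names(x))
  if (length(missing_cols)) {
    stop("fluorescence table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("fam", "hex")) {
    vals <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad)) {
      stop(sprintf("non-numeric %s intensity at row %s", col,
                   paste(bad, collapse = ", ")))
    }
    neg <- which(vals < 0)
    if (length(neg)) {
      stop(sprintf("negative %s intensity at row %s", col,
                   paste(neg, collapse = ", ")))
    }
    x[[col]] <- vals
  }
  for (col in c("replicate", "read_cycle")) {
    vals <- suppressWarnings(as.integer(x[[col]]))
    bad <- which(is.na(vals))
    if (length(bad)) {
      stop(sprintf("non-integer %s at row %s", col,
                   paste(bad, collapse = ", ")))
    }
    x[[col]] <- vals
  }
  bad_ds <- !x$dataset %in% DATASET_LEVELS
  if (any(bad_ds)) {
    stop("unknown dataset label(s): ",
         paste(unique(x$dataset[bad_ds]), collapse = ", "))
  }
  key <- paste(x$sample_id, x$snp_id, x$replicate, x$read_cycle, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (sample_id, snp_id, replicate, read_cycle) at row ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  rownames(x) <- NULL
  x
}

#' Write a fluorescence table
#'
#' @param x Fluorescence data.frame.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_fluorescence_table <- function(x, path, delim = ",") {
  utils::write.table(x, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a population design table
#'
#' Reads the member-level experimental design: one row per animal with its
#' population (container) assignment, the genotype expected from collection
#' records, and body mass. The population's genotypic profile (expected HI)
#' is recomputed as the mean of the members' genotype contributions; if the
#' file carries a stated `profile` column it is cross-checked against the
#' recomputed value.
#'
#' @param path Path to a CSV/TSV file with header columns `population_id`,
#'   `animal_id`, `expected_genotype`, and optionally `body_mass`, `profile`.
#' @param delim Field delimiter.
#' @return A data.frame of members with a recomputed `profile` column.
#' @export
read_design_table <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = delim,
                         stringsAsFactors = FALSE, check.names = FALSE)
  as_design_table(x)
}

#' Validate a design data.frame
#'
#' @param x data.frame with `population_id`, `animal_id`,
#'   `expected_genotype`, optional `body_mass` and stated `profile`.
#' @return The validated data.frame with `profile` recomputed per population.
#' @export
as_design_table <- function(x) {
  req <- c("population_id", "animal_id", "expected_genotype")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("design table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- !x$expected_genotype %in% GENOTYPE_LEVELS
  if (any(bad)) {
    stop("unknown expected_genotype value(s): ",
         paste(unique(x$expected_genotype[bad]), collapse = ", "))
  }
  if (!nrow(x)) stop("design table has no members")
  contrib <- genotype_hi(x$expected_genotype)
  recomputed <- stats::ave(contrib, x$population_id)
  if ("profile" %in% names(x)) {
    stated <- as.numeric(x$profile)
    off <- abs(stated - recomputed) > 1e-9
    if (any(off, na.rm = TRUE)) {
      bad_pops <- unique(x$population_id[which(off)])
      stop("stated profile disagrees with member genotypes for population(s): ",
           paste(bad_pops, collapse = ", "))
    }
  }
  x$profile <- recomputed
  rownames(x) <- NULL
  x
}

#' Write a design table
#'
#' @inheritParams write_fluorescence_table
#' @export
write_design_table <- function(x, path, delim = ",") {
  utils::write.table(x, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-population genotypic profiles
#'
#' Collapses a member-level design table to one row per population with its
#' member count and expected HI profile.
#'
#' @param design Design data.frame (see [read_design_table()]).
#' @return data.frame with `population_id`, `n_members`, `profile`.
#' @export
population_profiles <- function(design) {
  design <- as_design_table(design)
  agg <- stats::aggregate(
    list(profile = genotype_hi(design$expected_genotype)),
    by = list(population_id = design$population_id), FUN = mean)
  n <- stats::aggregate(list(n_members = design$animal_id),
                        by = list(population_id = design$population_id),
                        FUN = length)
  out <- merge(agg, n, by = "population_id")
  out[order(out$population_id), c("population_id", "n_members", "profile")]
}
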