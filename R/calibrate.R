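# Per-SNP calibration from swab samples with genotypes known from collection
# records: genotype centroids (component-wise medians), nearest-centroid
# genotype verification, robust median+MAD outlier exclusion, and centroid
# angles that anchor the angle-to-HI map.

#' Genotype-cluster centroids per SNP
#'
#' For each SNP and expected genotype class, the centroid is the
#' component-wise median (median FAM, median HEX) of the averaged signals of
#' all swab samples with that expected genotype. Marginal medians are the
#' robust reading of "median fluorescence"; the geometric median is not used.
#'
#' @param signals Averaged-signal data.frame (`sample_id`, `snp_id`,
#'   `fam_mean`, `hex_mean`) for swab samples.
#' @param expected data.frame mapping `animal_id` to `expected_genotype`
#'   (`"A"`, `"AB"`, `"B"`); `sample_id` in `signals` must match
#'   `animal_id`.
#' @param require_all_classes If `TRUE` (default) every SNP must have at
#'   least one sample in each genotype class.
#' @return data.frame with `snp_id`, `genotype`, `fam`, `hex`, `n`.
#' @export
compute_centroids <- function(signals, expected, require_all_classes = TRUE) {
  x <- merge(signals, expected[, c("animal_id", "expected_genotype")],
             by.x = "sample_id", by.y = "animal_id")
  if (!nrow(x)) stop("no swab signals match the expected-genotype table")
  cent <- stats::aggregate(
    cbind(fam = x$fam_mean, hex = x$hex_mean),
    by = list(snp_id = x$snp_id, genotype = x$expected_genotype),
    FUN = stats::median)
  n <- stats::aggregate(list(n = x$fam_mean),
                        by = list(snp_id = x$snp_id,
                                  genotype = x$expected_genotype),
                        FUN = length)
  cent <- merge(cent, n, by = c("snp_id", "genotype"))
  if (require_all_classes) {
    tab <- table(cent$snp_id)
    for (snp in names(tab)) {
      have <- cent$genotype[cent$snp_id == snp]
      miss <- setdiff(GENOTYPE_LEVELS, have)
      if (length(miss)) {
        stop(sprintf("SNP %s has no samples for genotype class %s",
                     snp, paste(miss, collapse = ", ")))
      }
    }
  }
  cent[order(cent$snp_id, cent$genotype), ]
}

euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

#' Flag genotype mismatches by nearest centroid
#'
#' Verifies each swab sample x SNP call against the calibration clusters:
#' the call is flagged as a mismatched genotype when its averaged signal is
#' closer to a centroid other than the one expected from collection records
#' (distance ties count as mismatches, since an ambiguous call cannot
#' validate anything). Flagged calls are excluded together with the eDNA
#' calls at that SNP for every population housing that animal; an animal
#' mismatched at every evaluated SNP is excluded entirely, along with all
#' eDNA samples from its containers.
#'
#' @param signals Averaged swab signals.
#' @param expected `animal_id` -> `expected_genotype` map.
#' @param centroids Output of [compute_centroids()].
#' @param design Optional member-level design table linking animals to
#'   populations, used to derive the eDNA exclusion set.
#' @return List with `calls` (all evaluated calls with distances, nearest
#'   centroid and `flagged`), `mismatches` (flagged subset),
#'   `animals_excluded` (animals mismatched at all evaluated SNPs), and
#'   `edna_exclusions` (data.frame `population_id`, `snp_id`; `snp_id` `NA`
#'   means the whole population is excluded).
#' @export
flag_mismatches <- function(signals, expected, centroids, design = NULL) {
  x <- merge(signals, expected[, c("animal_id", "expected_genotype")],
             by.x = "sample_id", by.y = "animal_id")
  wide <- stats::reshape(
    centroids[, c("snp_id", "genotype", "fam", "hex")],
    idvar = "snp_id", timevar = "genotype", direction = "wide")
  x <- merge(x, wide, by = "snp_id")
  d <- cbind(A  = euclid(x$fam_mean, x$hex_mean, x$fam.A,  x$hex.A),
             AB = euclid(x$fam_mean, x$hex_mean, x$fam.AB, x$hex.AB),
             B  = euclid(x$fam_mean, x$hex_mean, x$fam.B,  x$hex.B))
  own <- d[cbind(seq_len(nrow(d)), match(x$expected_genotype, colnames(d)))]
  nearest_idx <- max.col(-d, ties.method = "first")
  nearest <- colnames(d)[nearest_idx]
  nearest_dist <- d[cbind(seq_len(nrow(d)), nearest_idx)]
  # a distance tie at the minimum is ambiguous and treated as a mismatch
  tie <- rowSums(abs(d - nearest_dist) < 1e-12) > 1
  flagged <- nearest != x$expected_genotype | tie
  calls <- data.frame(sample_id = x$sample_id, snp_id = x$snp_id,
                      expected_genotype = x$expected_genotype,
                      fam_mean = x$fam_mean, hex_mean = x$hex_mean,
                      own_dist = own, nearest_genotype = nearest,
                      nearest_dist = nearest_dist, flagged = flagged)
  calls <- calls[order(calls$sample_id, calls$snp_id), ]
  rownames(calls) <- NULL
  mism <- calls[calls$flagged, , drop = FALSE]
  n_eval <- table(calls$sample_id)
  n_flag <- table(factor(mism$sample_id, levels = names(n_eval)))
  animals_excluded <- names(n_eval)[n_flag == n_eval & n_eval > 0]
  edna_exclusions <- data.frame(population_id = character(),
                                snp_id = character())
  if (!is.null(design) && nrow(mism)) {
    pops_of <- function(a) {
      unique(design$population_id[design$animal_id == a])
    }
    rows <- do.call(rbind, lapply(seq_len(nrow(mism)), function(i) {
      pops <- pops_of(mism$sample_id[i])
      if (!length(pops)) return(NULL)
      data.frame(population_id = pops, snp_id = mism$snp_id[i])
    }))
    full <- do.call(rbind, lapply(animals_excluded, function(a) {
      pops <- pops_of(a)
      if (!length(pops)) return(NULL)
      data.frame(population_id = pops, snp_id = NA_character_)
    }))
    edna_exclusions <- unique(rbind(rows, full))
    if (is.null(edna_exclusions)) {
      edna_exclusions <- data.frame(population_id = character(),
                                    snp_id = character())
    }
    rownames(edna_exclusions) <- NULL
  }
  list(calls = calls, mismatches = mism,
       animals_excluded = animals_excluded,
       edna_exclusions = edna_exclusions)
}

#' Robust outlier exclusion within genotype clusters
#'
#' Within each (SNP, genotype) cluster of mismatch-cleaned swab signals,
#' distances to the assigned centroid are screened with the robust rule
#' d >= median(d) + k x MAD(d), where MAD(d) = c x median(|d - median(d)|)
#' (default c = 1.4826, the normal-consistency constant, and k = 3).
#' Degenerate clusters with MAD = 0 would void themselves under the literal
#' ">=", so there only points strictly above the median are excluded.
#'
#' @param signals Averaged swab signals after mismatch removal.
#' @param expected `animal_id` -> `expected_genotype` map.
#' @param centroids Cluster centroids ([compute_centroids()]).
#' @param k Multiplier on the MAD (default 3).
#' @param c Consistency constant inside the MAD (default 1.4826).
#' @return List with `retained`, `outliers` (each row carries its distance
#'   and the cluster threshold) and `thresholds`, one row per cluster with
#'   its median distance, MAD and cutoff.
#' @export
exclude_outliers <- function(signals, expected, centroids, k = 3,
                             c = 1.4826) {
  x <- merge(signals, expected[, c("animal_id", "expected_genotype")],
             by.x = "sample_id", by.y = "animal_id")
  x <- merge(x, centroids, by.x = c("snp_id", "expected_genotype"),
             by.y = c("snp_id", "genotype"))
  x$dist <- euclid(x$fam_mean, x$hex_mean, x$fam, x$hex)
  key <- paste(x$snp_id, x$expected_genotype, sep = "\r")
  x$outlier <- FALSE
  x$threshold <- NA_real_
  thr_rows <- list()
  for (g in unique(key)) {
    idx <- which(key == g)
    d <- x$dist[idx]
    med <- stats::median(d)
    mad_raw <- stats::median(abs(d - med))
    mad <- c * mad_raw
    threshold <- med + k * mad
    if (length(d) < 2) {
      warning("cluster ", sub("\r", "/", g),
              " has a single point; no outlier screening")
      out <- rep(FALSE, length(d))
    } else if (mad == 0) {
      out <- d > med
    } else {
      out <- d >= threshold
    }
    x$outlier[idx] <- out
    x$threshold[idx] <- threshold
    thr_rows[[g]] <- data.frame(snp_id = x$snp_id[idx[1]],
                                genotype = x$expected_genotype[idx[1]],
                                n = length(d), median_dist = med,
                                mad = mad, threshold = threshold)
  }
  thresholds <- do.call(rbind, thr_rows)
  rownames(thresholds) <- NULL
  keep_cols <- c("sample_id", "snp_id", "expected_genotype", "fam_mean",
                 "hex_mean", "dataset", "n_replicates", "dist", "threshold")
  keep_cols <- intersect(keep_cols, names(x))
  list(retained = x[!x$outlier, keep_cols],
       outliers = x[x$outlier, keep_cols],
       thresholds = thresholds)
}

#' Angle of a point from the origin of the FAM-HEX plane
#'
#' Angles are measured from the origin with 0 degrees along the FAM axis and
#' 90 degrees along the HEX axis. A pure B-allele (FAM-only) signal sits at
#' 0, a pure A-allele (HEX-only) signal at 90.
#'
#' @param fam,hex Numeric vectors; the origin itself is rejected.
#' @return Angles in degrees.
#' @examples
#' angle_of(1, 1)  # 45
#' @export
angle_of <- function(fam, hex) {
  bad <- fam == 0 & hex == 0
  if (any(bad)) {
    stop("angle undefined at the origin (fam = hex = 0), element ",
         paste(which(bad), collapse = ", "))
  }
  atan2(hex, fam) * 180 / pi
}

#' Centroid angles and per-SNP calibration
#'
#' Converts final (post-outlier-removal) genotype centroids to their angles
#' alpha_A, alpha_AB, alpha_B and assembles the per-SNP calibration used by
#' [angle_to_hi()]. The angles must be strictly ordered
#' alpha_B < alpha_AB < alpha_A; a violation means the clusters are not
#' separable on the angular axis and the SNP is unusable.
#'
#' @param centroids Centroid data.frame ([compute_centroids()]), ideally
#'   recomputed from the retained points after outlier exclusion.
#' @return data.frame of class `"snp_calibration"` with one row per SNP:
#'   centroid coordinates, counts and angles.
#' @export
centroid_angles <- function(centroids) {
  wide <- stats::reshape(centroids, idvar = "snp_id", timevar = "genotype",
                         direction = "wide")
  for (g in GENOTYPE_LEVELS) {
    fcol <- paste0("fam.", g); hcol <- paste0("hex.", g)
    if (!all(c(fcol, hcol) %in% names(wide))) {
      stop("missing centroid for genotype class ", g)
    }
    wide[[paste0("alpha_", g)]] <- angle_of(wide[[fcol]], wide[[hcol]])
  }
  bad <- !(wide$alpha_B < wide$alpha_AB & wide$alpha_AB < wide$alpha_A)
  if (any(bad)) {
    stop("centroid angle ordering alpha_B < alpha_AB < alpha_A violated ",
         "for SNP(s): ", paste(wide$snp_id[bad], collapse = ", "))
  }
  names(wide) <- sub("^n\\.", "n_points_", names(wide))
  rownames(wide) <- NULL
  class(wide) <- c("snp_calibration", "data.frame")
  wide
}

#' Full swab-based calibration pipeline
#'
#' Runs the calibration sequence on averaged swab signals: (1) provisional
#' centroids from expected genotypes; (2) nearest-centroid genotype
#' verification with mismatch flagging and linked eDNA exclusions; (3)
#' median+MAD outlier screening on the mismatch-cleaned clusters; (4)
#' centroid recomputation from the retained points and angle extraction.
#' Mismatch flagging deliberately uses the pre-exclusion centroids, and
#' outliers are accounted separately from mismatches.
#'
#' @param signals Averaged swab signals ([average_replicates()]).
#' @param expected `animal_id` -> `expected_genotype` map.
#' @param design Optional design table for eDNA exclusion propagation.
#' @param config A [qc_config()].
#' @return List with `calibration` (per-SNP angles), `centroids_initial`,
#'   `centroids_final`, `mismatch` (the [flag_mismatches()] result),
#'   `outliers`, `thresholds`, and `counts`, a one-row summary.
#' @export
calibrate_snps <- function(signals, expected, design = NULL,
                           config = qc_config()) {
  cent0 <- compute_centroids(signals, expected)
  mm <- flag_mismatches(signals, expected, cent0, design = design)
  flagged_key <- paste(mm$mismatches$sample_id, mm$mismatches$snp_id)
  clean <- signals[!paste(signals$sample_id, signals$snp_id) %in% flagged_key &
                     !signals$sample_id %in% mm$animals_excluded, ,
                   drop = FALSE]
  out <- exclude_outliers(clean, expected, cent0,
                          k = config$mad_multiplier,
                          c = config$mad_scale_constant)
  kept <- out$retained
  cent1 <- compute_centroids(
    kept[, c("sample_id", "snp_id", "fam_mean", "hex_mean")], expected)
  calibration <- centroid_angles(cent1)
  counts <- data.frame(
    n_calls = nrow(mm$calls),
    n_mismatches = nrow(mm$mismatches),
    n_animals_excluded = length(mm$animals_excluded),
    n_outliers = nrow(out$outliers),
    n_retained = nrow(kept),
    mean_points_per_centroid = mean(cent1$n))
  list(calibration = calibration, centroids_initial = cent0,
       centroids_final = cent1, mismatch = mm,
       outliers = out$outliers, thresholds = out$thresholds,
       counts = counts)
}
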