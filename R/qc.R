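# Quality control: read-cycle selection against controls, low-fluorescence
# triangle filtering, field-control screening, replicate averaging.

#' Triangle membership in (FAM, HEX) space
#'
#' Tests whether points fall within a triangle, boundary inclusive. The
#' default analysis triangle (vertices (0,0), (2,0), (0,2)) delimits the
#' low-fluorescence region dominated by background noise and failed
#' amplifications; an inclusive boundary is the conservative reading of a
#' noise floor.
#'
#' @param fam,hex Numeric vectors of channel intensities.
#' @param triangle 3x2 numeric matrix of vertices.
#' @return Logical vector, `TRUE` where (fam, hex) lies inside or on the
#'   triangle.
#' @examples
#' in_triangle(c(0.5, 3, 1), c(0.5, 0.1, 1))
#' @export
in_triangle <- function(fam, hex, triangle = rbind(c(0, 0), c(2, 0), c(0, 2))) {
  triangle <- as.matrix(triangle)
  stopifnot(identical(dim(triangle), c(3L, 2L)))
  v1 <- triangle[1, ]; v2 <- triangle[2, ]; v3 <- triangle[3, ]
  det3 <- function(a, b, px, py) (b[1] - a[1]) * (py - a[2]) -
    (b[2] - a[2]) * (px - a[1])
  area <- det3(v1, v2, v3[1], v3[2])
  if (abs(area) < .Machine$double.eps) stop("degenerate triangle vertices")
  eps <- 1e-12 * max(1, abs(area))
  d1 <- det3(v1, v2, fam, hex)
  d2 <- det3(v2, v3, fam, hex)
  d3 <- det3(v3, v1, fam, hex)
  if (area < 0) { d1 <- -d1; d2 <- -d2; d3 <- -d3 }
  d1 >= -eps & d2 >= -eps & d3 >= -eps
}

#' Select the analysis read cycle from control wells
#'
#' End-point fluorescence is read at several cycle counts; excessive cycling
#' promotes primer-dimer fluorescence in template-free wells. The rule keeps
#' the largest candidate cycle at which no NTC or lab-negative reading falls
#' outside the low-fluorescence triangle (the only quantitative noise region
#' the framework defines, used here as the dimer proxy). If controls show
#' signal at every candidate cycle, the smallest is returned with a warning.
#'
#' @param readings Fluorescence data.frame covering the candidate cycles.
#' @param candidate_cycles Integer vector of cycles to consider; defaults to
#'   the cycles present in the control readings.
#' @param triangle Low-fluorescence triangle vertices.
#' @return The chosen cycle (integer), with attribute `"dimer_free"`: a named
#'   logical over the candidate cycles.
#' @export
select_read_cycle <- function(readings, candidate_cycles = NULL,
                              triangle = rbind(c(0, 0), c(2, 0), c(0, 2))) {
  ctrl <- readings[readings$dataset %in% c("ntc", "lab_negative"), ,
                   drop = FALSE]
  if (!nrow(ctrl)) stop("cycle selection impossible without controls")
  if (is.null(candidate_cycles)) {
    candidate_cycles <- sort(unique(ctrl$read_cycle))
  }
  candidate_cycles <- sort(as.integer(candidate_cycles))
  if (!length(candidate_cycles)) stop("no candidate cycles supplied")
  dimer_free <- vapply(candidate_cycles, function(cy) {
    at <- ctrl[ctrl$read_cycle == cy, , drop = FALSE]
    if (!nrow(at)) return(NA)
    !any(!in_triangle(at$fam, at$hex, triangle))
  }, logical(1))
  names(dimer_free) <- candidate_cycles
  if (all(is.na(dimer_free))) {
    stop("cycle selection impossible without controls")
  }
  ok <- which(!is.na(dimer_free) & dimer_free)
  if (length(ok)) {
    chosen <- max(candidate_cycles[ok])
  } else {
    chosen <- min(candidate_cycles)
    warning("controls show signal outside the low-fluorescence region at ",
            "every candidate cycle; falling back to cycle ", chosen)
  }
  structure(chosen, dimer_free = dimer_free)
}

#' Exclude low-fluorescence reactions
#'
#' Partitions readings into those outside the low-fluorescence triangle
#' (retained) and those inside or on its boundary (excluded as background
#' noise / failed amplification).
#'
#' @param readings Fluorescence data.frame.
#' @param triangle 3x2 matrix of triangle vertices.
#' @return List with `retained`, `excluded` (both data.frames partitioning
#'   the input) and `summary`: per-dataset counts of input/retained/excluded.
#' @export
filter_low_fluorescence <- function(readings,
                                    triangle = rbind(c(0, 0), c(2, 0),
                                                     c(0, 2))) {
  low <- in_triangle(readings$fam, readings$hex, triangle)
  retained <- readings[!low, , drop = FALSE]
  excluded <- readings[low, , drop = FALSE]
  datasets <- unique(readings$dataset)
  summary <- data.frame(
    dataset = datasets,
    n_input = vapply(datasets, function(d) sum(readings$dataset == d),
                     integer(1)),
    n_excluded = vapply(datasets, function(d) sum(excluded$dataset == d),
                        integer(1))
  )
  summary$n_retained <- summary$n_input - summary$n_excluded
  summary$frac_excluded <- summary$n_excluded / summary$n_input
  rownames(summary) <- NULL
  list(retained = retained, excluded = excluded, summary = summary)
}

#' Screen negative field controls for contamination
#'
#' Field controls (animal-free containers sampled and filtered like the real
#' samples) should show no fluorescence outside the low-fluorescence region.
#' Any field-control PCR outside the triangle flags that control as possibly
#' contaminated; this is a warning-level report and does not interrupt the
#' pipeline.
#'
#' @param readings Fluorescence data.frame (only `field_negative` rows are
#'   examined).
#' @param triangle Triangle vertices.
#' @return List with `by_sample` (per-control counts, fractions and a
#'   `flagged` column), `by_snp` (per control x SNP breakdown) and
#'   `flagged`, the IDs of controls with at least one out-of-triangle PCR.
#' @export
screen_field_controls <- function(readings,
                                  triangle = rbind(c(0, 0), c(2, 0),
                                                   c(0, 2))) {
  fc <- readings[readings$dataset == "field_negative", , drop = FALSE]
  if (!nrow(fc)) {
    empty <- data.frame(sample_id = character(), n_pcr = integer(),
                        n_outside = integer(), fraction = numeric(),
                        flagged = logical())
    return(list(by_sample = empty,
                by_snp = data.frame(sample_id = character(),
                                    snp_id = character(), n_pcr = integer(),
                                    n_outside = integer()),
                flagged = character()))
  }
  fc$outside <- !in_triangle(fc$fam, fc$hex, triangle)
  by_snp <- stats::aggregate(
    cbind(n_pcr = rep(1L, nrow(fc)), n_outside = as.integer(fc$outside)),
    by = list(sample_id = fc$sample_id, snp_id = fc$snp_id), FUN = sum)
  by_sample <- stats::aggregate(
    cbind(n_pcr = rep(1L, nrow(fc)), n_outside = as.integer(fc$outside)),
    by = list(sample_id = fc$sample_id), FUN = sum)
  by_sample$fraction <- by_sample$n_outside / by_sample$n_pcr
  by_sample$flagged <- by_sample$n_outside >= 1L
  list(by_sample = by_sample, by_snp = by_snp,
       flagged = by_sample$sample_id[by_sample$flagged])
}

#' Average retained PCR replicates per sample and SNP
#'
#' Reduces stochastic variation by averaging the FAM and HEX intensities of
#' the retained replicates of each sample x SNP combination (arithmetic
#' mean). Groups whose replicates were all excluded upstream yield no
#' averaged signal; pass the pre-filter readings via `original` to have them
#' listed as dropped.
#'
#' @param retained Fluorescence data.frame after low-fluorescence filtering.
#' @param original Optional pre-filter data.frame used to report groups that
#'   lost all replicates.
#' @return List with `signals`: one row per (sample_id, snp_id, dataset) with
#'   `fam_mean`, `hex_mean`, `n_replicates`; and `dropped`: groups present in
#'   `original` but absent from `signals`.
#' @export
average_replicates <- function(retained, original = NULL) {
  group_key <- function(x) paste(x$sample_id, x$snp_id, x$dataset, sep = "\r")
  if (nrow(retained)) {
    signals <- stats::aggregate(
      cbind(fam_mean = retained$fam, hex_mean = retained$hex),
      by = list(sample_id = retained$sample_id, snp_id = retained$snp_id,
                dataset = retained$dataset),
      FUN = mean)
    n <- stats::aggregate(list(n_replicates = retained$fam),
                          by = list(sample_id = retained$sample_id,
                                    snp_id = retained$snp_id,
                                    dataset = retained$dataset),
                          FUN = length)
    signals <- merge(signals, n,
                     by = c("sample_id", "snp_id", "dataset"), sort = TRUE)
  } else {
    signals <- data.frame(sample_id = character(), snp_id = character(),
                          dataset = character(), fam_mean = numeric(),
                          hex_mean = numeric(), n_replicates = integer())
  }
  dropped <- NULL
  if (!is.null(original)) {
    groups <- unique(original[, c("sample_id", "snp_id", "dataset")])
    dropped <- groups[!group_key(groups) %in% group_key(signals), ,
                      drop = FALSE]
    rownames(dropped) <- NULL
  }
  list(signals = signals, dropped = dropped)
}
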