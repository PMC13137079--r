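# In-code fixtures shared across test files.

# One fluorescence reading row.
fl <- function(sample, snp, fam, hex, rep = 1L, cycle = 48L,
               dataset = "swab") {
  data.frame(sample_id = sample, snp_id = snp, fam = fam, hex = hex,
             replicate = as.integer(rep), read_cycle = as.integer(cycle),
             dataset = dataset)
}

fl_tab <- function(...) do.call(rbind, list(...))

# A tidy averaged-signal table.
sig <- function(sample, snp, fam, hex, n = 4L, dataset = "swab") {
  data.frame(sample_id = sample, snp_id = snp, fam_mean = fam,
             hex_mean = hex, n_replicates = as.integer(n),
             dataset = dataset)
}

# Minimal well-separated three-cluster swab layout for one SNP: n points per
# genotype at the given angles (degrees), radius 3, optional jitter.
swab_cluster_signals <- function(snp = "s1", n = 5,
                                 angles = c(A = 82, AB = 46, B = 13),
                                 jitter = 0, seed = 1) {
  set.seed(seed)
  rows <- lapply(names(angles), function(g) {
    a <- angles[[g]] + stats::runif(n, -jitter, jitter)
    data.frame(sample_id = sprintf("%s%02d", g, seq_len(n)),
               snp_id = snp,
               fam_mean = 3 * cos(a * pi / 180),
               hex_mean = 3 * sin(a * pi / 180),
               n_replicates = 4L, dataset = "swab",
               expected = g)
  })
  out <- do.call(rbind, rows)
  list(signals = out[, c("sample_id", "snp_id", "fam_mean", "hex_mean",
                         "n_replicates", "dataset")],
       expected = data.frame(animal_id = out$sample_id,
                             expected_genotype = out$expected))
}

# A valid random calibration (alpha_B < alpha_AB < alpha_A).
random_calibration <- function() {
  a <- sort(stats::runif(3, 1, 89))
  data.frame(alpha_A = a[3], alpha_AB = a[2], alpha_B = a[1])
}
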