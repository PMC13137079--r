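test_that("simulators are bit-reproducible under a fixed seed", {
  cfg <- sim_config()
  expect_identical(simulate_snp_panel(cfg, seed = 42),
                   simulate_snp_panel(cfg, seed = 42))
  expect_identical(simulate_experiment(sim_config(seed = 9)),
                   simulate_experiment(sim_config(seed = 9)))
})

test_that("degenerate angle SDs collapse the panel onto the configured means", {
  cfg <- sim_config(alpha_A_sd = 0, alpha_AB_sd = 0, alpha_B_sd = 0)
  panel <- simulate_snp_panel(cfg, seed = 1)
  expect_equal(panel$alpha_A, rep(82.0, 9))
  expect_equal(panel$alpha_AB, rep(46.6, 9))
  expect_equal(panel$alpha_B, rep(12.9, 9))
})

test_that("panel angle draws have the configured mean (law of large numbers)", {
  cfg <- sim_config(n_snps = 10000)
  panel <- simulate_snp_panel(cfg, seed = 123)
  se <- 1.13 / sqrt(10000)
  expect_lt(abs(mean(panel$alpha_A) - 82.0), 3 * se)
  expect_true(all(panel$alpha_B < panel$alpha_AB &
                    panel$alpha_AB < panel$alpha_A))
})

test_that("the default layout reproduces the study design counts", {
  sim <- simulate_experiment(sim_config(seed = 4))
  expect_equal(nrow(sim$animals), 36)
  expect_equal(sum(sim$animals$genotype == "A"), 9)
  expect_equal(sum(sim$animals$genotype == "AB"), 18)
  expect_equal(sum(sim$animals$genotype == "B"), 9)
  expect_equal(length(unique(sim$design$population_id)), 18)
  expect_equal(nrow(sim$truth), 36)  # 18 populations x 2 regimes
  counts <- table(sim$fluorescence$dataset)
  expect_equal(unname(counts[["swab"]]), 36 * 9 * 4)
  expect_equal(unname(counts[["edna"]]), 36 * 9 * 4)
  expect_equal(unname(counts[["field_negative"]]), 72)
  expect_equal(unname(counts[["ntc"]]) + unname(counts[["lab_negative"]]),
               432)
  expect_equal(unname(counts[["positive"]]), 18)
  expect_equal(nrow(sim$fluorescence), 3114)
  expect_true(all(sim$truth$profile %in% c(0, 0.25, 0.5, 0.75, 1)))
})

test_that("noiseless swabs sit exactly at their genotype angles and calibrate cleanly", {
  cfg <- sim_config(swab_angle_sd = 0, dropout_rate = 0, false_het_rate = 0,
                    low_signal_rate = 0, seed = 2)
  sim <- simulate_experiment(cfg)
  swab <- sim$fluorescence[sim$fluorescence$dataset == "swab", ]
  a <- angle_of(swab$fam, swab$hex)
  geno <- sim$animals$genotype[match(swab$sample_id, sim$animals$animal_id)]
  prow <- match(swab$snp_id, sim$panel$snp_id)
  truth_angle <- ifelse(geno == "A", sim$panel$alpha_A[prow],
                        ifelse(geno == "AB", sim$panel$alpha_AB[prow],
                               sim$panel$alpha_B[prow]))
  expect_equal(a, truth_angle, tolerance = 1e-10)

  cal <- run_calibrate(sim$fluorescence, sim$design)
  expect_equal(cal$counts$n_mismatches, 0)
})

test_that("certain dropout turns every heterozygote into a downstream mismatch", {
  cfg <- sim_config(swab_angle_sd = 0, dropout_rate = 1, false_het_rate = 0,
                    low_signal_rate = 0, seed = 3)
  sim <- simulate_experiment(cfg)
  swab <- sim$fluorescence[sim$fluorescence$dataset == "swab", ]
  het <- sim$animals$animal_id[sim$animals$genotype == "AB"]
  a <- angle_of(swab$fam, swab$hex)
  prow <- match(swab$snp_id, sim$panel$snp_id)
  is_het_row <- swab$sample_id %in% het
  # every heterozygote reading renders at one of the homozygote angles
  at_hom <- abs(a - sim$panel$alpha_A[prow]) < 1e-8 |
    abs(a - sim$panel$alpha_B[prow]) < 1e-8
  expect_true(all(at_hom[is_het_row]))
})

test_that("eDNA latent proportions follow the shedding weights", {
  design <- data.frame(population_id = c("P1", "P1"),
                       animal_id = c("a1", "h1"),
                       expected_genotype = c("A", "AB"))
  panel <- simulate_snp_panel(sim_config(n_snps = 3), seed = 10)
  cfg0 <- sim_config(n_snps = 3, edna_angle_sd = 0, low_signal_rate = 0,
                     shedding_concentration = Inf)
  out <- simulate_edna(design, panel, cfg0, seed = 11)
  expect_equal(out$truth$p_latent, rep(0.25, 2))  # symmetric weights

  # strongly concentrated weights push p toward the dominant member's HI;
  # here realized p must stay within [0, 0.5], around 0.25 on average
  cfg1 <- sim_config(n_snps = 3, edna_angle_sd = 0, low_signal_rate = 0,
                     shedding_concentration = 0.2)
  many <- do.call(rbind, lapply(1:50, function(k) {
    transform(design, population_id = sprintf("P%02d", k),
              animal_id = paste0(animal_id, k))
  }))
  out1 <- simulate_edna(many, panel, cfg1, seed = 12)
  expect_true(all(out1$truth$p_latent >= 0 & out1$truth$p_latent <= 0.5))
  expect_gt(stats::sd(out1$truth$p_latent), 0.1)  # far from the equal-weight point
})

test_that("noiseless end-to-end recovery is exact", {
  cfg <- sim_config(swab_angle_sd = 0, edna_angle_sd = 0, dropout_rate = 0,
                    false_het_rate = 0, low_signal_rate = 0,
                    shedding_concentration = Inf, seed = 21)
  sim <- simulate_experiment(cfg)
  cal <- run_calibrate(sim$fluorescence, sim$design)
  est <- run_estimate(sim$fluorescence, cal, sim$design)
  m <- merge(est$population, sim$truth[, c("sample_id", "profile")],
             by = "sample_id")
  expect_equal(m$hi_obs, m$profile, tolerance = 1e-9)
})
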