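test_that("SNP bias retention follows the bootstrap CI band", {
  zeros <- data.frame(snp_id = "s1", deviation = rep(0, 20))
  out <- snp_bias(zeros, B = 200, seed = 1)
  expect_equal(out$median_bias, 0)
  expect_equal(c(out$ci_low, out$ci_high), c(0, 0))
  expect_true(out$retained)

  shifted <- data.frame(snp_id = "s1", deviation = rep(0.2, 20))
  out2 <- snp_bias(shifted, B = 200, seed = 1)
  expect_false(out2$retained)

  set.seed(42)
  tight <- data.frame(snp_id = "s1", deviation = rnorm(30, 0, 0.01))
  out3 <- snp_bias(tight, B = 2000, seed = 7)
  expect_true(out3$retained)

  one <- data.frame(snp_id = "s1", deviation = 0.1)
  expect_true(is.na(snp_bias(one, B = 50)$retained))
})

test_that("percentile bootstrap CI always brackets the sample median", {
  set.seed(12)
  for (i in 1:25) {
    d <- data.frame(snp_id = "s", deviation = rnorm(sample(5:40, 1)))
    out <- snp_bias(d, B = 300, seed = i)
    expect_lte(out$ci_low, out$median_bias)
    expect_gte(out$ci_high, out$median_bias)
  }
})

test_that("Spearman concordance recovers monotone relationships", {
  x <- c(0, 0.25, 0.5, 0.75, 1)
  r <- rep("low", 5)
  expect_equal(concordance(x, x, r)$rho, 1)
  expect_equal(concordance(rev(x), x, r)$rho, -1)
  expect_equal(concordance(c(0, 0.3, 0.45, 0.8, 0.95), x, r)$rho, 1)
  const <- concordance(x, rep(0.5, 5), r)
  expect_true(is.na(const$rho))
})

test_that("permutation ANCOVA finds no regime effect in duplicated data and a strong one when present", {
  hi_exp <- rep(c(0, 0.25, 0.5, 0.75, 1), 6)
  set.seed(3)
  y <- hi_exp + rnorm(30, 0, 0.05)
  # identical data relabelled as two regimes: no effect by construction
  null <- permutation_ancova(c(y, y), c(hi_exp, hi_exp),
                             rep(c("low", "high"), each = 30),
                             n_perm = 499, seed = 5)
  expect_gt(null$p_value[null$term == "regime"], 0.2)
  expect_gt(null$p_value[null$term == "hi_exp:regime"], 0.2)

  y2 <- c(y, y + 0.5)  # +0.5 HI offset in one regime
  eff <- permutation_ancova(y2, c(hi_exp, hi_exp),
                            rep(c("low", "high"), each = 30),
                            n_perm = 999, seed = 5)
  expect_lt(eff$p_value[eff$term == "regime"], 0.01)

  expect_error(permutation_ancova(y, hi_exp, rep("low", 30), n_perm = 99),
               "both sampling regimes")
  expect_error(permutation_ancova(c(y, y), c(hi_exp, hi_exp),
                                  rep(c("low", "high"), each = 30),
                                  n_perm = 0), "n_perm")
})

test_that("profile bias tests: Holm matches the step-down hand computation", {
  # Holm on raw {0.01, 0.04, 0.03} -> {0.03, 0.06, 0.06}
  expect_equal(stats::p.adjust(c(0.01, 0.04, 0.03), method = "holm"),
               c(0.03, 0.06, 0.06))
  set.seed(77)
  prof <- rep(c(0, 0.25, 0.5), each = 27)
  dev_null <- rnorm(81, 0, 0.05)
  null <- profile_bias_tests(dev_null, prof, rep("low", 81))
  expect_gt(null$kruskal$p_value, 0.01)

  dev_shift <- dev_null + ifelse(prof == 0.25, 0.2, 0)
  hit <- profile_bias_tests(dev_shift, prof, rep("low", 81))
  expect_lt(hit$wilcoxon$p_adj[hit$wilcoxon$profile == "0.25"], 0.05)
  expect_lt(hit$kruskal$p_value, 0.001)

  allzero <- profile_bias_tests(rep(0, 54), rep(c(0, 1), each = 27),
                                rep("low", 54))
  expect_equal(allzero$wilcoxon$p_value, c(1, 1))
})

test_that("pairwise Fligner-Killeen covers all pairs and detects spread differences", {
  set.seed(8)
  prof5 <- rep(c(0, 0.25, 0.5, 0.75, 1), each = 10)
  out <- variance_homogeneity(rnorm(50), prof5)
  expect_equal(nrow(out), 10)  # choose(5, 2)

  prof2 <- rep(c(0, 0.5), each = 50)
  d <- c(rnorm(50, 0, 0.02), rnorm(50, 0, 0.2))
  det <- variance_homogeneity(d, prof2)
  expect_lt(det$p_adj, 0.01)

  const <- variance_homogeneity(c(rep(0, 5), rnorm(5)),
                                rep(c("a", "b"), each = 5))
  expect_true(const$testable)  # pooled response not constant
  u <- variance_homogeneity(rep(0, 10), rep(c("a", "b"), each = 5))
  expect_false(u$testable)
})

test_that("Bland-Altman summary matches hand computation", {
  ba <- bland_altman(c(0.1, -0.1, 0.0, 0.2))
  expect_equal(ba$mean_bias, 0.05)
  expect_equal(ba$sd, sqrt(0.05 / 3))
  expect_equal(ba$loa_low, 0.05 - 1.96 * sqrt(0.05 / 3))
  expect_equal(ba$loa_high, 0.05 + 1.96 * sqrt(0.05 / 3))

  z <- bland_altman(rep(0, 5))
  expect_equal(c(z$loa_low, z$loa_high), c(0, 0))
  expect_error(bland_altman(0.3), "at least 2")
})

test_that("LoA coverage approaches 95% for normal differences", {
  set.seed(2024)
  n <- 20000
  d <- rnorm(n)
  ba <- bland_altman(d)
  cover <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_lt(abs(cover - 0.95), 3 * sqrt(0.95 * 0.05 / n))
})

test_that("biomass-effect test handles degenerate, effective and single-pair inputs", {
  u <- rep(0.2, 10)
  same <- biomass_effect_test(u, u, rep(0.25, 10))
  expect_equal(same$p_value, 1)
  expect_equal(same$median_diff, 0)

  set.seed(14)
  uu <- abs(rnorm(20, 0.3, 0.05))
  better <- biomass_effect_test(uu, uu - 0.1, rep(0.25, 20))
  expect_lt(better$p_value, 0.01)
  expect_equal(better$median_diff, 0.1)

  single <- biomass_effect_test(0.2, 0.1, 0.25)
  expect_false(single$testable)
})

test_that("Holm adjustment is monotone and never below the raw p-values", {
  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(2:12, 1))
    adj <- stats::p.adjust(p, method = "holm")
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})
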