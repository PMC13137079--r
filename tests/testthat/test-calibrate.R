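test_that("centroids are component-wise medians", {
  s <- rbind(sig(c("a1", "a2", "a3"), "s1", c(1, 2, 3), c(3, 4, 5)),
             sig(c("h1", "h2"), "s1", c(1, 3), c(3, 5)),
             sig("b1", "s1", 4, 0.5))
  expected <- data.frame(animal_id = c("a1", "a2", "a3", "h1", "h2", "b1"),
                         expected_genotype = c("A", "A", "A", "AB", "AB", "B"))
  cent <- compute_centroids(s, expected)
  expect_equal(cent$fam[cent$genotype == "A"], 2)   # odd n: middle value
  expect_equal(cent$hex[cent$genotype == "A"], 4)
  expect_equal(cent$fam[cent$genotype == "AB"], 2)  # even n: midpoint
  expect_equal(cent$hex[cent$genotype == "AB"], 4)
  expect_equal(cent$fam[cent$genotype == "B"], 4)   # singleton: the point

  expect_error(compute_centroids(s[1:3, ], expected), "genotype class")
})

test_that("mismatch flagging is nearest-centroid with ties treated as mismatches", {
  cl <- swab_cluster_signals(n = 4)
  cent <- compute_centroids(cl$signals, cl$expected)
  clean <- flag_mismatches(cl$signals, cl$expected, cent)
  expect_equal(nrow(clean$mismatches), 0)  # each point at its own centroid

  # move one expected-A animal onto the B centroid
  s2 <- cl$signals
  bcent <- cent[cent$genotype == "B", ]
  s2[s2$sample_id == "A01", c("fam_mean", "hex_mean")] <-
    c(bcent$fam, bcent$hex)
  mm <- flag_mismatches(s2, cl$expected, cent)
  expect_equal(mm$mismatches$sample_id, "A01")
  expect_equal(mm$mismatches$nearest_genotype, "B")

  # equidistant between own and foreign centroid: ambiguous -> flagged
  acent <- cent[cent$genotype == "A", ]
  mid <- c((acent$fam + bcent$fam) / 2, (acent$hex + bcent$hex) / 2)
  s3 <- cl$signals
  s3[s3$sample_id == "A02", c("fam_mean", "hex_mean")] <- mid
  mm3 <- flag_mismatches(s3, cl$expected, cent)
  expect_true("A02" %in% mm3$mismatches$sample_id)
})

test_that("an animal mismatched at all SNPs is excluded with all its containers' eDNA", {
  angles <- c(A = 82, AB = 46, B = 13)
  two_snps <- lapply(c("s1", "s2"), function(snp) {
    swab_cluster_signals(snp = snp, n = 4, angles = angles)
  })
  signals <- do.call(rbind, lapply(two_snps, `[[`, "signals"))
  expected <- two_snps[[1]]$expected
  # A01 looks heterozygous at every SNP though expected homozygous A
  for (snp in c("s1", "s2")) {
    i <- signals$sample_id == "A01" & signals$snp_id == snp
    signals[i, c("fam_mean", "hex_mean")] <-
      3 * c(cos(46 * pi / 180), sin(46 * pi / 180))
  }
  design <- data.frame(population_id = c("P1", "P1", "P2", "P2"),
                       animal_id = c("A01", "AB01", "A02", "AB02"),
                       expected_genotype = c("A", "AB", "A", "AB"))
  cent <- compute_centroids(signals, expected)
  mm <- flag_mismatches(signals, expected, cent, design = design)
  expect_equal(mm$animals_excluded, "A01")
  whole_pop <- mm$edna_exclusions[is.na(mm$edna_exclusions$snp_id), ]
  expect_equal(whole_pop$population_id, "P1")
})

test_that("a single mismatched call excludes the linked eDNA at that SNP only", {
  two_snps <- lapply(c("s1", "s2"), function(snp) {
    swab_cluster_signals(snp = snp, n = 4)
  })
  signals <- do.call(rbind, lapply(two_snps, `[[`, "signals"))
  expected <- two_snps[[1]]$expected
  cent <- compute_centroids(signals, expected)
  bcent <- cent[cent$genotype == "B" & cent$snp_id == "s1", ]
  i <- signals$sample_id == "A01" & signals$snp_id == "s1"
  signals[i, c("fam_mean", "hex_mean")] <- c(bcent$fam, bcent$hex)
  design <- data.frame(population_id = c("P1", "P1"),
                       animal_id = c("A01", "AB01"),
                       expected_genotype = c("A", "AB"))
  mm <- flag_mismatches(signals, expected, cent, design = design)
  expect_equal(mm$edna_exclusions,
               data.frame(population_id = "P1", snp_id = "s1"))
  expect_equal(length(mm$animals_excluded), 0)
})

test_that("MAD outlier rule matches hand computation including degenerate branches", {
  make_cluster <- function(d) {
    # points on the FAM axis at distance d right of a centroid at (3, 0)
    s <- sig(sprintf("x%02d", seq_along(d)), "s1", 3 + d, 0)
    e <- data.frame(animal_id = s$sample_id, expected_genotype = "A")
    cent <- data.frame(snp_id = "s1", genotype = "A", fam = 3, hex = 0, n = length(d))
    exclude_outliers(s, e, cent)
  }
  out <- make_cluster(c(0.1, 0.2, 0.3, 0.4, 2.0))
  expect_equal(out$thresholds$threshold, 0.3 + 3 * 1.4826 * 0.1)
  expect_equal(out$outliers$sample_id, "x05")

  # all distances equal: MAD 0, nothing strictly above the median
  out2 <- make_cluster(rep(0.3, 5))
  expect_equal(nrow(out2$outliers), 0)

  # {0, 0, 0, 5}: MAD 0 -> strict-excess rule excludes only the 5
  out3 <- make_cluster(c(0, 0, 0, 5))
  expect_equal(out3$outliers$sample_id, "x04")

  expect_warning(make_cluster(0.5), "single point")
})

test_that("centroid angles follow the FAM/HEX convention and enforce ordering", {
  cent <- data.frame(snp_id = "s1", genotype = c("A", "AB", "B"),
                     fam = c(0, 1, 1), hex = c(1, 1, 0), n = c(3, 3, 3))
  cal <- centroid_angles(cent)
  expect_equal(cal$alpha_A, 90)
  expect_equal(cal$alpha_AB, 45)
  expect_equal(cal$alpha_B, 0)

  bad <- cent; bad$fam <- c(1, 1, 0); bad$hex <- c(0, 1, 1)  # reversed
  expect_error(centroid_angles(bad), "ordering.*s1")
  expect_error(angle_of(0, 0), "origin")
})

test_that("angles are invariant under uniform positive scaling", {
  set.seed(5)
  fam <- runif(100, 0.1, 5); hex <- runif(100, 0.1, 5)
  k <- runif(100, 0.01, 50)
  expect_equal(angle_of(k * fam, k * hex), angle_of(fam, hex))
})

test_that("calibration is idempotent on clean clusters and recovers true angles as noise shrinks", {
  angles <- c(A = 82, AB = 46, B = 13)
  for (jit in c(2, 0.2, 0.002)) {
    cl <- swab_cluster_signals(n = 9, angles = angles, jitter = jit, seed = 8)
    cal <- calibrate_snps(cl$signals, cl$expected)
    err <- max(abs(c(cal$calibration$alpha_A - 82,
                     cal$calibration$alpha_AB - 46,
                     cal$calibration$alpha_B - 13)))
    expect_lt(err, 2 * jit)
    expect_equal(cal$counts$n_mismatches, 0)  # clean, well-separated data
  }
  # zero jitter: every point at its centroid, nothing excluded, exact angles
  cl0 <- swab_cluster_signals(n = 6, angles = angles, jitter = 0)
  cal0 <- calibrate_snps(cl0$signals, cl0$expected)
  expect_equal(cal0$counts$n_outliers, 0)
  expect_equal(cal0$calibration$alpha_A, 82, tolerance = 1e-12)
  expect_equal(cal0$calibration$alpha_B, 13, tolerance = 1e-12)
})
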