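test_that("low-fluorescence triangle membership handles interior, exterior and boundary", {
  expect_true(in_triangle(0.5, 0.5))
  expect_false(in_triangle(3.0, 0.1))
  expect_true(in_triangle(1.0, 1.0))   # on the fam + hex = 2 edge
  expect_true(in_triangle(0, 0))       # vertex
  expect_false(in_triangle(2.1, 0))
  expect_error(in_triangle(1, 1, rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("filtering partitions the input and reports per-dataset counts", {
  tab <- fl_tab(fl("a1", "s1", 0.5, 0.5), fl("a1", "s1", 3, 0.1, rep = 2),
                fl("e1", "s1", 1, 1, dataset = "edna"),
                fl("e1", "s1", 2.5, 0.5, rep = 2, dataset = "edna"))
  out <- filter_low_fluorescence(tab)
  expect_equal(nrow(out$retained) + nrow(out$excluded), nrow(tab))
  expect_equal(sort(out$summary$n_excluded), c(1L, 1L))
  expect_equal(out$excluded$sample_id, c("a1", "e1"))
})

test_that("radial shrink toward the origin can only grow the excluded set", {
  set.seed(31)
  for (i in 1:50) {
    fam <- runif(40, 0, 5); hex <- runif(40, 0, 5)
    lambda <- runif(1)
    before <- in_triangle(fam, hex)
    after <- in_triangle(lambda * fam, lambda * hex)
    expect_true(all(after[before]))  # once inside, stays inside when shrunk
  }
})

test_that("read-cycle selection keeps the largest dimer-free cycle", {
  cycles <- c(39L, 42L, 45L, 48L, 51L)
  clean <- do.call(rbind, lapply(cycles, function(cy) {
    fl("NTC1", "s1", 0.2, 0.2, cycle = cy, dataset = "ntc")
  }))
  expect_equal(as.integer(select_read_cycle(clean, cycles)), 51L)

  dirty51 <- clean
  dirty51$fam[dirty51$read_cycle == 51] <- 3  # dimer signal at 51 only
  expect_equal(as.integer(select_read_cycle(dirty51, cycles)), 48L)

  all_dirty <- clean
  all_dirty$fam <- 3
  expect_warning(chosen <- select_read_cycle(all_dirty, cycles),
                 "every candidate cycle")
  expect_equal(as.integer(chosen), 39L)

  no_controls <- fl("a1", "s1", 2, 2, cycle = 48)
  expect_error(select_read_cycle(no_controls, cycles), "without controls")
})

test_that("field-control screening flags any out-of-triangle PCR", {
  inside <- do.call(rbind, lapply(1:4, function(r) {
    fl("FNC1", "s1", 0.3, 0.3, rep = r, dataset = "field_negative")
  }))
  rep0 <- screen_field_controls(inside)
  expect_equal(length(rep0$flagged), 0)

  contaminated <- inside
  contaminated$fam[1:2] <- 3
  rep1 <- screen_field_controls(contaminated)
  expect_equal(rep1$flagged, "FNC1")
  expect_equal(rep1$by_sample$fraction, 0.5)

  empty <- screen_field_controls(fl("a1", "s1", 3, 3))
  expect_equal(nrow(empty$by_sample), 0)
})

test_that("replicate averaging is an arithmetic mean, permutation-invariant, and reports dropped groups", {
  tab <- fl_tab(fl("a1", "s1", 1, 4, rep = 1), fl("a1", "s1", 2, 3, rep = 2),
                fl("a1", "s1", 3, 2, rep = 3), fl("a1", "s1", 4, 1, rep = 4))
  out <- average_replicates(tab)$signals
  expect_equal(out$fam_mean, 2.5)
  expect_equal(out$hex_mean, 2.5)
  expect_equal(out$n_replicates, 4L)

  shuffled <- tab[c(3, 1, 4, 2), ]
  expect_equal(average_replicates(shuffled)$signals, out)

  # one replicate excluded by the triangle -> mean over the remaining 3
  tab2 <- rbind(tab, fl("a2", "s1", 0.2, 0.2, rep = 1),
                fl("a2", "s1", 0.3, 0.1, rep = 2))
  filt <- filter_low_fluorescence(rbind(tab2, fl("a1", "s1", 0.5, 0.5, rep = 5)))
  res <- average_replicates(filt$retained, original = filt$retained)
  a1 <- res$signals[res$signals$sample_id == "a1", ]
  expect_equal(a1$n_replicates, 4L)

  # all replicates of a2 excluded -> group dropped and reported
  filt2 <- filter_low_fluorescence(tab2)
  res2 <- average_replicates(filt2$retained, original = tab2)
  expect_false("a2" %in% res2$signals$sample_id)
  expect_equal(res2$dropped$sample_id, "a2")
})
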