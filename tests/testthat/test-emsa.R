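test_that("Fraction Bound is the bound share of total band intensity", {
  expect_equal(fraction_bound(500, 500), 0.5)
  expect_equal(fraction_bound(0, 800), 0)
  expect_equal(fraction_bound(900, 100), 0.9)
  expect_equal(fraction_bound(c(1, 3), c(3, 1)), c(0.25, 0.75))
  expect_error(fraction_bound(0, 0), "positive")
  expect_error(fraction_bound(-1, 2), "nonnegative")
})

test_that("allele comparison reproduces the textbook pooled-variance t test", {
  major <- c(0.20, 0.22, 0.21); minor <- c(0.60, 0.62, 0.61)
  comp <- compare_alleles(major, minor)
  expect_equal(comp$delta_fb, 0.40, tolerance = 1e-12)
  expect_lt(comp$p_value, 0.01)
  # oracle: textbook pooled t statistic and one-sided tail
  sp <- sqrt((2 * var(major) + 2 * var(minor)) / 4)
  tt <- (mean(minor) - mean(major)) / (sp * sqrt(2 / 3))
  expect_equal(comp$p_value, pt(-abs(tt), df = 4), tolerance = 1e-12)
  # cross-check against stats::t.test with pooled variance
  ref <- t.test(minor, major, var.equal = TRUE, alternative = "greater")
  expect_equal(comp$p_value, ref$p.value, tolerance = 1e-12)

  same <- compare_alleles(major, major)
  expect_equal(same$delta_fb, 0)
  expect_equal(same$p_value, 0.5)

  expect_error(compare_alleles(0.2, c(0.3, 0.4)), "replicates")
  expect_error(compare_alleles(c(0.2, 1.2), c(0.3, 0.4)), "\\[0, 1\\]")
})

test_that("effect classes follow the delta and significance thresholds", {
  cmp <- function(d, p) list(delta_fb = d, p_value = p)
  expect_equal(classify_effect(cmp(0.47, 0.001)), "DOWN")
  expect_equal(classify_effect(cmp(-0.53, 0.001)), "UP")
  expect_equal(classify_effect(cmp(0.05, 1e-4)), "NO_DIFFERENCE")
  expect_equal(classify_effect(cmp(0.3, 0.2)), "NO_DIFFERENCE")
  # monotone: growing |delta| at fixed p never leaves UP/DOWN
  for (d in seq(0.1, 1, by = 0.1)) {
    expect_equal(classify_effect(cmp(d, 0.01)), "DOWN")
    expect_equal(classify_effect(cmp(-d, 0.01)), "UP")
  }
})

test_that("delta is antisymmetric under swapping alleles", {
  set.seed(21)
  for (i in 1:20) {
    a <- runif(3); b <- runif(3)
    expect_equal(compare_alleles(a, b)$delta_fb,
                 -compare_alleles(b, a)$delta_fb, tolerance = 1e-12)
    expect_equal(compare_alleles(a, b)$p_value,
                 compare_alleles(b, a)$p_value, tolerance = 1e-12)
  }
})

test_that("type-I error of the allele comparison is near nominal", {
  set.seed(22)
  n_sim <- 2000
  rej <- 0L
  for (i in seq_len(n_sim)) {
    a <- rnorm(3, 0.4, 0.05); b <- rnorm(3, 0.4, 0.05)
    a <- pmin(pmax(a, 0), 1); b <- pmin(pmax(b, 0), 1)
    # one-sided-in-observed-direction doubles the nominal rate, so
    # compare at alpha/2 which corresponds to a two-sided 0.05 test
    if (compare_alleles(a, b)$p_value < 0.025) rej <- rej + 1L
  }
  rate <- rej / n_sim
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / n_sim))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("lane tables produce per-competitor comparisons and classes", {
  lanes <- rbind(
    data.frame(competitor_label = "rsA", allele = "major", replicate = 1:3,
               bound = c(200, 220, 210), unbound = c(800, 780, 790)),
    data.frame(competitor_label = "rsA", allele = "minor", replicate = 1:3,
               bound = c(600, 620, 610), unbound = c(400, 380, 390)),
    data.frame(competitor_label = "Ideal", allele = "control",
               replicate = 1:3, bound = c(50, 60, 55),
               unbound = c(950, 940, 945)))
  tab <- emsa_comparison_table(lanes)
  expect_equal(nrow(tab), 1)    # control lanes are not compared
  expect_equal(tab$delta_fb, 0.40, tolerance = 1e-12)
  expect_equal(tab$effect_class, "DOWN")
  tab2 <- emsa_comparison_table(lanes, p_adjust = "BH")
  expect_true("p_adj" %in% names(tab2))
  # convenience sanity check on the control pair
  fb <- fraction_bound(lanes$bound, lanes$unbound)
  expect_lt(mean(fb[lanes$competitor_label == "Ideal"]),
            mean(fb[lanes$competitor_label == "rsA"]))
})

test_that("positional profiles average |delta FB| per motif position", {
  recs <- data.frame(motif_position = c(5, 5, 13),
                     delta_fb = c(0.2, -0.4, 0.1))
  prof <- position_effect_profile(recs)
  expect_equal(prof$mean_abs_delta_fb[prof$motif_position == 5], 0.3)
  expect_equal(prof$n[prof$motif_position == 5], 2)
  expect_equal(prof$mean_abs_delta_fb[prof$motif_position == 13], 0.1)
  expect_equal(nrow(position_effect_profile(recs[0, ])), 0)

  one <- position_effect_profile(data.frame(motif_position = 5,
                                            delta_fb = 0.3))
  expect_equal(one$mean_abs_delta_fb, 0.3)
})

test_that("positional profile recovers generator truth on synthetic lanes", {
  sim <- simulate_bundle(sim_config(seed = 55, genome_length = 5e4,
                                    n_motifs = 10, n_snps = 10, depth = 5,
                                    emsa_noise_sd = 0.01))
  tab <- emsa_comparison_table(sim$lanes)
  joined <- merge(tab, sim$truth$emsa, by.x = "competitor_label",
                  by.y = "snp_id")
  expect_equal(joined$delta_fb, joined$delta_fb_true, tolerance = 0.05)
})

test_that("reporter normalization and allele comparison behave as defined", {
  expect_equal(luciferase_relative_activity(1000, 1000, 500, 500), 1)
  expect_equal(luciferase_relative_activity(2000, 1000, 1000, 1000), 2)
  expect_equal(luciferase_relative_activity(500, 1000, 1000, 1000), 0.5)
  expect_error(luciferase_relative_activity(0, 1, 1, 1), "positive")

  res <- compare_reporter_alleles(c(1.0, 1.1, 0.9), c(0.4, 0.5, 0.45),
                                  expected_class = "UP")
  expect_lt(res$p_value, 0.05)
  expect_equal(res$direction, -1)     # minor more repressed
  expect_true(res$consistent)
  # oracle recomputation with stats::t.test (two-sided, pooled)
  ref <- t.test(c(0.4, 0.5, 0.45), c(1.0, 1.1, 0.9), var.equal = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  same <- compare_reporter_alleles(c(1, 1), c(1, 1))
  expect_equal(same$p_value, 1)
})

test_that("reporter comparison holds its nominal type-I rate", {
  set.seed(23)
  n_sim <- 1000
  rej <- sum(replicate(n_sim, {
    compare_reporter_alleles(rnorm(3, 1, 0.1), rnorm(3, 1, 0.1))$p_value < 0.05
  }))
  rate <- rej / n_sim
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / n_sim))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})
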