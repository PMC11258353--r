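test_that("current ratio propagates independent relative errors", {
  m1 <- dual_measurement(electrode_summary(5, 0.2), electrode_summary(5, 0.2))
  expect_equal(current_ratio(m1)$r, 1)
  m2 <- dual_measurement(electrode_summary(10, 1), electrode_summary(5, 0.5))
  cr <- current_ratio(m2)
  expect_equal(cr$r, 2)
  expect_equal(cr$sd_r, 2 * sqrt(0.1^2 + 0.1^2)) # 0.282843
  bad <- dual_measurement(electrode_summary(10, 1), electrode_summary(0, 0.5))
  expect_error(current_ratio(bad), class = "gbas_undefined_ratio")
})

test_that("ratio curve plateaus at the loading-weighted Vmax ratio", {
  g <- seq(0.5, 1.2, by = 0.1)
  blank <- ligand_dose("none", 0, 0.01)
  ht <- ligand_dose("4-HT", 1e-6, 0.01)
  # identical enzymes, unit loadings: ratio identically 1
  e <- gdh_wildtype()
  expect_equal(ratio_curve(e, e, c(k1 = 1, k2 = 1), g, blank), rep(1, 8))
  # 4-HT lowers the whole curve
  r_b <- ratio_curve(glucose_grid = g, dose = blank)
  r_h <- ratio_curve(glucose_grid = g, dose = ht)
  expect_true(all(r_h < r_b))
  # saturation algebra at very high glucose
  e5i <- gdh_5e_plus(immobilized_alpha_max())
  ew <- gdh_wildtype()
  lo <- default_loadings(e5 = e5i, ew = ew)
  plateau <- ratio_curve(e5i, ew, lo, 1e5, ht)
  f <- inhibition_factor(e5i, ht) / inhibition_factor(ew, ht)
  expect_equal(plateau,
               lo[["k1"]] * f * e5i$vmax_blank / (lo[["k2"]] * ew$vmax_blank),
               tolerance = 1e-4)
  # calibration: blank plateau near 6.37, 4-HT plateau near 4.85
  expect_equal(ratio_curve(glucose_grid = 100, dose = blank), 6.37,
               tolerance = 1e-3)
  expect_equal(ratio_curve(glucose_grid = 100, dose = ht), 4.85,
               tolerance = 1e-3)
})

test_that("ratio is glucose-invariant inside the operational range", {
  g <- seq(0.5, 1.2, by = 0.05)
  r <- ratio_curve(glucose_grid = g, dose = ligand_dose("none", 0, 0.01))
  expect_lt(sd(r) / mean(r), 0.05)
})

test_that("operational-range gate uses a strict 0.4 mM threshold", {
  expect_true(in_operational_range(5.6))
  expect_false(in_operational_range(0.2))
  expect_false(in_operational_range(0.4)) # strict inequality
  expect_warning(ok <- in_operational_range(NULL), "assuming blood-range")
  expect_true(ok)
})

test_that("classification calls the nearest reference with refusal bands", {
  refs <- ratio_reference()
  expect_identical(classify_ratio(6.1, 0.5, refs)$call, "NEGATIVE")
  expect_identical(classify_ratio(4.6, 0.4, refs)$call, "POSITIVE_4HT")
  # midpoint tie refuses
  expect_identical(classify_ratio(5.61, 0.05, refs)$call, "INDETERMINATE")
  # range gate dominates
  expect_identical(classify_ratio(6.1, 0.5, refs, range_ok = FALSE)$call,
                   "OUT_OF_RANGE")
  # far from both references with tight errors: refuse
  expect_identical(classify_ratio(20, 0.01, refs)$call, "INDETERMINATE")
  # monotonicity: decreasing r never flips POSITIVE_4HT back to NEGATIVE
  calls <- vapply(seq(5.5, 3.5, by = -0.25), function(r)
    classify_ratio(r, 0.3, refs)$call, character(1))
  first_pos <- match("POSITIVE_4HT", calls)
  expect_false(any(calls[first_pos:length(calls)] == "NEGATIVE"))
})

test_that("group comparison matches the t distribution and stats::t.test", {
  # identical groups: no effect
  eq <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  # summary-statistics input: the 112 vs 92 activity pair
  res <- compare_groups(list(mean = 112, sd = 2, n = 3),
                        list(mean = 92, sd = 2, n = 3))
  expect_equal(res$t, 20 / (2 * sqrt(2 / 3)), tolerance = 1e-12) # 12.2474
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-20 / (2 * sqrt(2 / 3)), 4), tolerance = 1e-12)
  expect_lt(abs(res$p - 2.6e-4), 2e-5)
  # cross-check both variants against stats::t.test on raw replicates
  set.seed(9)
  a <- rnorm(5, 10, 1); b <- rnorm(7, 8, 2)
  pooled <- compare_groups(a, b, var_equal = TRUE)
  welch <- compare_groups(a, b, var_equal = FALSE)
  expect_equal(pooled$p, t.test(a, b, var.equal = TRUE)$p.value)
  expect_equal(welch$p, t.test(a, b)$p.value)
  # p decreases monotonically as the effect grows at fixed sd
  ps <- vapply(seq(0, 40, by = 5), function(d)
    compare_groups(list(mean = 100 + d, sd = 2, n = 3),
                   list(mean = 100, sd = 2, n = 3))$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(compare_groups(c(1), c(1, 2)),
               class = "gbas_insufficient_replicates")
})

test_that("decoding a simulated blood measurement is reproducible and correct", {
  s <- blood_sample(glucose_mM = 5.6,
                    dose = ligand_dose("4-HT", 1e-6, 0.01),
                    volume_uL = 200, electrolyte_mL = 2)
  m1 <- simulate_dual_measurement(s, seed = 5)
  m2 <- simulate_dual_measurement(s, seed = 5)
  expect_identical(m1$i_5e$mean_uA, m2$i_5e$mean_uA)
  d <- decode_measurement(m1)
  expect_identical(d$call, "POSITIVE_4HT")
  blank <- blood_sample(glucose_mM = 5.6, dose = ligand_dose("none", 0, 0.01),
                        volume_uL = 200, electrolyte_mL = 2)
  expect_identical(decode_measurement(simulate_dual_measurement(blank, seed = 6))$call,
                   "NEGATIVE")
})
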