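test_that("round-1 permissive calling is a fold threshold over control", {
  expect_false(round1_classify(0.002, 0.002)) # equal to control
  expect_true(round1_classify(0.02, 0.002, fold_threshold = 3)) # 10-fold
  expect_error(round1_classify(NA_real_, 0.002), class = "gbas_missing_data")
})

test_that("round-1 recovers ground-truth permissive labels at the 5-fold effect", {
  cfg <- sim_config(seed = 101)
  tab <- generate_screen_table(cfg)
  called <- round1_classify(tab$r1_rate, tab$r1_control_rate)
  truth <- tab$truth_label != "inactive"
  expect_gte(mean(called == truth), 0.95)
})

test_that("round-2 allosteric calling gates on permissiveness", {
  same <- c(1, 1.1, 0.9)
  expect_equal(round2_allosteric(same, same)$p, 1)
  expect_false(round2_allosteric(same, same)$allosteric)
  # a clear effect on a non-permissive variant is never allosteric
  strong <- round2_allosteric(c(1, 1.02, 0.98), c(0.5, 0.51, 0.49),
                              permissive = FALSE)
  expect_lt(strong$p, 0.05)
  expect_false(strong$allosteric)
  expect_error(round2_allosteric(1, c(1, 2)),
               class = "gbas_insufficient_replicates")
})

test_that("round-2 power exceeds 0.8 for a 31% effect at 11% CV", {
  set.seed(202)
  hits <- replicate(1500, {
    d <- 1 * (1 + rnorm(3, 0, 0.11))
    h <- 0.69 * (1 + rnorm(3, 0, 0.11))
    round2_allosteric(d, h, permissive = TRUE)$allosteric
  })
  expect_gt(mean(hits), 0.8)
})

test_that("profile summary reports exact counts and fractions", {
  cfg <- sim_config(seed = 17)
  tab <- generate_screen_table(cfg)
  prof <- profile_summary(tab) # truth-labelled fixture
  expect_equal(prof$n_total, 454)
  expect_equal(prof$n_permissive, 232)
  expect_equal(prof$n_allosteric, 71)
  expect_equal(prof$frac_permissive, 232 / 454) # ~51.1%
  expect_equal(prof$frac_allosteric, 71 / 454)  # ~15.6%
  # degenerate tables
  empty <- data.frame(permissive = logical(0), allosteric = logical(0))
  expect_equal(profile_summary(empty)$frac_permissive, 0)
  allp <- data.frame(permissive = rep(TRUE, 5), allosteric = rep(FALSE, 5))
  expect_equal(profile_summary(allp)$frac_permissive, 1)
})

test_that("classification is label-consistent: allosteric within permissive", {
  cfg <- sim_config(seed = 303)
  cls <- classify_screen(generate_screen_table(cfg))
  expect_true(all(!cls$allosteric | cls$permissive))
  prof <- profile_summary(cls)
  # recovered fractions within 3 points of the generating truth
  expect_lt(abs(prof$frac_permissive - 232 / 454), 0.03)
  expect_lt(abs(prof$frac_allosteric - 71 / 454), 0.03)
})

test_that("type-I error of the allosteric test is close to alpha on null data", {
  set.seed(404)
  p <- replicate(4000, {
    d <- 1 * (1 + rnorm(3, 0, 0.11))
    h <- 1 * (1 + rnorm(3, 0, 0.11))
    round2_allosteric(d, h)$p
  })
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
})

test_that("structural enrichment compares against a length-weighted null", {
  ss <- generate_ss_annotation(454)
  # every residue as a site: exactly proportional, chi-square ~ 0
  all_sites <- structural_enrichment(ss$residue, ss)
  expect_equal(as.numeric(all_sites$counts), as.numeric(all_sites$expected))
  expect_lt(all_sites$chisq, 1e-9)
  # all sites in loops: total loop enrichment
  loops <- ss$residue[ss$ss_class == "loop"][1:50]
  enr <- structural_enrichment(loops, ss)
  expect_equal(enr$fractions[1], 1)
  expect_lt(enr$p, 0.001)
  expect_error(structural_enrichment(c(1, 9999), ss),
               class = "gbas_annotation_gap")
  # generated allosteric truth is loop/interface-biased and detectable
  cfg <- sim_config(seed = 505)
  tab <- generate_screen_table(cfg)
  sites <- tab$position[tab$truth_label == "allosteric"]
  enr2 <- structural_enrichment(sites, ss)
  loop_frac_null <- mean(ss$ss_class == "loop")
  expect_gt(enr2$fractions[1], loop_frac_null)
})

test_that("coupon-collector coverage matches brute-force simulation", {
  expect_equal(coverage_probability(0, 10)$p_full_coverage, 0)
  expect_equal(coverage_probability(5, 1)$p_full_coverage, 1)
  # the screening-scale library: 7392 picks over 454 variants
  cov <- coverage_probability(7392, 454)
  expect_gt(cov$p_full_coverage, 0.999)
  expect_gt(cov$p_full_coverage, cov$lower_bound - 1e-12)
  # monotone in picks, antitone in library size
  ns <- vapply(c(2500, 3000, 4000, 6000, 8000), function(N)
    coverage_probability(N, 454)$p_full_coverage, numeric(1))
  expect_true(all(diff(ns) > 0))
  ks <- vapply(c(100, 200, 454, 900), function(n)
    coverage_probability(3000, n)$p_full_coverage, numeric(1))
  expect_true(all(diff(ks) < 0))
  # Monte-Carlo agreement on a small instance
  set.seed(606)
  n <- 8; N <- 25; B <- 4000
  mc <- mean(replicate(B, length(unique(sample.int(n, N, replace = TRUE))) == n))
  exact <- coverage_probability(N, n)$p_full_coverage
  expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / B))
})

test_that("read-count coverage counts positions with any reads", {
  expect_equal(coverage_from_reads(rep(0L, 454))$completeness, 0)
  expect_equal(coverage_from_reads(rep(3L, 454))$completeness, 1)
  cfg <- sim_config(seed = 707)
  tab <- generate_screen_table(cfg)
  # 140,340 multinomial reads over 454 positions covers everything
  expect_equal(coverage_from_reads(tab$reads)$completeness, 1)
  expect_error(coverage_from_reads(rep(1L, 10)), class = "gbas_invalid_input")
})
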