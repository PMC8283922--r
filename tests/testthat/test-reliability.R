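# Test-retest reliability statistics.

test_that("ICC(A,k) agrees with an aov-based oracle on random panels", {
  set.seed(11)
  for (i in 1:200) {
    p <- random_panel(n = sample(5:15, 1))
    panel <- measurement_panel(p$s1, p$s2)
    got <- icc_a_k(panel)
    expect_equal(got$icc, oracle_icc_aov(p$s1, p$s2), tolerance = 1e-9)
    # the F-based interval brackets the estimate away from the degenerate
    # near-zero region (the approximation is known to misbehave there)
    if (got$icc > 0.2)
      expect_true(got$ci_low <= got$icc + 1e-9 && got$icc <= got$ci_high + 1e-9)
  }
})

test_that("ICC is 1 for perfect agreement and undefined without variance", {
  panel <- measurement_panel(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc_a_k(panel)$icc, 1)
  flat <- measurement_panel(rep(2, 5), rep(2, 5))
  res <- icc_a_k(flat)
  expect_false(res$defined)
  expect_true(is.na(res$icc))
  expect_error(measurement_panel(1, 1), "at least 2 subjects")
})

test_that("ICC is invariant to a common affine transform", {
  set.seed(12)
  p <- random_panel(12)
  base <- icc_a_k(measurement_panel(p$s1, p$s2))$icc
  tr <- icc_a_k(measurement_panel(3.7 * p$s1 - 11, 3.7 * p$s2 - 11))$icc
  expect_equal(tr, base, tolerance = 1e-9)
})

test_that("SEM and SRD follow the ANOVA error term", {
  # constructed: SEM = 1 implies SRD = 1.96 * sqrt(2)
  set.seed(13)
  p <- random_panel(10)
  panel <- measurement_panel(p$s1, p$s2)
  s <- sem_srd(panel)
  expect_equal(s$srd, 1.96 * sqrt(2) * s$sem, tolerance = 1e-12)
  expect_equal(s$srd / s$sem, 2.771859, tolerance = 1e-6)
  # sem equals sqrt(MSE) of the aov fit
  n <- length(p$s1)
  d <- data.frame(value = c(p$s1, p$s2),
                  subject = factor(rep(1:n, 2)),
                  session = factor(rep(1:2, each = n)))
  mse <- summary(stats::aov(value ~ subject + session, d))[[1]]["Residuals", "Mean Sq"]
  expect_equal(s$sem, sqrt(mse), tolerance = 1e-9)
  # noiseless panel: SEM = SRD = 0, srd_pct defined by the spread
  clean <- measurement_panel(1:6, 1:6)
  expect_equal(sem_srd(clean)$sem, 0)
  expect_equal(sem_srd(clean)$srd, 0)
  # zero range is flagged
  expect_true(is.na(suppressWarnings(
    sem_srd(measurement_panel(rep(1, 4), rep(1, 4)))$srd_pct)))
})

test_that("reliability improves monotonically as within-subject noise vanishes", {
  set.seed(14)
  sds <- c(2, 1, 0.5, 0.2, 0.05)
  icc <- srd <- numeric(length(sds))
  for (j in seq_along(sds)) {
    r <- replicate(40, {
      p <- simulate_panel(n = 20, sigma_subject = 1, sigma_error = sds[j])
      c(icc_a_k(p)$icc, sem_srd(p)$srd)
    })
    icc[j] <- mean(r[1, ]); srd[j] <- mean(r[2, ])
  }
  expect_true(all(diff(icc) > 0))
  expect_true(all(diff(srd) < 0))
  expect_gt(icc[5], 0.99)
  expect_lt(srd[5], 0.25)
})

test_that("systematic shift is the range-normalised oriented mean difference", {
  s1 <- c(2, 4, 6, 8, 10)
  expect_equal(systematic_shift(measurement_panel(s1, s1)), 0)
  # constant offset d on retest over range R recovers 100 d / R
  d <- 0.8
  panel <- measurement_panel(s1, s1 + d)
  expect_equal(systematic_shift(panel, direction = "lower"),
               100 * d / (max(s1 + d) - min(s1)))
  # for higher-is-better metrics a gain on retest is an improvement (< 0)
  expect_lt(systematic_shift(panel, direction = "higher"), 0)
  expect_equal(systematic_shift(panel, direction = "higher"),
               -systematic_shift(panel, direction = "lower"))
})

test_that("Bland-Altman limits bracket the differences", {
  same <- measurement_panel(c(1, 2, 3), c(1, 2, 3))
  ba0 <- bland_altman(same)
  expect_equal(c(ba0$mean_diff, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  # differences {-1, +1}: mean 0, limits +- 1.96 * sd
  panel <- measurement_panel(c(5, 9), c(4, 10))
  ba <- bland_altman(panel)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_high, 1.96 * stats::sd(c(-1, 1)))
  expect_equal(ba$loa_low, -ba$loa_high)
  expect_equal(ba$pairs$diff, c(-1, 1))
  # unbiased noise: zero lies inside the limits in most replicates
  set.seed(15)
  inside <- replicate(300, {
    p <- simulate_panel(n = 15, sigma_subject = 1, sigma_error = 0.5)
    b <- bland_altman(p)
    b$loa_low < 0 && 0 < b$loa_high
  })
  expect_gt(mean(inside), 0.93)
})

test_that("test-retest Spearman matches the rank-then-Pearson oracle", {
  p1 <- measurement_panel(1:6, (1:6)^2)   # monotone map
  expect_equal(test_retest_spearman(p1)$rho, 1)
  p2 <- measurement_panel(1:6, -(1:6))
  expect_equal(test_retest_spearman(p2)$rho, -1)
  set.seed(16)
  for (i in 1:100) {
    p <- random_panel(n = 10, integer = TRUE)
    panel <- measurement_panel(p$s1, p$s2)
    got <- test_retest_spearman(panel)
    if (!got$defined) next
    expect_equal(got$rho, oracle_spearman(p$s1, p$s2), tolerance = 1e-12)
  }
  const <- measurement_panel(rep(1, 5), 1:5)
  expect_false(test_retest_spearman(const)$defined)
})

test_that("reliability flags apply the 0.7 / 30% / 6.35 decision rules", {
  set.seed(17)
  p <- simulate_panel(n = 25, sigma_subject = 1, sigma_error = 0.2, seed = 1)
  row <- reliability_stats(p)
  expect_identical(row$icc_ok, row$icc > 0.7)
  expect_identical(row$srd_ok, row$srd_pct < 30)
  expect_identical(row$shift_ok, abs(row$shift_pct) <= 6.35)
})

test_that("reliability_report produces one calibrated row per metric", {
  cfg <- generator_config()
  subjects <- sample_cohort(cfg, 21)
  sim <- simulate_trials(subjects[subjects$group == "stroke", ][1:12, ], cfg, 21)
  mt <- extract_metrics(sim$trials)
  rep_ <- reliability_report(mt, trials = sim$trials, side = "affected")
  expect_setequal(rep_$metric, metric_catalogue()$metric)
  expect_true(all(is.finite(rep_$icc)))
  expect_true(all(rep_$sem >= 0))
  # trial-informed pooled range is at least the session-mean range
  expect_true(all(rep_$srd_pct >= 0, na.rm = TRUE))
})
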