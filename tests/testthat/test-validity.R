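# Discriminant validity, normative z-scoring, concurrent validity and
# metric independence.

test_that("Kruskal-Wallis H matches the brute-force rank statistic", {
  same <- kruskal_bonferroni(list(a = c(1, 1, 2), b = c(1, 2, 1), c = c(2, 1, 1)))
  expect_gt(same$p, 0.5)
  flat <- kruskal_bonferroni(list(a = rep(3, 4), b = rep(3, 4)))
  expect_true(flat$degenerate)
  expect_equal(flat$p, 1)
  # fully separated groups: maximal H for n = 9, 3 groups
  sep <- kruskal_bonferroni(list(a = 1:3, b = 11:13, c = 21:23))
  expect_equal(sep$h, oracle_kw_h(list(1:3, 11:13, 21:23)), tolerance = 1e-9)
  expect_lt(sep$p, 0.05)
  set.seed(21)
  for (i in 1:200) {
    g <- lapply(1:3, function(.) sample(0:6, sample(4:9, 1), replace = TRUE))
    got <- kruskal_bonferroni(g)
    if (got$degenerate) next
    expect_equal(got$h, oracle_kw_h(g), tolerance = 1e-9)
    expect_true(all(got$pairwise$p_adj >= got$pairwise$p_raw - 1e-12))
    expect_true(all(got$pairwise$p_adj <= 1))
  }
  expect_error(kruskal_bonferroni(list(a = 1:3, b = numeric(0))), "empty")
})

test_that("AUC equals the Mann-Whitney U over n1 n2, including ties", {
  expect_equal(roc_auc(c(1, 2, 3), c(10, 11, 12), "lower"), 1)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3), "lower"), 0.5)
  expect_equal(roc_auc(c(1, 3), c(2, 4), "lower"), 0.75)
  # orientation: for higher-is-better metrics low patient values are worse
  expect_equal(roc_auc(c(10, 11, 12), c(1, 2, 3), "higher"), 1)
  set.seed(22)
  for (i in 1:200) {
    ctrl <- sample(0:8, sample(3:20, 1), replace = TRUE)
    pat <- sample(0:8, sample(3:20, 1), replace = TRUE)
    dirn <- sample(c("lower", "higher"), 1)
    a <- roc_auc(ctrl, pat, dirn)
    expect_equal(a, oracle_auc_enum(ctrl, pat, dirn), tolerance = 1e-12)
    # exact U-statistic identity
    s <- if (dirn == "lower") 1 else -1
    u <- suppressWarnings(stats::wilcox.test(s * pat, s * ctrl))$statistic
    expect_equal(a * length(ctrl) * length(pat), unname(u), tolerance = 1e-9)
  }
  expect_error(roc_auc(numeric(0), 1:3, "lower"), "non-empty")
})

test_that("AUC agrees with an independent ROC library", {
  set.seed(23)
  ctrl <- rnorm(40); pat <- rnorm(35, mean = 1)
  got <- roc_auc(ctrl, pat, "lower")
  ref <- pROC::auc(pROC::roc(
    response = rep(c(0, 1), c(40, 35)), predictor = c(ctrl, pat),
    direction = "<", quiet = TRUE))
  expect_equal(got, as.numeric(ref), tolerance = 1e-9)
})

test_that("confound model is exact on noiseless linear data", {
  set.seed(24)
  d <- expand.grid(subject_id = sprintf("C%02d", 1:12), trial_num = 1:5,
                   hand = c("left", "right"), stringsAsFactors = FALSE)
  d$age <- rep(sample(50:85, 12), 10)
  d$gender <- rep(sample(c("male", "female"), 12, replace = TRUE), 10)
  d$task_effect <- d$hand
  d$value <- 50 - 0.2 * (d$age - 66) + 3 * (d$gender == "male") +
    1.5 * (d$hand == "right")
  m <- suppressWarnings(fit_confound_model(d))
  expect_equal(m$c1, 0, tolerance = 1e-6)
  expect_equal(m$c2, 0, tolerance = 1e-6)
  expect_equal(m$quality, "good")
  expect_equal(m$coefficients["age", "estimate"], -0.2, tolerance = 1e-6)
})

test_that("confound removal recenters and is idempotent", {
  set.seed(25)
  n <- 24
  subj <- data.frame(subject_id = sprintf("C%02d", 1:n),
                     age = sample(50:85, n, replace = TRUE),
                     gender = sample(c("male", "female"), n, replace = TRUE),
                     stringsAsFactors = FALSE)
  d <- subj[rep(1:n, each = 8), ]
  d$hand <- rep(rep(c("left", "right"), each = 4), n)
  d$trial_num <- rep(1:4, 2 * n)
  d$task_effect <- d$hand
  d$value <- 30 - 0.15 * (d$age - 66) + 2 * (d$gender == "male") +
    rnorm(nrow(d), 0, 1) + rep(rnorm(n, 0, 2), each = 8)
  m <- fit_confound_model(d)
  adj <- adjust_values(m, d$value, d)
  # refit on adjusted values: covariate effects vanish
  d2 <- d; d2$value <- adj
  m2 <- fit_confound_model(d2)
  expect_lt(abs(m2$coefficients["age", "estimate"]), 0.02)
  expect_lt(abs(m2$coefficients["gendermale", "estimate"]), 0.2)
  # adjusting already-adjusted values changes nothing
  adj2 <- adjust_values(m2, adj, d)
  expect_equal(adj2, adj, tolerance = 0.2)
})

test_that("control-referenced z-scores are standardised and calibrated", {
  set.seed(26)
  ctrl <- rnorm(62, mean = 10, sd = 3)
  zi <- zscore_impairment(ctrl, ctrl, direction = "lower")
  expect_equal(mean(zi$z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(zi$z), 1, tolerance = 1e-9)
  expect_lt(mean(zi$impaired), 0.12)   # ~5% of controls flag themselves
  # strict inequality at the threshold
  mu <- mean(ctrl); s <- stats::sd(ctrl)
  boundary <- mu + zi$cutoff * s
  at <- zscore_impairment(boundary, ctrl, direction = "lower")
  expect_false(at$impaired)
  expect_equal(at$z, zi$cutoff, tolerance = 1e-12)
  # orientation: for higher-is-better metrics small values are impaired
  lo <- zscore_impairment(mu - 5 * s, ctrl, direction = "higher")
  expect_true(lo$impaired)
  expect_error(zscore_impairment(1, rep(2, 5)), "degenerate")
})

test_that("patients far below the norm are almost all flagged", {
  set.seed(27)
  hits <- replicate(100, {
    ctrl <- rnorm(62)
    pat <- rnorm(30, mean = 3)   # 3 SD worse, lower-is-better scale
    mean(zscore_impairment(pat, ctrl, direction = "lower")$impaired)
  })
  # analytic: P(N(3,1) > ~1.66) ~ 0.91
  expect_equal(mean(hits), pnorm(3 - 1.66), tolerance = 0.05)
})

test_that("classification agreement counts matching impairment flags", {
  expect_equal(classify_and_agree(rep(TRUE, 8), rep(30, 8), "FMA")$pct_agreement, 100)
  expect_equal(classify_and_agree(rep(TRUE, 8), rep(65, 8), "FMA")$pct_agreement, 0)
  # 30 subjects, all clinically impaired, robot agrees on 21: 70%
  ca <- classify_and_agree(rep(c(TRUE, FALSE), c(21, 9)), rep(30, 30), "FMA")
  expect_equal(ca$pct_agreement, 70)
  # kUDT threshold: impaired strictly below 2
  ck <- classify_and_agree(c(TRUE, TRUE, FALSE), c(0, 1, 2), "kUDT")
  expect_equal(ck$pct_agreement, 100)
  # missing clinical scores drop out of agreement but keep the robot call
  cm <- classify_and_agree(c(TRUE, TRUE), c(NA, 30), "FMA")
  expect_equal(cm$n, 1)
  expect_equal(cm$pct_impaired, 100)
})

test_that("correlation strength labels follow the conventional bands", {
  expect_equal(correlation_strength(c(0.05, -0.09)), rep("negligible", 2))
  expect_equal(correlation_strength(c(0.1, 0.39, -0.2)), rep("weak", 3))
  expect_equal(correlation_strength(c(0.4, -0.48, 0.69)), rep("moderate", 3))
  expect_equal(correlation_strength(c(0.7, -0.95, 1)), rep("strong", 3))
})

test_that("concurrent correlations recover monotone relationships", {
  set.seed(28)
  fma <- sample(4:65, 30, replace = TRUE)
  clin <- data.frame(FMA = fma, BBT = rnorm(30), kUDT = sample(0:2, 30, TRUE))
  cc <- concurrent_correlations(sqrt(fma) + fma^2 / 100, clin)
  expect_equal(cc$rho[cc$scale == "FMA"], 1, tolerance = 1e-9)
  expect_equal(cc$strength[cc$scale == "FMA"], "strong")
  # independent pairs are labelled negligible on average
  rhos <- replicate(200, {
    cc <- concurrent_correlations(rnorm(40), data.frame(FMA = rnorm(40)))
    cc$rho
  })
  expect_lt(abs(mean(rhos)), 0.05)
  const <- concurrent_correlations(rep(1, 10), data.frame(FMA = rnorm(10)))
  expect_true(is.na(const$rho))
})

test_that("partial Spearman separates direct from confounded association", {
  set.seed(29)
  # y = x with an irrelevant covariate: partial rho = 1
  x <- rnorm(40)
  d <- data.frame(x = x, y = x, z = rnorm(40))
  ps <- partial_spearman(d)
  expect_equal(ps$rho["x", "y"], 1, tolerance = 1e-9)
  # x and y driven only by z: marginally correlated, conditionally not
  marg <- part <- numeric(50)
  for (i in 1:50) {
    z <- rnorm(60)
    x <- z + rnorm(60, 0, 0.3)
    y <- z + rnorm(60, 0, 0.3)
    marg[i] <- oracle_spearman(x, y)
    part[i] <- partial_spearman(data.frame(x = x, y = y, z = z))$rho["x", "y"]
  }
  expect_gt(mean(marg), 0.8)
  expect_lt(abs(mean(part)), 0.1)
  # independent metrics with independent covariates: partial rho ~ 0
  nulls <- replicate(100, partial_spearman(
    as.data.frame(matrix(rnorm(40 * 4), 40)))$rho[1, 2])
  expect_lt(abs(mean(nulls)), 0.05)
  expect_error(partial_spearman(data.frame(a = 1:3, b = 1:3, c = 1:3)),
               "complete cases")
})

test_that("paired side comparison handles identical and shifted sides", {
  same <- paired_sides_test(c(1, 2, 3, 4), c(1, 2, 3, 4), "higher")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$auc, 0.5)
  # constant nonzero difference: zero-variance edge case, flagged
  shifted <- paired_sides_test(1:10 + 5, 1:10, "lower")
  expect_true(shifted$degenerate)
  expect_equal(shifted$p, 0)
  # simulated shift: power close to the analytic paired-t prediction
  set.seed(30)
  n <- 12; delta <- 1; sigma <- 1.2
  hits <- replicate(400, {
    base <- rnorm(n, sd = 2)
    a <- base + delta + rnorm(n, 0, sigma)
    b <- base + rnorm(n, 0, sigma)
    paired_sides_test(a, b, "lower")$p < 0.05
  })
  analytic <- stats::power.t.test(n = n, delta = delta,
                                  sd = sqrt(2) * sigma,
                                  type = "paired")$power
  expect_equal(mean(hits), analytic, tolerance = 0.07)
})
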