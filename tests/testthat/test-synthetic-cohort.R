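# Synthetic cohort generator.

test_that("cohorts are reproducible and match the design counts", {
  cfg <- generator_config()
  a <- sample_cohort(cfg, 42)
  b <- sample_cohort(cfg, 42)
  expect_identical(a, b)
  expect_false(identical(a, sample_cohort(cfg, 43)))
  expect_equal(sum(a$group == "stroke"), 30)
  expect_equal(sum(a$group == "control"), 31)
  expect_true(all(a$handedness[a$group == "control"] == "right"))
  expect_true(all(is.na(a$FMA[a$group == "control"])))
  expect_true(all(a$FMA[a$group == "stroke"] >= 0 &
                    a$FMA[a$group == "stroke"] <= 66))
  expect_true(all(a$kUDT[a$group == "stroke"] %in% 0:2))
  sim1 <- simulate_trials(a[c(1, 40), ], cfg, 42)
  sim2 <- simulate_trials(a[c(1, 40), ], cfg, 42)
  expect_identical(sim1$trials, sim2$trials)
})

test_that("trial counts per assessment follow the protocol", {
  cfg <- generator_config()
  subj <- sample_cohort(cfg, 3)
  sim <- simulate_trials(subj[c(2, 33), ], cfg, 3)
  tr <- sim$trials
  counts <- table(tr$subject_id, tr$session, tr$task)
  for (task in c("matching", "reaching", "rom", "force", "tracking")) {
    per_cell <- counts[, , task]
    per_cell <- per_cell[per_cell > 0]
    # both sides pooled: twice the per-side count
    expect_true(all(per_cell ==
      2 * protocol_constants()$trial_counts[[task]]))
  }
  # stroke: 2 sessions x 2 sides; control: 1 session x 2 hands
  expect_setequal(unique(tr$session[tr$group == "stroke"]), 1:2)
  expect_setequal(unique(tr$session[tr$group == "control"]), 1)
  expect_setequal(unique(tr$side[tr$group == "stroke"]),
                  c("affected", "less_affected"))
  expect_setequal(unique(tr$side[tr$group == "control"]), c("left", "right"))
})

test_that("at most 40% of stroke subjects have intact proprioception", {
  cfg <- generator_config()
  fracs <- vapply(1:30, function(s) {
    subj <- sample_cohort(cfg, s)
    mean(subj$kUDT[subj$group == "stroke"] == 2)
  }, 1)
  expect_true(all(fracs <= 0.4))
})

test_that("clinical scores are monotone in the latent severities", {
  cfg <- generator_config()
  set.seed(31)
  n <- 500
  subj <- data.frame(group = rep("stroke", n),
                     s_motor = runif(n), s_proprio = runif(n))
  sc <- simulate_clinical_scores(subj, cfg)
  expect_lt(cor(subj$s_motor, sc$FMA, method = "spearman"), -0.8)
  expect_lt(cor(subj$s_proprio, sc$kUDT, method = "spearman"), -0.5)
  # intact motor function scores near the FMA ceiling
  intact <- data.frame(group = "stroke", s_motor = 0, s_proprio = 0)
  fmas <- replicate(50, simulate_clinical_scores(intact, cfg)$FMA)
  expect_gt(mean(fmas >= 60), 0.8)
  # severe proprioceptive loss drives kUDT to the floor
  severe <- data.frame(group = "stroke", s_motor = 1, s_proprio = 1)
  kudts <- replicate(50, simulate_clinical_scores(severe, cfg)$kUDT)
  expect_gt(mean(kudts == 0), 0.8)
})

test_that("an intact noiseless subject performs perfectly and identically across sessions", {
  cfg <- generator_config(noise = 0)
  subj <- data.frame(subject_id = "S01", group = "stroke", age = 65,
                     gender = "male", handedness = "right",
                     affected_side = "right", s_motor = 0, s_proprio = 0,
                     FMA = 66, kUDT = 2, BBT_affected = 60,
                     BBT_less_affected = 60, MoCA = 30, MAS = 0,
                     stringsAsFactors = FALSE)
  s1 <- simulate_session(subj, "affected", 1, cfg, seed = 1)$trials
  s2 <- simulate_session(subj, "affected", 2, cfg, seed = 1)$trials
  ae <- position_matching_error(
    s1$presented_deg[s1$task == "matching"],
    s1$reported_deg[s1$task == "matching"])
  expect_equal(ae$value, 0)
  expect_equal(s1$value[s1$task == "tracking"], rep(0, 6), tolerance = 1e-9)
  expect_equal(s1$value[!is.na(s1$value)], s2$value[!is.na(s2$value)],
               tolerance = 1e-12)
  # trace mode: perfect tracking and an exactly realised velocity pulse
  cfg$trace_fs_hz <- 200
  tr <- simulate_session(subj, "affected", 1, cfg, seed = 1, mode = "trace")
  track <- tr$traces[grep("tracking", names(tr$traces))[1]][[1]]
  expect_lt(tracking_rmse(track$target_deg, track$position_deg), 1e-6)
})

test_that("metric expectations degrade monotonically with severity", {
  cfg <- generator_config(noise = 0)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  means <- matrix(NA, length(grid), 9,
                  dimnames = list(NULL, generator_config()$metrics$metric))
  for (g in seq_along(grid)) {
    vals <- sapply(1:120, function(i) {
      subj <- data.frame(subject_id = sprintf("S%03d", i), group = "stroke",
                         age = 66, gender = "male", handedness = "right",
                         affected_side = "right",
                         s_motor = grid[g], s_proprio = grid[g],
                         stringsAsFactors = FALSE)
      tr <- simulate_session(subj, "affected", 1, cfg, seed = i)$trials
      mt <- extract_metrics(tr)
      mt$value[match(colnames(means), mt$metric)]
    })
    means[g, ] <- rowMeans(vals)
  }
  for (m in colnames(means)) {
    trend <- diff(means[, m])
    if (metric_direction(m) == "lower") expect_true(all(trend > -1e-9))
    else expect_true(all(trend < 1e-9))
  }
})

test_that("null preset makes stroke and control distributions indistinguishable", {
  cfg <- generator_config("null")
  ctrl_vals <- list(); strk_vals <- list()
  for (s in 1:8) {
    subj <- sample_cohort(cfg, s)
    sim <- simulate_trials(subj, cfg, s)
    mt <- extract_metrics(sim$trials)
    mt$group <- subj$group[match(mt$subject_id, subj$subject_id)]
    m1 <- mt[mt$session == 1, ]
    for (metric in unique(m1$metric)) {
      ctrl_vals[[metric]] <- c(ctrl_vals[[metric]],
        m1$value[m1$group == "control" & m1$metric == metric])
      strk_vals[[metric]] <- c(strk_vals[[metric]],
        m1$value[m1$group == "stroke" & m1$metric == metric &
                   m1$side == "affected"])
    }
  }
  ps <- vapply(names(ctrl_vals), function(m)
    suppressWarnings(stats::ks.test(ctrl_vals[[m]], strk_vals[[m]])$p.value), 1)
  expect_gt(min(ps), 0.01)
})

test_that("trace-mode signals reproduce the programmed trial outcomes", {
  cfg <- generator_config(trace_fs_hz = 250)
  subj <- sample_cohort(cfg, 9)
  # a control hand stays inside the workspace, so extraction should recover
  # the programmed scalars closely
  ctrl <- subj[subj$group == "control", ][2, ]
  met <- simulate_session(ctrl, "right", 1, cfg, seed = 9)$trials
  sim <- simulate_trials(ctrl, cfg, 9, mode = "trace")
  ext <- extract_trial_scalars(sim)
  key <- function(d) paste(d$side, d$session, d$task, d$condition, d$trial_idx)
  ext1 <- ext[ext$side == "right" & ext$session == 1, ]
  met <- met[match(key(ext1), key(met)), ]
  for (task in c("rom", "force", "tracking")) {
    i <- ext1$task == task
    expect_equal(ext1$value[i], met$value[i], tolerance = 0.1)
  }
  i <- ext1$task == "reaching"
  expect_gt(cor(ext1$value[i], met$value[i]), 0.9)
  # on a severely affected side the device's mechanical stop can only
  # reduce the measured peak velocity, never raise it
  severe <- subj[subj$group == "stroke", ][which.max(subj$s_motor[subj$group == "stroke"]), ]
  met_s <- simulate_session(severe, "affected", 1, cfg, seed = 9)$trials
  sim_s <- simulate_trials(severe, cfg, 9, mode = "trace")
  ext_s <- extract_trial_scalars(sim_s)
  e1 <- ext_s[ext_s$side == "affected" & ext_s$session == 1 &
                ext_s$task == "reaching", ]
  m1 <- met_s[met_s$side == "affected" & met_s$session == 1 &
                met_s$task == "reaching", ]
  m1 <- m1[match(paste(e1$condition, e1$trial_idx),
                 paste(m1$condition, m1$trial_idx)), ]
  expect_true(all(e1$value <= m1$value * 1.02))
})

test_that("datasets round-trip through CSV export", {
  cfg <- generator_config()
  subj <- sample_cohort(cfg, 12)
  sim <- simulate_trials(subj[c(1:3, 31:33), ], cfg, 12)
  dir <- tempfile("ds")
  export_dataset(sim, dir)
  back <- read_dataset(dir)
  expect_equal(back$trials$value, sim$trials$value, tolerance = 1e-9)
  expect_equal(back$subjects$subject_id, sim$subjects$subject_id)
  expect_equal(dim(back$trials), dim(sim$trials))
  # closed-form row count: 59 trials per side-session, stroke 2x2, control 2x1
  full <- simulate_trials(subj, cfg, 12)
  expect_equal(nrow(full$trials), 59 * (30 * 4 + 31 * 2))
  unlink(dir, recursive = TRUE)
})

test_that("variance components injected by simulate_panel are recoverable", {
  set.seed(32)
  res <- replicate(150, {
    p <- simulate_panel(n = 30, m = 4, sigma_subject = 1,
                        sigma_error = 0.4, sigma_trial = 0.8)
    c(icc_a_k(p)$icc, sem_srd(p)$sem)
  })
  analytic_icc <- 1 / (1 + (0.4^2 + 0.8^2 / 4) / 2)
  expect_equal(mean(res[1, ]), analytic_icc, tolerance = 0.03)
  expect_equal(mean(res[2, ]), sqrt(0.4^2 + 0.8^2 / 4), tolerance = 0.05)
})
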