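# Synthetic cohort generator.
#
# Generates virtual control and stroke cohorts with the statistical structure
# the clinimetric analysis assumes: two latent severities (motor and
# proprioceptive) drive the assessment metrics and the simulated clinical
# scores; metrics carry between-subject, between-session and within-session
# (trial) variance components; age, gender and tested hand act as confounds
# on the motor metrics; the matching error grows with the presented angle.
#
# Two generation modes exist: a fast "metric" mode that draws per-trial
# scalar responses directly (for Monte-Carlo statistics), and a "trace" mode
# that synthesises raw position/velocity/force signals so the signal
# conditioning and metric extraction are genuinely exercised.

# E[mean of 3 largest of 10 lognormal(meanlog = -s^2/2, sdlog = s)] at
# s = 0.25, and the relative SD of that aggregate; order-statistic constants
# used to keep the top-3-of-10 reaching aggregate unbiased (precomputed
# numerically, 3e5 draws).
.TOP3_LN_MEAN <- 1.28048
.TOP3_LN_RELSD <- 0.10859

#' Generator configuration
#'
#' Builds the configuration of the synthetic cohort generator.  The
#' `"paper_like"` preset targets the published affected-side metric
#' distributions of a sub-acute stroke cohort (e.g. position matching
#' absolute error 14.63 +/- 6.43 deg, maximum extension velocity
#' 149.06 +/- 146.27 deg/s, active ROM 43.89 +/- 36.20 deg, maximum flexion
#' force 11.64 +/- 11.55 N, slow tracking RMSE 21.09 +/- 8.68 deg) together
#' with cohort demographics (30 stroke subjects aged 64.5 +/- 14.0 years,
#' 31 controls aged 66.9 +/- 7.9).  Control-hand metric distributions are
#' synthetic plausibility calibrations (no published control table is
#' reproduced) chosen to imply the published discrimination (AUC) levels.
#'
#' The `"null"` preset sets all severities to zero so stroke and control
#' metric distributions coincide; `"high_noise"` doubles the within-subject
#' variance components.
#'
#' @param preset `"paper_like"`, `"null"` or `"high_noise"`.
#' @param n_stroke,n_control Cohort sizes (>= 2).
#' @param noise Global scale on all stochastic components; 0 gives a
#'   noiseless deterministic cohort (error metrics collapse to 0 for intact
#'   subjects).
#' @param shift_frac Named numeric or single number: relative session-2
#'   offset per metric (fraction of the metric level; default 0).
#' @param la_frac Severity fraction expressed on the less-affected side.
#' @param trace_fs_hz Sampling rate used by trace mode.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(preset = c("paper_like", "null", "high_noise"),
                             n_stroke = 30, n_control = 31,
                             noise = 1, shift_frac = 0, la_frac = 0.4,
                             trace_fs_hz = 1000) {
  preset <- match.arg(preset)
  stopifnot(n_stroke >= 2, n_control >= 2, noise >= 0)
  metrics <- data.frame(
    metric = c("AE", "VelFlex", "VelExt", "AROM", "PROM",
               "ForceFlex", "ForceExt", "RMSESlow", "RMSEFast"),
    # control-hand distributions: synthetic plausibility calibration
    control_mean = c(4.5, 600, 450, 80, 89, 32, 10, 9.5, 10.5),
    control_sd = c(2.0, 110, 110, 10, 5, 10, 5, 3.0, 3.0),
    # stroke affected-side targets (published test-session means/SDs)
    stroke_mean = c(14.63, 314.94, 149.06, 43.89, 83.88,
                    11.64, 4.12, 21.09, 21.45),
    stroke_sd = c(6.43, 180.30, 146.27, 36.20, 10.48,
                  11.55, 4.52, 8.68, 7.80),
    # relative measurement error of the session-level outcome, calibrated
    # from the published smallest real differences: SEM = SRD/(1.96 sqrt 2),
    # expressed relative to the stroke target mean
    within_cv = c(0.225, 0.183, 0.147, 0.128, 0.038,
                  0.151, 0.245, 0.157, 0.148),
    # within-session trial-to-trial coefficient of variation; the matching
    # task is mechanistic (half-normal per-trial errors), marked NA
    trial_cv = c(NA, 0.25, 0.25, 0.12, 0.05, 0.15, 0.15, 0.18, 0.18),
    # latent severity loadings
    # physical caps (device workspace, gauge range, plausible maxima)
    cap = c(50, 1500, 1500, 90, 90, 60, 30, 45, 45),
    w_motor = c(0, 1, 1, 1, 1, 1, 1, 0.35, 0.55),
    w_proprio = c(1, 0, 0, 0, 0, 0, 0, 0.65, 0.45),
    stringsAsFactors = FALSE
  )
  if (preset == "high_noise") {
    metrics$within_cv <- 2 * metrics$within_cv
    metrics$trial_cv <- 2 * metrics$trial_cv
  }
  # per-metric severity ratio r: solves E[r^(2s)] = stroke_mean/control_mean
  metrics$sev_ratio <- vapply(seq_len(nrow(metrics)), function(i) {
    target <- metrics$stroke_mean[i] / metrics$control_mean[i]
    stats::uniroot(function(r) exp_unif_moment(r, 2) - target,
                   interval = c(1e-4, 1e4), tol = 1e-10)$root
  }, numeric(1))
  sf <- rep(0, nrow(metrics)); names(sf) <- metrics$metric
  if (length(shift_frac) == 1L && is.null(names(shift_frac)))
    sf[] <- shift_frac
  else sf[names(shift_frac)] <- shift_frac
  metrics$shift_frac <- unname(sf)
  structure(list(
    preset = preset,
    n_stroke = n_stroke, n_control = n_control,
    noise = noise,
    metrics = metrics,
    la_frac = la_frac,
    # demographics
    stroke_age = c(mean = 64.50, sd = 14.02),
    control_age = c(mean = 66.87, sd = 7.92),
    p_male_stroke = 19 / 30, p_male_control = 20 / 31,
    p_left_handed_stroke = 4 / 30,
    # at most this fraction of stroke subjects with intact proprioception
    kudt_intact_max = 0.4,
    # correlation of the motor and proprioceptive severities
    severity_cor = 0.4,
    # correlation of a subject's metric-specific quantile with the shared
    # subject-level quantile (idiosyncratic scatter between metrics)
    metric_cor = 0.5,
    # confound coefficients on motor metrics (age centred at 66 years;
    # gender and hand effects centred at the population shares)
    confounds = list(
      age_center = 66,
      age = c(ForceFlex = -0.10, ForceExt = -0.04),
      gender_male = c(ForceFlex = 4.0, ForceExt = 1.5,
                      VelFlex = 40, VelExt = 30),
      hand_right = c(VelFlex = 15, VelExt = 10, AROM = 2, PROM = 1,
                     ForceFlex = 0.8, ForceExt = 0.3),
      angle_slope = 0.25   # relative matching-error increase per 10 deg
    ),
    trace_fs_hz = trace_fs_hz
  ), class = "generator_config")
}

# gamma quantile parameterised by mean and sd
qgamma_ms <- function(p, mean, sd) {
  shape <- (mean / sd)^2
  stats::qgamma(p, shape = shape, rate = shape / mean)
}

# CDF of w1*U1 + w2*U2 (independent uniforms, w1 + w2 = 1); uniformises the
# weighted severity so quantile maps receive a uniform variate
unif_sum_cdf <- function(x, w1, w2) {
  if (w1 < w2) { tmp <- w1; w1 <- w2; w2 <- tmp }
  if (w2 < 1e-9) return(pmin(pmax(x / w1, 0), 1))
  ifelse(x <= 0, 0,
  ifelse(x >= w1 + w2, 1,
  ifelse(x < w2, x^2 / (2 * w1 * w2),
  ifelse(x < w1, (2 * x - w2) / (2 * w1),
         1 - (w1 + w2 - x)^2 / (2 * w1 * w2)))))
}

#' Sample a virtual cohort
#'
#' Draws stroke and control subject profiles: demographics, the latent
#' motor and proprioceptive severities of the stroke subjects (spanning mild
#' to severe), and simulated clinical scores.  The cohort honours the design
#' constraint that at most `kudt_intact_max` (default 40%) of stroke subjects
#' have intact proprioception (kUDT = 2).  Reproducible: the same seed gives
#' the same cohort.
#'
#' @param config A [generator_config()].
#' @param seed Integer master seed.
#' @return Data frame with one row per subject: `subject_id`, `group`,
#'   `age`, `gender`, `handedness`, `affected_side`, `s_motor`, `s_proprio`,
#'   `FMA`, `kUDT`, `BBT_affected`, `BBT_less_affected`, `MoCA`, `MAS`.
#' @export
sample_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(sub_seed(seed, "cohort"), {
    ns <- config$n_stroke; nc <- config$n_control
    clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    rho <- config$severity_cor
    z1 <- stats::rnorm(ns); z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(ns)
    s_motor <- stats::pnorm(z1)
    s_proprio <- stats::pnorm(z2)
    if (config$preset == "null") s_motor <- s_proprio <- rep(0, ns)
    subjects <- data.frame(
      subject_id = c(sprintf("S%02d", seq_len(ns)), sprintf("C%02d", seq_len(nc))),
      group = rep(c("stroke", "control"), c(ns, nc)),
      age = round(c(
        clamp(stats::rnorm(ns, config$stroke_age["mean"], config$stroke_age["sd"]), 20, 95),
        clamp(stats::rnorm(nc, config$control_age["mean"], config$control_age["sd"]), 50, 92))),
      gender = c(
        ifelse(stats::runif(ns) < config$p_male_stroke, "male", "female"),
        ifelse(stats::runif(nc) < config$p_male_control, "male", "female")),
      handedness = c(
        ifelse(stats::runif(ns) < config$p_left_handed_stroke, "left", "right"),
        rep("right", nc)),
      affected_side = c(sample(c("left", "right"), ns, replace = TRUE),
                        rep(NA_character_, nc)),
      s_motor = c(s_motor, rep(0, nc)),
      s_proprio = c(s_proprio, rep(0, nc)),
      stringsAsFactors = FALSE
    )
    # enforce the proprioception inclusion constraint: redraw intact
    # subjects' proprioceptive severity until at most 40% score kUDT = 2
    scores <- simulate_clinical_scores(subjects, config)
    if (config$preset != "null") {
      for (attempt in 1:25) {
        is_stroke <- subjects$group == "stroke"
        intact <- is_stroke & !is.na(scores$kUDT) & scores$kUDT == 2
        if (mean(intact[is_stroke]) <= config$kudt_intact_max) break
        worst <- which(intact)
        redraw <- sample(worst, ceiling(length(worst) / 4))
        subjects$s_proprio[redraw] <- stats::runif(length(redraw), 0.4, 1)
        scores <- simulate_clinical_scores(subjects, config)
      }
    }
    cbind(subjects, scores)
  })
}

#' Simulate clinical scores from latent severities
#'
#' Monotone noisy maps from the latent severities to the clinical ranges:
#' FMA (0-66, decreasing in motor severity), kUDT (0-2, decreasing in
#' proprioceptive severity), BBT per side, MoCA (0-30) and MAS.  Control
#' subjects receive `NA` (clinical testing is part of the patient protocol
#' only).
#'
#' @param subjects Data frame with `group`, `s_motor`, `s_proprio`.
#' @param config A [generator_config()].
#' @return Data frame with columns `FMA`, `kUDT`, `BBT_affected`,
#'   `BBT_less_affected`, `MoCA`, `MAS`.
#' @export
simulate_clinical_scores <- function(subjects, config) {
  n <- nrow(subjects)
  stroke <- subjects$group == "stroke"
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  sm <- subjects$s_motor; sp <- subjects$s_proprio
  noise <- config$noise
  out <- data.frame(
    FMA = round(clamp(66 * (1 - sm) + noise * stats::rnorm(n, 0, 5), 0, 66)),
    kUDT = clamp(round(2.4 * (1 - sp) + noise * stats::rnorm(n, 0, 0.45)), 0, 2),
    BBT_affected = round(clamp(60 * (1 - 1.05 * sm - 0.25 * sp) +
                                 noise * stats::rnorm(n, 0, 6), 0, 80)),
    BBT_less_affected = round(clamp(66 - 12 * sm + noise * stats::rnorm(n, 0, 8),
                                    0, 90)),
    MoCA = round(clamp(30 - 14 * stats::runif(n) * ifelse(stroke, 1, 0.5) +
                         noise * stats::rnorm(n, 0, 2.5), 0, 30)),
    MAS = ifelse(stats::runif(n) < 0.93, 0, sample(1:3, n, replace = TRUE))
  )
  out[!stroke, ] <- NA
  out
}

# Expected (pre-noise) metric level for one subject side.
# Severity scales the per-subject metric mean multiplicatively:
# m(s) = control_mean * r^(2 s), with the ratio r calibrated per metric so
# that a uniform affected-side severity mix averages exactly to the stroke
# target mean (E[r^(2s)] = (r^2 - 1)/(2 log r) for s ~ U(0, 1)).  The map is
# strictly positive and monotone in severity; residual between-subject
# spread interpolates from the control SD so the null preset reproduces the
# control distribution exactly.
metric_level <- function(cfgm, s_eff, u) {
  r <- cfgm$sev_ratio
  m <- cfgm$control_mean * r^(2 * s_eff)
  var_m <- cfgm$control_mean^2 *
    (exp_unif_moment(r, 4) - exp_unif_moment(r, 2)^2)
  excess <- 0.75 * (cfgm$stroke_sd^2 - cfgm$control_sd^2 - var_m)
  # residual spread: bounded by the stroke target SD and by a coefficient of
  # variation of 1.2, so severely impaired subjects scatter in proportion to
  # their (small) expected level rather than in absolute control units
  sdev <- pmin(sqrt(cfgm$control_sd^2 + (2 * s_eff)^2 * pmax(excess, 0)),
               cfgm$stroke_sd, 1.2 * m)
  pmin(qgamma_ms(u, m, sdev), cfgm$cap)
}

# E[r^(k s)] for s ~ U(0, 1)
exp_unif_moment <- function(r, k) {
  if (abs(r - 1) < 1e-9) 1 else (r^k - 1) / (k * log(r))
}

# subject-side-level expected metric values (before confounds and noise)
subject_metric_base <- function(subject, side_severity_frac, config, seed) {
  cm <- config$metrics
  with_seed(seed, {
    z_subj <- stats::rnorm(1)
    rho <- config$metric_cor
    vals <- numeric(nrow(cm))
    for (i in seq_len(nrow(cm))) {
      w1 <- cm$w_proprio[i]; w2 <- cm$w_motor[i]
      s_eff <- side_severity_frac *
        (w1 * subject$s_proprio + w2 * subject$s_motor)
      # severity-linked quantile with idiosyncratic metric scatter
      z_im <- rho * z_subj + sqrt(1 - rho^2) * stats::rnorm(1)
      u <- stats::pnorm(z_im)
      v <- metric_level(cm[i, ], s_eff, u)
      # noiseless configurations collapse error metrics to perfect
      # performance for intact subjects
      if (cm$metric[i] %in% c("AE", "RMSESlow", "RMSEFast"))
        v <- v * max(config$noise, s_eff)
      vals[i] <- v
    }
    names(vals) <- cm$metric
    vals
  })
}

# additive confound offsets for one subject side, per metric
confound_offsets <- function(subject, hand, config) {
  cf <- config$confounds
  cm <- config$metrics
  off <- stats::setNames(numeric(nrow(cm)), cm$metric)
  add <- function(coefs, x) {
    off[names(coefs)] <<- off[names(coefs)] + coefs * x
  }
  add(cf$age, subject$age - cf$age_center)
  add(cf$gender_male, (subject$gender == "male") - 0.63)
  add(cf$hand_right, (hand == "right") - 0.5)
  off
}

# session-level multiplicative noise factor; lognormal, mean 1
session_factor <- function(cfgm_row, noise) {
  agg_rel <- switch(cfgm_row$metric,
    AE = sqrt(pi / 2 - 1) / sqrt(21),               # half-normal trials
    VelFlex = , VelExt = .TOP3_LN_RELSD * cfgm_row$trial_cv / 0.25,
    cfgm_row$trial_cv / sqrt(3))
  s2 <- sqrt(pmax(cfgm_row$within_cv^2 - agg_rel^2, 0.1 * cfgm_row$within_cv^2))
  s2 <- s2 * noise
  exp(stats::rnorm(1, -s2^2 / 2, s2))
}

# lognormal per-trial multipliers, mean 1
trial_factors <- function(n, cv, noise) {
  s <- cv * noise
  exp(stats::rnorm(n, -s^2 / 2, s))
}

#' Simulate one assessment session for one subject side
#'
#' Generates the trial-level responses of all five tasks for one subject,
#' one side and one session: 21 position-matching trials (reported angle =
#' presented angle plus a proprioceptive error whose spread grows with the
#' presented-angle magnitude), 10 reaching trials per direction (per-trial
#' peak velocities), 3 active and 3 passive ROM repetitions, 3 force trials
#' per direction and 3 tracking trials per trajectory speed.  Session 2
#' applies the configured systematic shift.  In `"trace"` mode, raw signal
#' traces are synthesised for the reaching, ROM, force and tracking trials
#' (see [simulate_trial_trace()]) and the scalar `value` column is left to
#' be recovered by [extract_trial_scalars()].
#'
#' @param subject One-row data frame from [sample_cohort()].
#' @param side `"affected"`/`"less_affected"` (stroke) or `"right"`/`"left"`
#'   (control).
#' @param session Session index (1 or 2).
#' @param config A [generator_config()].
#' @param seed Master seed; substreams are derived per subject, side,
#'   session and task.
#' @param mode `"metric"` (fast scalar draws) or `"trace"`.
#' @return List with `trials` (data frame) and, in trace mode, `traces`
#'   (named list of per-trial data frames).
#' @export
simulate_session <- function(subject, side, session, config, seed,
                             mode = c("metric", "trace")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "generator_config"), nrow(subject) == 1L)
  cm <- config$metrics
  sev_frac <- if (subject$group == "control") 0
              else if (side == "affected") 1 else config$la_frac
  hand <- if (subject$group == "control") side
          else if (side == "affected") subject$affected_side
          else setdiff(c("left", "right"), subject$affected_side)
  base <- subject_metric_base(subject, sev_frac, config,
                              sub_seed(seed, subject$subject_id, side, "base"))
  # confound effects cannot push a level below a small positive floor, but
  # the floor never raises a level above its pre-confound value (an exact
  # zero stays zero in noiseless configurations)
  base <- pmax(base + confound_offsets(subject, hand, config),
               pmin(0.02 * cm$control_mean, base))
  s_eff_track <- sev_frac * (0.65 * subject$s_proprio + 0.35 * subject$s_motor)
  rows <- list(); traces <- list()
  with_seed(sub_seed(seed, subject$subject_id, side, session, "trials"), {
    v_sess <- stats::setNames(numeric(nrow(cm)), cm$metric)
    for (i in seq_len(nrow(cm))) {
      v <- base[i] * session_factor(cm[i, ], config$noise)
      if (session == 2) v <- v * (1 + cm$shift_frac[i])
      v_sess[i] <- v
    }
    mkrow <- function(task, condition, idx, value = NA_real_,
                      presented = NA_real_, reported = NA_real_) {
      data.frame(subject_id = subject$subject_id, group = subject$group,
                 side = side, hand = hand, session = session, task = task,
                 condition = condition, trial_idx = idx, value = value,
                 presented_deg = presented, reported_deg = reported,
                 stringsAsFactors = FALSE)
    }
    # gauge position matching: mechanistic half-normal errors, spread
    # increasing with presented-angle magnitude
    ang <- sample(10:30)
    w <- 1 + config$confounds$angle_slope * (ang - 20) / 10
    sigma_k <- v_sess["AE"] * sqrt(pi / 2) * w
    reported <- ang + stats::rnorm(21, 0, sigma_k)
    rows$matching <- mkrow("matching", "none", 1:21,
                           presented = ang, reported = reported)
    # fast target reaching: per-trial peak velocities
    for (dir in c("flexion", "extension")) {
      metric <- if (dir == "flexion") "VelFlex" else "VelExt"
      j <- match(metric, cm$metric)
      peaks <- (v_sess[metric] / .TOP3_LN_MEAN) *
        trial_factors(10, cm$trial_cv[j], config$noise)
      rows[[paste0("reach_", dir)]] <- mkrow("reaching", dir, 1:10, value = peaks)
    }
    # range of motion: per-repetition ROM
    for (md in c("active", "passive")) {
      metric <- if (md == "active") "AROM" else "PROM"
      j <- match(metric, cm$metric)
      reps <- v_sess[metric] * trial_factors(3, cm$trial_cv[j], config$noise)
      rows[[paste0("rom_", md)]] <- mkrow("rom", md, 1:3, value = reps)
    }
    # maximum force: per-trial peak force
    for (dir in c("flexion", "extension")) {
      metric <- if (dir == "flexion") "ForceFlex" else "ForceExt"
      j <- match(metric, cm$metric)
      peaks <- v_sess[metric] * trial_factors(3, cm$trial_cv[j], config$noise)
      rows[[paste0("force_", dir)]] <- mkrow("force", dir, 1:3, value = peaks)
    }
    # trajectory following: per-trial RMSE
    for (sp in c("slow", "fast")) {
      metric <- if (sp == "slow") "RMSESlow" else "RMSEFast"
      j <- match(metric, cm$metric)
      rmse <- v_sess[metric] * trial_factors(3, cm$trial_cv[j], config$noise)
      rows[[paste0("track_", sp)]] <- mkrow("tracking", sp, 1:3, value = rmse)
    }
    if (mode == "trace") {
      trials <- do.call(rbind, rows)
      for (r in seq_len(nrow(trials))) {
        tk <- trials$task[r]
        if (tk == "matching") next
        id <- paste(trials$subject_id[r], side, session, tk,
                    trials$condition[r], trials$trial_idx[r], sep = "|")
        traces[[id]] <- simulate_trial_trace(
          task = tk, condition = trials$condition[r],
          value = trials$value[r],
          s_motor = sev_frac * subject$s_motor, s_eff = s_eff_track,
          config = config)
        trials$value[r] <- NA_real_   # to be recovered by extraction
      }
      rows <- list(trials)
    }
  })
  list(trials = do.call(rbind, rows), traces = if (mode == "trace") traces)
}

#' Simulate trial-level data for a whole cohort
#'
#' Runs [simulate_session()] for every subject, side and session: stroke
#' subjects contribute both sides in two sessions (test and retest),
#' controls contribute both hands in a single session.
#'
#' @param subjects Cohort from [sample_cohort()].
#' @param config A [generator_config()].
#' @param seed Master seed.
#' @param mode `"metric"` or `"trace"`.
#' @return List of class `hand_sim` with `trials` (long data frame),
#'   `traces` (trace mode only), `subjects` and `config`.
#' @export
simulate_trials <- function(subjects, config, seed = 1,
                            mode = c("metric", "trace")) {
  mode <- match.arg(mode)
  all_rows <- list(); all_traces <- list()
  for (i in seq_len(nrow(subjects))) {
    subj <- subjects[i, ]
    sides <- if (subj$group == "stroke") c("affected", "less_affected")
             else c("right", "left")
    sessions <- if (subj$group == "stroke") 1:2 else 1L
    for (side in sides) for (sess in sessions) {
      out <- simulate_session(subj, side, sess, config, seed, mode = mode)
      all_rows[[length(all_rows) + 1L]] <- out$trials
      if (mode == "trace") all_traces <- c(all_traces, out$traces)
    }
  }
  structure(list(trials = do.call(rbind, all_rows),
                 traces = if (mode == "trace") all_traces,
                 subjects = subjects, config = config, seed = seed),
            class = "hand_sim")
}

#' Synthesise one raw trial trace
#'
#' Builds the raw signal of a single trial from its programmed scalar
#' outcome and the behavioural parameters implied by severity:
#' \itemize{
#' \item reaching: bell-shaped velocity pulse whose peak equals the
#'   programmed per-trial peak, time-to-peak lengthening with motor severity
#'   (122 ms intact to ~198 ms severe), position integrated and saturated at
#'   the device workspace;
#' \item rom: smooth flexion-extension excursion realising the programmed
#'   per-repetition ROM (75% of the excursion in flexion);
#' \item force: sigmoid rise to a plateau at the programmed peak;
#' \item tracking: response = centre + gain x (target(t - lag) - centre) +
#'   low-frequency wander, with gain dropping and lag growing with the
#'   sensorimotor severity and the wander amplitude chosen to realise the
#'   programmed trial RMSE.
#' }
#'
#' @param task `"reaching"`, `"rom"`, `"force"` or `"tracking"`.
#' @param condition Task condition (direction, mode or speed).
#' @param value Programmed per-trial scalar outcome.
#' @param s_motor,s_eff Severity inputs for behavioural parameters.
#' @param config A [generator_config()] (sampling rate, noise).
#' @return Data frame with `time_s` and the task's signal columns
#'   (`position_deg`, `velocity_degps`, `force_n`, `target_deg` as
#'   applicable).
#' @export
simulate_trial_trace <- function(task, condition, value, s_motor = 0,
                                 s_eff = 0, config = generator_config()) {
  fs <- config$trace_fs_hz
  noise <- config$noise
  if (task == "reaching") {
    stim <- reaching_stimulus(condition)
    t <- seq(0, stim$window_s, by = 1 / fs)
    lat <- 0.3
    ttp <- max(0.122 + 0.076 * s_motor + noise * stats::rnorm(1, 0, 0.02), 0.06)
    width <- ttp / 2.2
    sgn <- if (condition == "flexion") 1 else -1
    vel <- sgn * value * exp(-(t - (lat + ttp))^2 / (2 * width^2))
    pos <- clip_workspace(stim$start_deg + cumsum(vel) / fs)
    vel_meas <- c(0, diff(pos)) * fs
    data.frame(time_s = t, position_deg = as.numeric(pos),
               velocity_degps = vel_meas)
  } else if (task == "rom") {
    t <- seq(0, 4, by = 1 / fs)
    flex_max <- min(0.75 * value, 60)
    ext_min <- flex_max - value
    # 0 -> flexion max -> extension min -> 0, smooth half-cosine segments
    seg <- function(a, b, n) a + (b - a) * (1 - cos(pi * seq(0, 1, length.out = n))) / 2
    n3 <- floor(length(t) / 3)
    pos <- c(seg(0, flex_max, n3), seg(flex_max, ext_min, n3),
             seg(ext_min, 0, length(t) - 2 * n3))
    data.frame(time_s = t, position_deg = as.numeric(clip_workspace(pos)))
  } else if (task == "force") {
    t <- seq(0, 3, by = 1 / fs)
    sgn <- if (condition == "flexion") 1 else -1
    rise <- 1 / (1 + exp(-(t - 0.5) / 0.08))
    f <- sgn * value * rise * (1 + noise * 0.01 * sin(2 * pi * 6 * t))
    data.frame(time_s = t, force_n = f)
  } else if (task == "tracking") {
    spec <- trajectory_spec(condition)
    tgt <- generate_target_trajectory(spec, fs)
    gain <- 1 - 0.4 * s_eff
    lag <- 0.5 * s_eff
    nlag <- round(lag * fs)
    lagged <- c(rep(tgt$position_deg[1], nlag),
                tgt$position_deg)[seq_along(tgt$position_deg)]
    det <- spec$center_deg + gain * (lagged - spec$center_deg)
    rms_det <- sqrt(mean((det - tgt$position_deg)^2))
    wander_sd <- sqrt(max(value^2 - rms_det^2, 0))
    if (wander_sd > 0) {
      w <- lowpass(stats::rnorm(length(det)), cutoff_hz = 0.5, fs_hz = fs)
      w <- w / sqrt(mean(w^2))
      # workspace saturation clips part of the wander; rescale a few times so
      # the realised trial RMSE approaches the programmed value where the
      # workspace allows it
      k <- wander_sd
      for (it in 1:4) {
        resp <- clip_workspace(det + k * w)
        realised <- sqrt(mean((resp - tgt$position_deg)^2))
        if (realised >= value * 0.98 || k > 6 * wander_sd) break
        k <- k * min(value / max(realised, 1e-9), 1.8)
      }
      resp <- clip_workspace(det + k * w)
    } else resp <- clip_workspace(det)
    data.frame(time_s = tgt$time_s, target_deg = tgt$position_deg,
               position_deg = as.numeric(resp))
  } else stop("unknown task: ", task, call. = FALSE)
}

#' Recover per-trial scalars from simulated traces
#'
#' Runs the metric-extraction path on the raw traces of a trace-mode
#' simulation: velocity traces are low-pass filtered and peak-rectified,
#' ROM is taken as the position excursion, force as the rectified peak and
#' tracking error as the RMSE between target and response.  Fills the
#' `value` column of the trial table.
#'
#' @param sim A `hand_sim` from [simulate_trials()] (trace mode).
#' @return The trial data frame with `value` completed.
#' @export
extract_trial_scalars <- function(sim) {
  stopifnot(inherits(sim, "hand_sim"), !is.null(sim$traces))
  trials <- sim$trials
  fs <- sim$config$trace_fs_hz
  for (r in seq_len(nrow(trials))) {
    tk <- trials$task[r]
    if (tk == "matching") next
    id <- paste(trials$subject_id[r], trials$side[r], trials$session[r],
                tk, trials$condition[r], trials$trial_idx[r], sep = "|")
    tr <- sim$traces[[id]]
    if (is.null(tr)) next
    trials$value[r] <- switch(tk,
      reaching = peak_velocity(tr$velocity_degps, trials$condition[r],
                               filter = TRUE, fs_hz = fs),
      rom = max(tr$position_deg) - min(tr$position_deg),
      force = max((if (trials$condition[r] == "flexion") 1 else -1) *
                    lowpass(tr$force_n, fs_hz = fs)),
      tracking = tracking_rmse(tr$target_deg, tr$position_deg))
  }
  trials
}

#' Export / read a simulated dataset as CSV
#'
#' Writes the trial table and subject table to `trials.csv` and
#' `subjects.csv` in `dir`; [read_dataset()] reads them back so that the
#' round trip is lossless up to floating-point text formatting.
#'
#' @param sim A `hand_sim` (or a list with `trials` and `subjects`).
#' @param dir Output directory (created if needed).
#' @return `export_dataset` returns the two file paths invisibly;
#'   `read_dataset` returns `list(trials, subjects)`.
#' @export
export_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ft <- file.path(dir, "trials.csv"); fs_ <- file.path(dir, "subjects.csv")
  utils::write.csv(sim$trials, ft, row.names = FALSE)
  utils::write.csv(sim$subjects, fs_, row.names = FALSE)
  invisible(c(trials = ft, subjects = fs_))
}

#' @rdname export_dataset
#' @export
read_dataset <- function(dir) {
  list(trials = utils::read.csv(file.path(dir, "trials.csv"),
                                stringsAsFactors = FALSE),
       subjects = utils::read.csv(file.path(dir, "subjects.csv"),
                                  stringsAsFactors = FALSE))
}

#' Simulate a test-retest panel with known variance components
#'
#' Direct additive-model panel generator for variance-component studies,
#' independent of the cohort generator: subject effects, a random
#' between-session (day) effect, an optional fixed retest shift,
#' session-level error and trial-level error:
#' `y_ijt = mu + b_i + c_j + shift * [j = 2] + e_ij + eps_ijt`.
#' The analytic absolute-agreement average-measures ICC over `k = 2`
#' sessions is `sigma_b^2 / (sigma_b^2 + (sigma_c^2 + sigma_e^2 +
#' sigma_t^2 / m) / k)` (for zero shift); the error SD of the session-level
#' outcome excluding the session main effect (the quantity [sem_srd()]
#' estimates) is `sqrt(sigma_e^2 + sigma_t^2 / m)`.
#'
#' @param n Subjects.
#' @param m Trials per subject per session.
#' @param sigma_subject,sigma_session,sigma_error,sigma_trial SDs of the
#'   between-subject, between-session (random day effect), session-level
#'   error and trial-level components.
#' @param shift Fixed value added in session 2.
#' @param mu Grand mean.
#' @param seed Optional seed.
#' @return A [measurement_panel()] carrying the trial-level values.
#' @export
simulate_panel <- function(n = 30, m = 1, sigma_subject = 1,
                           sigma_session = 0, sigma_error = 0.5,
                           sigma_trial = 0, shift = 0, mu = 0, seed = NULL) {
  gen <- function() {
    b <- stats::rnorm(n, 0, sigma_subject)
    cday <- stats::rnorm(2, 0, sigma_session)
    trials <- expand.grid(trial = seq_len(m), session = 1:2, subject = seq_len(n))
    e <- stats::rnorm(2 * n, 0, sigma_error)   # session-level error, per cell
    cell <- (trials$subject - 1) * 2 + trials$session
    trials$trial_value <- mu + b[trials$subject] + cday[trials$session] +
      shift * (trials$session == 2) +
      e[cell] + stats::rnorm(nrow(trials), 0, sigma_trial)
    sm <- tapply(trials$trial_value, list(trials$subject, trials$session), mean)
    measurement_panel(sm[, 1], sm[, 2],
                      trials = trials[c("subject", "session", "trial_value")])
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
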