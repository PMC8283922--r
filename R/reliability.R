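# Test-retest reliability statistics: ICC(A,k), SEM/SRD, systematic shift,
# Bland-Altman limits of agreement and test-retest Spearman correlation.

#' Construct a test-retest measurement panel
#'
#' A panel holds, for one metric on one body side, each subject's session-1
#' and session-2 values (session means) and optionally the underlying
#' trial-level values.  Trial-level values, when present, refine the standard
#' error of measurement (see [sem_srd()]) and define the pooled range used to
#' normalise SRD% and the systematic shift.
#'
#' @param session1,session2 Numeric vectors of per-subject session means
#'   (same subject order).
#' @param trials Optional data frame `subject, session, trial_value` with the
#'   trial-level values behind the session means.
#' @param metric Optional metric name (used to orient the systematic shift
#'   via [metric_direction()]).
#' @return An object of class `measurement_panel`.
#' @export
measurement_panel <- function(session1, session2, trials = NULL, metric = NULL) {
  if (length(session1) != length(session2))
    stop("sessions must be paired per subject", call. = FALSE)
  ok <- is.finite(session1) & is.finite(session2)
  session1 <- session1[ok]; session2 <- session2[ok]
  if (length(session1) < 2L)
    stop("a panel needs at least 2 subjects", call. = FALSE)
  if (!is.null(trials))
    stopifnot(all(c("subject", "session", "trial_value") %in% names(trials)))
  structure(list(session1 = session1, session2 = session2,
                 trials = trials, metric = metric,
                 n = length(session1)),
            class = "measurement_panel")
}

# pooled values defining the observed range of a metric: all trial-level
# values across subjects and sessions when available, session means otherwise
panel_pooled_values <- function(panel) {
  if (!is.null(panel$trials)) panel$trials$trial_value
  else c(panel$session1, panel$session2)
}

# two-way (subject x session) mean squares on the session-mean matrix
panel_mean_squares <- function(panel) {
  x <- cbind(panel$session1, panel$session2)
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  res <- x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm
  mse <- sum(res^2) / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Intraclass correlation ICC(A,k)
#'
#' Absolute-agreement, average-measures intraclass correlation from a two-way
#' random-effects ANOVA (subjects x sessions) on the session-level values:
#' \deqn{ICC(A,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n)}
#' where \eqn{MS_R}, \eqn{MS_C} and \eqn{MS_E} are the subject, session and
#' error mean squares and \eqn{n} the number of subjects.  The confidence
#' interval is the F-distribution-based interval of the single-measures
#' absolute-agreement form, stepped up to k measurements with the
#' Spearman-Brown relation (McGraw-Wong style).
#'
#' Values above 0.7 are conventionally taken as acceptable test-retest
#' reliability for this kind of assessment metric.
#'
#' @param panel A [measurement_panel()].
#' @param alpha Confidence level is `1 - alpha` (default 0.05).
#' @return List with `icc`, `ci_low`, `ci_high`, the mean squares, and
#'   `defined` (FALSE for degenerate zero-variance panels, where `icc` is NA).
#' @export
icc_a_k <- function(panel, alpha = 0.05) {
  stopifnot(inherits(panel, "measurement_panel"))
  ms <- panel_mean_squares(panel)
  n <- ms$n; k <- ms$k
  tot <- stats::var(c(panel$session1, panel$session2))
  if (!is.finite(tot) || tot <= .Machine$double.eps)
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                ms = ms, defined = FALSE))
  icc <- (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / n)
  # single-measures form and its F-based interval, then Spearman-Brown step-up
  icc1 <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
  a <- k * icc1 / (n * (1 - icc1))
  b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
  v <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  f_u <- stats::qf(1 - alpha / 2, n - 1, v)
  f_l <- stats::qf(1 - alpha / 2, v, n - 1)
  l1 <- n * (ms$msr - f_u * ms$mse) /
    (f_u * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  u1 <- n * (f_l * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * f_l * ms$msr)
  sb <- function(r) r * k / (1 + (k - 1) * r)
  list(icc = icc, ci_low = sb(l1), ci_high = sb(u1), ms = ms, defined = TRUE)
}

#' Standard error of measurement and smallest real difference
#'
#' The SEM is the square root of the measurement-error variance of the
#' primary outcome, `sqrt(MS_E)` from the two-way (subject x session) ANOVA
#' behind [icc_a_k()].  When trial-level values are present they are
#' accounted for through a nested decomposition: the pooled within-cell
#' (trial replicate) variance `sigma_trial^2` is estimated, the session-level
#' error in excess of the trial-averaging share is
#' `sigma_session^2 = MS_E - sigma_trial^2 / m`, and the two components are
#' reported alongside the SEM.  With `basis = "aggregate"` (default) the SEM
#' quantifies the error of the session aggregate,
#' `SEM^2 = sigma_session^2 + sigma_trial^2 / m`; with `basis = "trial"` it
#' quantifies a single-trial measurement, `SEM^2 = sigma_session^2 +
#' sigma_trial^2`.
#'
#' The smallest real difference is `SRD = 1.96 * sqrt(2) * SEM`, and SRD% is
#' SRD as a percentage of the observed range (max - min) of the pooled
#' trial-level values across all subjects and both sessions.  An SRD% below
#' 30 is conventionally taken to indicate acceptable measurement error.
#'
#' @param panel A [measurement_panel()].
#' @param basis `"aggregate"` (error of the session-level outcome) or
#'   `"trial"` (error of a single trial).
#' @return List with `sem`, `srd`, `srd_pct`, `range`, the nested components
#'   `sigma_trial` and `sigma_session`, and `defined` (`srd_pct` is NA when
#'   the observed range is zero).
#' @export
sem_srd <- function(panel, basis = c("aggregate", "trial")) {
  basis <- match.arg(basis)
  stopifnot(inherits(panel, "measurement_panel"))
  ms <- panel_mean_squares(panel)
  sigma_t <- NA_real_
  if (!is.null(panel$trials)) {
    tr <- panel$trials
    cell <- interaction(tr$subject, tr$session, drop = TRUE)
    m_bar <- mean(tabulate(cell))
    dev <- tr$trial_value - stats::ave(tr$trial_value, cell)
    df_w <- nrow(tr) - nlevels(cell)
    sigma_t2 <- if (df_w > 0) sum(dev^2) / df_w else 0
    sigma_s2 <- max(ms$mse - sigma_t2 / m_bar, 0)
    sigma_t <- sqrt(sigma_t2)
    sem <- if (basis == "trial") sqrt(sigma_s2 + sigma_t2)
           else sqrt(sigma_s2 + sigma_t2 / m_bar)
  } else {
    sigma_s2 <- ms$mse
    sem <- sqrt(ms$mse)
  }
  srd <- 1.96 * sqrt(2) * sem
  rng <- diff(range(panel_pooled_values(panel)))
  list(sem = sem, srd = srd,
       srd_pct = if (rng > 0) 100 * srd / rng else NA_real_,
       range = rng, sigma_trial = sigma_t, sigma_session = sqrt(sigma_s2),
       defined = rng > 0)
}

#' Systematic shift between test and retest
#'
#' The mean test-to-retest difference as a percentage of the observed range
#' of the metric, oriented so that a positive shift means worse performance
#' on retest and a negative shift means improvement (a learning effect).
#' Shifts within [-6.35, 6.35] are conventionally taken to indicate the
#' absence of a strong learning effect.
#'
#' @param panel A [measurement_panel()].  If the panel carries a `metric`
#'   name, the sign is oriented via [metric_direction()]; otherwise
#'   higher-is-better is assumed for the raw difference `session2 - session1`
#'   only when `direction` says so.
#' @param direction Override for the direction of better performance
#'   (`"higher"` or `"lower"`).
#' @return Signed shift in percent of the range (NA when the range is zero).
#' @export
systematic_shift <- function(panel, direction = NULL) {
  stopifnot(inherits(panel, "measurement_panel"))
  if (is.null(direction))
    direction <- if (!is.null(panel$metric)) metric_direction(panel$metric)
                 else "lower"
  s <- if (direction == "lower") 1 else -1   # worseness = s * (T2 - T1)
  rng <- diff(range(panel_pooled_values(panel)))
  if (rng <= 0) return(NA_real_)
  100 * s * mean(panel$session2 - panel$session1) / rng
}

#' Bland-Altman agreement statistics
#'
#' Mean test-retest difference and 95% limits of agreement
#' (`mean +- 1.96 * SD` of the per-subject differences), plus the per-subject
#' (mean, difference) pairs for plotting.
#'
#' @param panel A [measurement_panel()].
#' @return List with `mean_diff`, `sd_diff`, `loa_low`, `loa_high` and a data
#'   frame `pairs` with columns `mean` and `diff`.
#' @export
bland_altman <- function(panel) {
  stopifnot(inherits(panel, "measurement_panel"))
  d <- panel$session2 - panel$session1
  m <- (panel$session1 + panel$session2) / 2
  sd_d <- stats::sd(d)
  list(mean_diff = mean(d), sd_diff = sd_d,
       loa_low = mean(d) - 1.96 * sd_d, loa_high = mean(d) + 1.96 * sd_d,
       pairs = data.frame(mean = m, diff = d))
}

#' Test-retest Spearman correlation
#'
#' Spearman rank-order correlation between the session-1 and session-2 values
#' with tie-corrected (mid-)ranks, and its two-sided p-value.
#'
#' @param panel A [measurement_panel()].
#' @return List with `rho`, `p` and `defined` (FALSE when either session is
#'   constant, in which case the correlation is undefined).
#' @export
test_retest_spearman <- function(panel) {
  stopifnot(inherits(panel, "measurement_panel"))
  if (panel$n < 3L) stop("Spearman correlation needs at least 3 pairs", call. = FALSE)
  if (stats::sd(panel$session1) == 0 || stats::sd(panel$session2) == 0)
    return(list(rho = NA_real_, p = NA_real_, defined = FALSE))
  ct <- suppressWarnings(stats::cor.test(panel$session1, panel$session2,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, defined = TRUE)
}

#' Full reliability report for one panel
#'
#' Runs all test-retest statistics on one panel and evaluates the
#' conventional decision rules: ICC > 0.7, SRD% < 30 and |shift| <= 6.35
#' (strict inequalities for ICC and SRD%, inclusive bounds for the shift).
#'
#' @param panel A [measurement_panel()].
#' @param alpha Alpha for the ICC confidence interval.
#' @return A one-row data frame with descriptive statistics per session,
#'   ICC and CI, SEM, SRD, SRD%, shift, Bland-Altman fields, Spearman rho/p
#'   and the logical flags `icc_ok`, `srd_ok`, `shift_ok`.
#' @export
reliability_stats <- function(panel, alpha = 0.05) {
  icc <- icc_a_k(panel, alpha = alpha)
  ss <- sem_srd(panel)
  shift <- systematic_shift(panel)
  ba <- bland_altman(panel)
  rho <- test_retest_spearman(panel)
  data.frame(
    n = panel$n,
    mean_t1 = mean(panel$session1), sd_t1 = stats::sd(panel$session1),
    mean_t2 = mean(panel$session2), sd_t2 = stats::sd(panel$session2),
    mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
    icc = icc$icc, icc_ci_low = icc$ci_low, icc_ci_high = icc$ci_high,
    sem = ss$sem, srd = ss$srd, srd_pct = ss$srd_pct,
    shift_pct = shift,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    rho = rho$rho, rho_p = rho$p,
    icc_ok = isTRUE(icc$icc > 0.7),
    srd_ok = isTRUE(ss$srd_pct < 30),
    shift_ok = isTRUE(abs(shift) <= 6.35)
  )
}

#' Test-retest reliability report across all metrics
#'
#' Builds one [measurement_panel()] per metric from a metric table (and the
#' trial table, when given, for trial-level SEM and pooled ranges) and
#' returns one row of [reliability_stats()] per metric.
#'
#' @param metric_table Data frame from [extract_metrics()].
#' @param trials Optional trial-level data frame (see
#'   [trial_metric_values()]); enables the trial-informed SEM and pooled
#'   range normalisation.
#' @param side Which side to analyse (a value of `metric_table$side`).
#' @param sessions Length-2 vector naming test and retest session (default
#'   `c(1, 2)`).
#' @return Data frame, one row per metric, columns as [reliability_stats()]
#'   plus `metric` and `side`.
#' @export
reliability_report <- function(metric_table, trials = NULL, side = "affected",
                               sessions = c(1, 2)) {
  mt <- metric_table[metric_table$side == side, ]
  tv <- if (!is.null(trials)) {
    x <- trial_metric_values(trials)
    x[x$side == side, ]
  } else NULL
  out <- list()
  for (metric in unique(mt$metric)) {
    m1 <- mt[mt$metric == metric & mt$session == sessions[1], ]
    m2 <- mt[mt$metric == metric & mt$session == sessions[2], ]
    common <- intersect(m1$subject_id, m2$subject_id)
    if (length(common) < 2L) next
    s1 <- m1$value[match(common, m1$subject_id)]
    s2 <- m2$value[match(common, m2$subject_id)]
    tr <- if (!is.null(tv)) {
      z <- tv[tv$metric == metric & tv$subject_id %in% common &
                tv$session %in% sessions, ]
      data.frame(subject = z$subject_id, session = z$session,
                 trial_value = z$trial_value)
    } else NULL
    panel <- measurement_panel(s1, s2, trials = tr, metric = metric)
    row <- reliability_stats(panel)
    row <- cbind(data.frame(metric = metric, side = side,
                            stringsAsFactors = FALSE), row)
    out[[metric]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
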