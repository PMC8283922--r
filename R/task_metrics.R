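# Extraction of each task's primary outcome measure from trial-level data.
#
# Nine metrics are produced by the five-task battery:
#   AE                          position matching absolute error (deg, lower better)
#   VelFlex / VelExt            maximum reaching velocity per direction (deg/s)
#   AROM / PROM                 active / passive range of motion (deg)
#   ForceFlex / ForceExt        maximum fingertip force per direction (N)
#   RMSESlow / RMSEFast         trajectory tracking error per speed (deg, lower better)

#' Metric catalogue
#'
#' Names, units, task of origin and the direction of better performance for
#' the nine primary outcome measures of the assessment battery.
#'
#' @return A data frame with columns `metric`, `task`, `condition`, `unit`,
#'   `direction_of_better` (`"higher"` or `"lower"`) and `category`
#'   (`"sensory"`, `"motor"`, `"sensorimotor"`).
#' @export
metric_catalogue <- function() {
  data.frame(
    metric = c("AE", "VelFlex", "VelExt", "AROM", "PROM",
               "ForceFlex", "ForceExt", "RMSESlow", "RMSEFast"),
    task = c("matching", "reaching", "reaching", "rom", "rom",
             "force", "force", "tracking", "tracking"),
    condition = c("none", "flexion", "extension", "active", "passive",
                  "flexion", "extension", "slow", "fast"),
    unit = c("deg", "deg/s", "deg/s", "deg", "deg", "N", "N", "deg", "deg"),
    direction_of_better = c("lower", "higher", "higher", "higher", "higher",
                            "higher", "higher", "lower", "lower"),
    category = c("sensory", "motor", "motor", "motor", "motor",
                 "motor", "motor", "sensorimotor", "sensorimotor"),
    stringsAsFactors = FALSE
  )
}

#' Direction of better performance for a metric
#'
#' @param metric Metric name(s) from [metric_catalogue()].
#' @return Character vector, `"higher"` or `"lower"` per metric.
#' @export
metric_direction <- function(metric) {
  cat_ <- metric_catalogue()
  out <- cat_$direction_of_better[match(metric, cat_$metric)]
  if (anyNA(out)) stop("unknown metric: ",
                       paste(metric[is.na(out)], collapse = ", "), call. = FALSE)
  out
}

#' Position matching absolute error
#'
#' Per-trial error is the absolute difference between the reported and the
#' presented angle; the primary outcome (AE) is the mean absolute error over
#' the 21 trials of one assessment.
#'
#' @param presented_deg Presented target angles (deg).
#' @param reported_deg Reported (gauge-indicated) angles (deg), same length.
#' @return List with `metric` (`"AE"`), `value` (mean absolute error, deg),
#'   `per_trial` (absolute errors) and `n_trials`.
#' @export
#' @examples
#' position_matching_error(c(10, 20, 30), c(12, 18, 33))$value  # 7/3
position_matching_error <- function(presented_deg, reported_deg) {
  if (length(presented_deg) == 0L) stop("empty input", call. = FALSE)
  if (length(presented_deg) != length(reported_deg))
    stop("`presented_deg` and `reported_deg` must have equal length", call. = FALSE)
  if (length(presented_deg) < 21L)
    warning("fewer than 21 matching trials; AE computed over available trials",
            call. = FALSE)
  e <- abs(reported_deg - presented_deg)
  list(metric = "AE", value = mean(e), per_trial = e,
       n_trials = length(e))
}

# mean of the k largest values
top_k_mean <- function(x, k) mean(sort(x, decreasing = TRUE)[seq_len(min(k, length(x)))])

#' Per-trial peak reaching velocity
#'
#' Rectifies the velocity trace toward the movement direction (flexion
#' positive, extension negative) and returns its peak.  The trace is expected
#' to be low-pass filtered (see [lowpass()]); set `filter = TRUE` to filter
#' here.
#'
#' @param velocity_degps Velocity trace (deg/s).
#' @param direction `"flexion"` or `"extension"`.
#' @param filter Apply the 20 Hz first-order low-pass before peak detection?
#' @param fs_hz Sampling rate, used only when `filter = TRUE`.
#' @return Peak velocity toward the target (deg/s, nonnegative for any
#'   movement toward the target).
#' @export
peak_velocity <- function(velocity_degps, direction = c("flexion", "extension"),
                          filter = FALSE, fs_hz = 1000) {
  direction <- match.arg(direction)
  v <- if (filter) lowpass(velocity_degps, fs_hz = fs_hz) else velocity_degps
  s <- if (direction == "flexion") 1 else -1
  max(s * v)
}

#' Maximum velocity metric of the fast target reaching task
#'
#' The primary outcome per movement direction is the mean of the three
#' largest per-trial peak velocities over the 10 trials of that direction.
#'
#' @param peaks Per-trial peak velocities (deg/s), one per trial, or a list of
#'   velocity traces from which peaks are extracted via [peak_velocity()].
#' @param direction `"flexion"` or `"extension"` (used for the metric name and
#'   for rectifying traces).
#' @param ... Passed to [peak_velocity()] when `peaks` is a list of traces.
#' @return List with `metric` (`"VelFlex"` or `"VelExt"`), `value`,
#'   `per_trial` peaks and `n_trials`; `value` is `NA` (flagged `missing`)
#'   with fewer than 3 valid trials.
#' @export
#' @examples
#' max_velocity(seq(10, 100, by = 10), "flexion")$value  # 90
max_velocity <- function(peaks, direction = c("flexion", "extension"), ...) {
  direction <- match.arg(direction)
  if (is.list(peaks))
    peaks <- vapply(peaks, peak_velocity, numeric(1), direction = direction, ...)
  peaks <- peaks[is.finite(peaks)]
  metric <- if (direction == "flexion") "VelFlex" else "VelExt"
  if (length(peaks) < 3L)
    return(list(metric = metric, value = NA_real_, per_trial = peaks,
                n_trials = length(peaks), missing = TRUE))
  list(metric = metric, value = top_k_mean(peaks, 3L), per_trial = peaks,
       n_trials = length(peaks), missing = FALSE)
}

#' Range of motion metric
#'
#' Per repetition, the range of motion is the difference between the maximum
#' position reached in flexion and the maximum position reached in extension
#' (i.e. `max - min` of the position trace, deg).  The primary outcome
#' (AROM or PROM) is the mean over the three repetitions.
#'
#' @param reps Either a list of position traces (one per repetition) or a
#'   numeric vector of per-repetition ROM values.
#' @param mode `"active"` or `"passive"`.
#' @return List with `metric` (`"AROM"`/`"PROM"`), `value`, `per_trial` ROMs
#'   and `n_trials`.
#' @export
#' @examples
#' range_of_motion(list(c(-10, 40), c(-5, 45), c(-15, 50)), "active")$value
range_of_motion <- function(reps, mode = c("active", "passive")) {
  mode <- match.arg(mode)
  rom <- if (is.list(reps))
    vapply(reps, function(p) max(p) - min(p), numeric(1))
  else reps
  rom <- rom[is.finite(rom)]
  if (length(rom) == 0L) stop("no valid repetitions", call. = FALSE)
  if (length(rom) < 3L)
    warning("fewer than 3 repetitions; ROM averaged over available reps",
            call. = FALSE)
  list(metric = if (mode == "active") "AROM" else "PROM",
       value = mean(rom), per_trial = rom, n_trials = length(rom))
}

#' Maximum fingertip force metric
#'
#' Per trial, the peak of the direction-rectified force trace; the primary
#' outcome per direction is the mean of the three per-trial peaks (N).
#'
#' @param traces A list of force traces (N) or a numeric vector of per-trial
#'   peak forces.
#' @param direction `"flexion"` or `"extension"` (flexion positive sign
#'   convention, as for positions).
#' @return List with `metric` (`"ForceFlex"`/`"ForceExt"`), `value`,
#'   `per_trial` peaks and `n_trials`; `NA` value when no trial is available.
#' @export
#' @examples
#' max_force(c(10, 12, 14), "flexion")$value  # 12
max_force <- function(traces, direction = c("flexion", "extension")) {
  direction <- match.arg(direction)
  s <- if (direction == "flexion") 1 else -1
  peaks <- if (is.list(traces))
    vapply(traces, function(f) max(s * f), numeric(1))
  else traces
  peaks <- peaks[is.finite(peaks)]
  metric <- if (direction == "flexion") "ForceFlex" else "ForceExt"
  if (length(peaks) == 0L)
    return(list(metric = metric, value = NA_real_, per_trial = peaks,
                n_trials = 0L, missing = TRUE))
  list(metric = metric, value = mean(peaks), per_trial = peaks,
       n_trials = length(peaks), missing = FALSE)
}

#' Per-trial tracking error (RMSE)
#'
#' Root mean squared deviation between the displayed target trajectory and
#' the performed motion over the full 30-second trial.
#'
#' @param target_deg Target trajectory samples (deg).
#' @param response_deg Performed-motion samples on the same time base (deg).
#' @return RMSE in degrees.
#' @export
#' @examples
#' tracking_rmse(rep(15, 100), rep(20, 100))  # 5
tracking_rmse <- function(target_deg, response_deg) {
  if (length(target_deg) != length(response_deg))
    stop("target and response must share one time base", call. = FALSE)
  if (length(target_deg) == 0L) stop("empty input", call. = FALSE)
  sqrt(mean((response_deg - target_deg)^2))
}

#' Tracking-error metric of the trajectory-following task
#'
#' The primary outcome per trajectory speed is the mean of the per-trial RMSE
#' values over the three trials of that speed.
#'
#' @param rmse Per-trial RMSE values (deg).
#' @param speed `"slow"` or `"fast"`.
#' @return List with `metric` (`"RMSESlow"`/`"RMSEFast"`), `value`,
#'   `per_trial` and `n_trials`.
#' @export
tracking_metric <- function(rmse, speed = c("slow", "fast")) {
  speed <- match.arg(speed)
  rmse <- rmse[is.finite(rmse)]
  if (length(rmse) == 0L) stop("no valid tracking trials", call. = FALSE)
  list(metric = if (speed == "slow") "RMSESlow" else "RMSEFast",
       value = mean(rmse), per_trial = rmse, n_trials = length(rmse))
}

# ---- long-table extraction ------------------------------------------------

#' Per-trial metric values from a trial table
#'
#' Converts a long trial table (one row per trial) into per-trial metric
#' contributions: the absolute matching error for `AE`, the per-trial peak
#' velocity/force, the per-repetition ROM and the per-trial tracking RMSE.
#' These trial-level values feed the reliability analysis, whose range
#' normalisations pool "all trials of a task".
#'
#' The table must have columns `subject_id`, `side`, `session`, `task`,
#' `condition`, `trial_idx` and either `value` (per-trial scalar) or, for the
#' matching task, `presented_deg`/`reported_deg`.
#'
#' @param trials Trial-level data frame (see Details).
#' @return Data frame `subject_id, side, session, metric, trial_idx,
#'   trial_value`.
#' @export
trial_metric_values <- function(trials) {
  stopifnot(all(c("subject_id", "side", "session", "task",
                  "condition", "trial_idx") %in% names(trials)))
  cat_ <- metric_catalogue()
  key <- paste(trials$task, trials$condition)
  metric <- cat_$metric[match(key, paste(cat_$task, cat_$condition))]
  if (anyNA(metric))
    stop("unrecognised task/condition combination: ",
         paste(unique(key[is.na(metric)]), collapse = ", "), call. = FALSE)
  v <- if ("value" %in% names(trials)) trials$value else rep(NA_real_, nrow(trials))
  m <- trials$task == "matching"
  if (any(m)) {
    if (!all(c("presented_deg", "reported_deg") %in% names(trials)))
      stop("matching trials need `presented_deg` and `reported_deg`", call. = FALSE)
    v[m] <- abs(trials$reported_deg[m] - trials$presented_deg[m])
  }
  data.frame(subject_id = trials$subject_id, side = trials$side,
             session = trials$session, metric = metric,
             trial_idx = trials$trial_idx, trial_value = v,
             stringsAsFactors = FALSE)
}

#' Extract the metric table from a trial table
#'
#' Aggregates per-trial values to one primary outcome per subject, side,
#' session and metric, using each task's aggregation rule: mean absolute
#' error over 21 trials (AE), mean of the three largest per-trial peaks
#' (VelFlex/VelExt), mean over three repetitions (AROM/PROM, ForceFlex/
#' ForceExt, RMSESlow/RMSEFast).  Missing trials degrade gracefully: the
#' aggregate uses the available trials and `n_trials` records how many.
#'
#' @param trials Trial-level data frame, see [trial_metric_values()].
#' @return The metric table: data frame `subject_id, side, session, metric,
#'   value, n_trials`.
#' @export
extract_metrics <- function(trials) {
  tv <- trial_metric_values(trials)
  keys <- unique(tv[c("subject_id", "side", "session", "metric")])
  idx <- match(paste(tv$subject_id, tv$side, tv$session, tv$metric),
               paste(keys$subject_id, keys$side, keys$session, keys$metric))
  agg <- function(vals, metric) {
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0L) return(NA_real_)
    if (metric %in% c("VelFlex", "VelExt")) {
      if (length(vals) < 3L) return(NA_real_)
      top_k_mean(vals, 3L)
    } else mean(vals)
  }
  groups <- split(tv$trial_value, factor(idx, levels = seq_len(nrow(keys))))
  keys$value <- unlist(Map(agg, groups, keys$metric), use.names = FALSE)
  keys$n_trials <- vapply(groups, function(v) sum(is.finite(v)), integer(1),
                          USE.NAMES = FALSE)
  rownames(keys) <- NULL
  keys
}
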