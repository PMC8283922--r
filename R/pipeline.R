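# Pipeline orchestration: simulate -> extract -> reliability -> validity ->
# independence -> report bundle, with input validation and a text summary.

#' Discriminant / concurrent validity report
#'
#' For every metric: Kruskal-Wallis omnibus and Bonferroni-corrected pairwise
#' comparisons between controls (both hands pooled), the affected and the
#' less-affected side of stroke subjects; ROC AUCs for the three group
#' pairs; a paired t-test between the two stroke sides; normative z-score
#' impairment classification against the control reference (confound-removed
#' for motor-category metrics by default, see [fit_confound_model()]);
#' classification agreement with the clinical thresholds (FMA < 60,
#' kUDT < 2); and Spearman correlations of the affected-side values with
#' FMA, BBT and kUDT.
#'
#' @param metric_table From [extract_metrics()].
#' @param subjects Subject table (see [sample_cohort()] for the schema).
#' @param trials Optional trial-level table; required for confound-model
#'   fitting (trial-level control data).
#' @param session Session used for between-group comparisons (default 1).
#' @param adjust Which metric categories get confound removal before
#'   z-scoring: `"motor"` (default), `"all"` or `"none"`.
#' @param zscore_threshold Passed to [zscore_impairment()] (default the
#'   one-sided normative limit).
#' @return List with `table` (one row per metric), `confound_models`
#'   (per-task model summaries) and `impairment` (per-subject calls).
#' @export
validity_report <- function(metric_table, subjects, trials = NULL,
                            session = 1, adjust = c("motor", "all", "none"),
                            zscore_threshold = "normative") {
  adjust <- match.arg(adjust)
  cat_ <- metric_catalogue()
  mt <- metric_table[metric_table$session == session, ]
  mt$group <- subjects$group[match(mt$subject_id, subjects$subject_id)]

  # confound models fitted per task on control trial-level data
  models <- list()
  if (!is.null(trials) && adjust != "none") {
    tv <- trial_metric_values(trials)
    tv$group <- subjects$group[match(tv$subject_id, subjects$subject_id)]
    tv$hand <- trials$hand
    tv$condition <- trials$condition
    tv$presented_deg <- trials$presented_deg
    ctrl <- tv[tv$group == "control" & is.finite(tv$trial_value), ]
    ctrl$age <- subjects$age[match(ctrl$subject_id, subjects$subject_id)]
    ctrl$gender <- subjects$gender[match(ctrl$subject_id, subjects$subject_id)]
    for (task in unique(cat_$task)) {
      d <- ctrl[cat_$task[match(ctrl$metric, cat_$metric)] == task, ]
      if (nrow(d) < 20L) next
      d$value <- d$trial_value
      d$task_effect <- if (task == "matching") d$presented_deg else d$condition
      d$trial_num <- d$trial_idx
      models[[task]] <- fit_confound_model(d)
    }
  }

  adjusted_values <- function(metric, rows) {
    task <- cat_$task[cat_$metric == metric]
    category <- cat_$category[cat_$metric == metric]
    use_adj <- !is.null(models[[task]]) &&
      (adjust == "all" || (adjust == "motor" && category == "motor"))
    if (!use_adj) return(rows$value)
    covs <- data.frame(
      age = subjects$age[match(rows$subject_id, subjects$subject_id)],
      gender = subjects$gender[match(rows$subject_id, subjects$subject_id)],
      hand = rows$hand,
      task_effect = if (task == "matching") 20 else
        cat_$condition[cat_$metric == metric],
      trial_num = mean(seq_len(protocol_constants()$trial_counts[[task]])),
      stringsAsFactors = FALSE)
    adjust_values(models[[task]], rows$value, covs)
  }

  # hand of each metric row (needed for confound adjustment)
  if (!is.null(trials)) {
    key_tr <- paste(trials$subject_id, trials$side)
    mt$hand <- trials$hand[match(paste(mt$subject_id, mt$side), key_tr)]
  } else {
    mt$hand <- ifelse(mt$group == "control", mt$side, NA)
  }

  stroke_ids <- subjects$subject_id[subjects$group == "stroke"]
  rows <- list(); impairment <- list()
  for (metric in unique(mt$metric)) {
    dirn <- metric_direction(metric)
    category <- cat_$category[cat_$metric == metric]
    m <- mt[mt$metric == metric & is.finite(mt$value), ]
    ctrl <- m[m$group == "control", ]
    aff <- m[m$side == "affected", ]
    la <- m[m$side == "less_affected", ]
    if (nrow(ctrl) == 0L || nrow(aff) == 0L) next
    kw <- kruskal_bonferroni(list(control = ctrl$value, affected = aff$value,
                                  less_affected = la$value))
    pw <- function(a, b) {
      i <- which(kw$pairwise$group1 == a & kw$pairwise$group2 == b)
      if (length(i)) kw$pairwise$p_adj[i] else NA_real_
    }
    # paired side comparison
    both <- intersect(aff$subject_id, la$subject_id)
    pst <- if (length(both) >= 2)
      paired_sides_test(aff$value[match(both, aff$subject_id)],
                        la$value[match(both, la$subject_id)], dirn)
    else list(t = NA, p = NA, auc = NA)
    # z-score impairment against the (adjusted) control reference
    ctrl_adj <- adjusted_values(metric, ctrl)
    zi_aff <- zscore_impairment(adjusted_values(metric, aff), ctrl_adj,
                                direction = dirn, threshold = zscore_threshold)
    zi_la <- zscore_impairment(adjusted_values(metric, la), ctrl_adj,
                               direction = dirn, threshold = zscore_threshold)
    imp_aff <- stats::setNames(zi_aff$impaired, aff$subject_id)
    impairment[[metric]] <- data.frame(
      metric = metric, subject_id = c(aff$subject_id, la$subject_id),
      side = c(aff$side, la$side), z = c(zi_aff$z, zi_la$z),
      impaired = c(zi_aff$impaired, zi_la$impaired), stringsAsFactors = FALSE)
    # classification agreement with clinical thresholds
    si <- match(aff$subject_id, subjects$subject_id)
    ag_fma <- if (category != "sensory")
      classify_and_agree(unname(imp_aff), subjects$FMA[si], "FMA")
    else NULL
    ag_kudt <- if (category != "motor")
      classify_and_agree(unname(imp_aff), subjects$kUDT[si], "kUDT")
    else NULL
    # concurrent validity: affected-side values vs clinical scores
    clin <- data.frame(FMA = subjects$FMA[si],
                       BBT = subjects$BBT_affected[si],
                       kUDT = subjects$kUDT[si])
    cc <- concurrent_correlations(aff$value, clin)
    g <- function(sc, f) cc[[f]][cc$scale == sc]
    rows[[metric]] <- data.frame(
      metric = metric, category = category,
      n_control = nrow(ctrl), n_affected = nrow(aff),
      auc_ctrl_aff = roc_auc(ctrl$value, aff$value, dirn),
      auc_ctrl_la = if (nrow(la)) roc_auc(ctrl$value, la$value, dirn) else NA,
      auc_aff_la = pst$auc,
      kw_p = kw$p,
      kw_p_ctrl_aff = pw("control", "affected"),
      kw_p_ctrl_la = pw("control", "less_affected"),
      kw_p_aff_la = pw("affected", "less_affected"),
      paired_t = pst$t, paired_p = pst$p,
      pct_impaired_aff = 100 * mean(zi_aff$impaired),
      pct_impaired_la = if (nrow(la)) 100 * mean(zi_la$impaired) else NA,
      agree_fma = if (!is.null(ag_fma)) ag_fma$pct_agreement else NA,
      agree_kudt = if (!is.null(ag_kudt)) ag_kudt$pct_agreement else NA,
      rho_fma = g("FMA", "rho"), p_fma = g("FMA", "p"),
      strength_fma = g("FMA", "strength"),
      rho_bbt = g("BBT", "rho"), p_bbt = g("BBT", "p"),
      strength_bbt = g("BBT", "strength"),
      rho_kudt = g("kUDT", "rho"), p_kudt = g("kUDT", "p"),
      strength_kudt = g("kUDT", "strength"),
      stringsAsFactors = FALSE)
  }
  cm_summary <- if (length(models)) data.frame(
    task = names(models),
    c1 = vapply(models, function(m) m$c1, numeric(1)),
    c2 = vapply(models, function(m) m$c2, numeric(1)),
    quality = vapply(models, function(m) m$quality, character(1)),
    row.names = NULL, stringsAsFactors = FALSE) else NULL
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  list(table = tab, confound_models = cm_summary,
       models = models,
       impairment = do.call(rbind, c(impairment, make.row.names = FALSE)))
}

#' Metric-independence analysis
#'
#' Partial Spearman correlations between one selected metric per assessment
#' domain (affected side, session 1), controlling each pair for the
#' remaining selected metrics.
#'
#' @param metric_table From [extract_metrics()].
#' @param subjects Subject table.
#' @param select Metrics to include (default: the representative of each
#'   task, `AE`, `VelExt`, `AROM`, `ForceFlex`, `RMSESlow`).
#' @param session Session to analyse.
#' @param control_for Passed to [partial_spearman()].
#' @return The [partial_spearman()] result plus the selection used.
#' @export
independence_report <- function(metric_table, subjects,
                                select = c("AE", "VelExt", "AROM",
                                           "ForceFlex", "RMSESlow"),
                                session = 1, control_for = "others") {
  m <- metric_table[metric_table$side == "affected" &
                      metric_table$session == session &
                      metric_table$metric %in% select, ]
  select <- intersect(select, unique(m$metric))   # drop missing metrics
  if (length(select) < 2L) return(NULL)
  ids <- sort(unique(m$subject_id))
  wide <- data.frame(row.names = ids)
  for (mm in select) {
    sub <- m[m$metric == mm, ]
    wide[[mm]] <- sub$value[match(ids, sub$subject_id)]
  }
  out <- tryCatch(partial_spearman(wide, control_for = control_for),
                  error = function(e) NULL)
  if (is.null(out)) return(NULL)
  out$select <- select
  out
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a dataset, extracts the metric table and produces
#' the reliability report for both stroke sides, the validity report, the
#' metric-independence matrix and a run manifest.  Deterministic given the
#' seed.
#'
#' @param config A [generator_config()] (ignored when `data` is given).
#' @param seed Master seed.
#' @param data Optional `list(trials, subjects)` to analyse instead of
#'   simulating (e.g. from [read_dataset()]).
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV with a JSON mirror and a `manifest.json`.
#' @param adjust Confound-removal scope, see [validity_report()].
#' @return List of class `hand_report` with `metric_table`,
#'   `reliability_affected`, `reliability_less_affected`, `validity`,
#'   `independence`, `subjects`, `manifest`.
#' @export
run_pipeline <- function(config = generator_config(), seed = 1, data = NULL,
                         out_dir = NULL, adjust = "motor") {
  if (is.null(data)) {
    subjects <- sample_cohort(config, seed)
    sim <- simulate_trials(subjects, config, seed)
    trials <- sim$trials
  } else {
    trials <- data$trials; subjects <- data$subjects
  }
  issues <- validate_inputs(trials, subjects)
  mt <- extract_metrics(trials)
  rel_aff <- reliability_report(mt, trials = trials, side = "affected")
  rel_la <- reliability_report(mt, trials = trials, side = "less_affected")
  val <- validity_report(mt, subjects, trials = trials, adjust = adjust)
  ind <- independence_report(mt, subjects)
  manifest <- list(
    seed = seed,
    preset = if (is.null(data)) config$preset else "external",
    n_stroke = sum(subjects$group == "stroke"),
    n_control = sum(subjects$group == "control"),
    package_version = as.character(utils::packageVersion("handassess")),
    n_issues = if (is.null(issues)) 0L else nrow(issues))
  bundle <- structure(list(
    metric_table = mt,
    reliability_affected = rel_aff,
    reliability_less_affected = rel_la,
    validity = val$table,
    confound_models = val$confound_models,
    impairment = val$impairment,
    independence = ind,
    subjects = subjects,
    issues = issues,
    manifest = manifest), class = "hand_report")
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' Long-format CSV files plus a JSON mirror and the run manifest.
#'
#' @param bundle A `hand_report` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return The output directory, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (is.null(x)) return()
    utils::write.csv(x, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  wr(bundle$metric_table, "metric_table")
  wr(bundle$reliability_affected, "reliability_affected")
  wr(bundle$reliability_less_affected, "reliability_less_affected")
  wr(bundle$validity, "validity")
  wr(bundle$confound_models, "confound_models")
  if (!is.null(bundle$independence))
    wr(as.data.frame(bundle$independence$rho), "independence_rho")
  json <- list(manifest = bundle$manifest,
               reliability_affected = bundle$reliability_affected,
               reliability_less_affected = bundle$reliability_less_affected,
               validity = bundle$validity,
               independence_rho = bundle$independence$rho)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' Validate a trial table and subject table
#'
#' Schema and plausibility checks: required columns, per-task trial-count
#' conformance (21 matching, 20 reaching, 6 rom/force/tracking trials per
#' subject-side-session), duplicate trial keys and clinical-score ranges
#' (FMA 0-66, kUDT 0-2, MoCA 0-30, BBT nonnegative).
#'
#' @param trials Trial-level data frame.
#' @param subjects Subject table.
#' @return A data frame of issues (`severity`, `issue`, `detail`); `NULL`
#'   when everything conforms.
#' @export
validate_inputs <- function(trials, subjects) {
  issues <- list()
  note <- function(severity, issue, detail)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, issue = issue, detail = detail,
      stringsAsFactors = FALSE)
  need_t <- c("subject_id", "side", "session", "task", "condition", "trial_idx")
  miss <- setdiff(need_t, names(trials))
  if (length(miss))
    note("error", "missing_columns", paste("trials:", paste(miss, collapse = ", ")))
  need_s <- c("subject_id", "group")
  miss <- setdiff(need_s, names(subjects))
  if (length(miss))
    note("error", "missing_columns", paste("subjects:", paste(miss, collapse = ", ")))
  if (length(issues)) return(do.call(rbind, issues))
  # trial-count conformance
  counts <- protocol_constants()$trial_counts
  key <- paste(trials$subject_id, trials$side, trials$session, trials$task)
  tab <- table(key)
  expected <- counts[vapply(strsplit(names(tab), " "), function(p) p[4], "")]
  bad <- which(as.integer(tab) != as.integer(expected))
  for (b in bad)
    note("warning", "trial_count",
         sprintf("%s: %d trials, expected %d", names(tab)[b],
                 as.integer(tab[b]), as.integer(expected[b])))
  # duplicate trial keys
  full_key <- paste(key, trials$condition, trials$trial_idx)
  if (anyDuplicated(full_key))
    note("error", "duplicate_trials",
         paste(sum(duplicated(full_key)), "duplicated trial keys"))
  # unknown subjects
  unknown <- setdiff(unique(trials$subject_id), subjects$subject_id)
  if (length(unknown))
    note("error", "unknown_subjects", paste(unknown, collapse = ", "))
  # clinical ranges
  rng_check <- function(col, lo, hi) {
    if (!col %in% names(subjects)) return()
    x <- subjects[[col]]
    bad <- which(!is.na(x) & (x < lo | x > hi))
    if (length(bad))
      note("error", "range_violation",
           sprintf("%s outside [%g, %g] for %s", col, lo, hi,
                   paste(subjects$subject_id[bad], collapse = ", ")))
  }
  rng_check("FMA", 0, 66); rng_check("kUDT", 0, 2)
  rng_check("MoCA", 0, 30); rng_check("BBT_affected", 0, 150)
  if (length(issues)) do.call(rbind, issues) else NULL
}

#' Summarise a report bundle
#'
#' One verdict line per metric: reliable (ICC strictly above 0.7, SRD%
#' strictly below 30, |shift| within 6.35), discriminative (control vs
#' affected AUC strictly above 0.7) and the strongest concurrent
#' correlation.
#'
#' @param bundle A `hand_report`.
#' @return Character vector of summary lines, invisibly; also printed.
#' @export
summarize_report <- function(bundle) {
  rel <- bundle$reliability_affected
  val <- bundle$validity
  lines <- character(0)
  for (metric in val$metric) {
    r <- rel[rel$metric == metric, ]
    v <- val[val$metric == metric, ]
    reliable <- nrow(r) == 1 && isTRUE(r$icc_ok && r$srd_ok && r$shift_ok)
    disc <- isTRUE(v$auc_ctrl_aff > 0.7)
    rhos <- c(FMA = v$rho_fma, BBT = v$rho_bbt, kUDT = v$rho_kudt)
    best <- names(rhos)[which.max(abs(rhos))]
    lines <- c(lines, sprintf(
      "%-9s %s, %s; ICC=%.2f SRD%%=%.1f AUC=%.2f; strongest clinical corr: %s (rho=%.2f, %s)",
      metric,
      if (reliable) "reliable" else "not reliable",
      if (disc) "discriminative" else "not discriminative",
      if (nrow(r)) r$icc else NA, if (nrow(r)) r$srd_pct else NA,
      v$auc_ctrl_aff, best, rhos[best],
      correlation_strength(rhos[best])))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @exportS3Method base::print
print.hand_report <- function(x, ...) {
  cat("Robot-assisted hand assessment report\n")
  cat(sprintf("  cohort: %d stroke, %d control (seed %s, preset %s)\n",
              x$manifest$n_stroke, x$manifest$n_control,
              x$manifest$seed, x$manifest$preset))
  summarize_report(x)
  invisible(x)
}
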