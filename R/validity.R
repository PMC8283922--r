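# Discriminant validity (Kruskal-Wallis, ROC AUC, z-score impairment
# classification with mixed-model confound removal), concurrent validity
# (Spearman correlations with clinical scales, classification agreement) and
# metric-independence analysis (partial Spearman correlations).

# orient values so that larger = worse performance
badness <- function(values, direction) {
  if (direction == "lower") values else -values
}

#' Kruskal-Wallis test with Bonferroni-corrected pairwise follow-ups
#'
#' Rank-based omnibus comparison of the groups (tie-corrected H statistic)
#' followed by all pairwise two-group Kruskal-Wallis tests whose p-values are
#' multiplied by the number of comparisons and capped at 1.
#'
#' @param groups Named list of numeric vectors (typically control, stroke
#'   affected side, stroke less-affected side).
#' @return List with `h`, `df`, `p` (omnibus) and `pairwise`, a data frame
#'   with `group1`, `group2`, `p_raw`, `p_adj`.
#' @export
#' @examples
#' kruskal_bonferroni(list(a = 1:3, b = 11:13, c = 21:23))$p < 0.05
kruskal_bonferroni <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  if (stats::sd(pooled) == 0)
    return(list(h = 0, df = length(groups) - 1L, p = 1,
                pairwise = NULL, degenerate = TRUE))
  kw <- stats::kruskal.test(pooled, factor(rep(names(groups), lengths(groups)),
                                           levels = names(groups)))
  pairs <- utils::combn(names(groups), 2L)
  m <- ncol(pairs)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   p_raw = NA_real_, p_adj = NA_real_,
                   stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    a <- groups[[pairs[1, j]]]; b <- groups[[pairs[2, j]]]
    p <- if (stats::sd(c(a, b)) == 0) 1
         else stats::kruskal.test(c(a, b),
                factor(rep(1:2, c(length(a), length(b)))))$p.value
    pw$p_raw[j] <- p
    pw$p_adj[j] <- min(1, p * m)
  }
  list(h = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairwise = pw, degenerate = FALSE)
}

#' ROC area under the curve between a control and a patient group
#'
#' The AUC is the probability that a randomly drawn patient value is worse
#' than a randomly drawn control value, with ties counted as 1/2; it equals
#' the Mann-Whitney U statistic divided by `n_control * n_patient`.  Values
#' are oriented through the metric's direction of better performance, so an
#' AUC above 0.5 always means the patient group performs worse, and an AUC
#' above 0.7 is conventionally read as adequate discrimination.
#'
#' @param control Numeric values of the reference (control) group.
#' @param patient Numeric values of the comparison (patient) group.
#' @param direction Direction of better performance of the metric
#'   (`"higher"` or `"lower"`).
#' @return AUC in [0, 1].
#' @export
#' @examples
#' roc_auc(c(1, 3), c(2, 4), direction = "lower")  # 0.75
roc_auc <- function(control, patient, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  control <- control[is.finite(control)]
  patient <- patient[is.finite(patient)]
  if (length(control) == 0L || length(patient) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  bc <- badness(control, direction)
  bp <- badness(patient, direction)
  r <- rank(c(bc, bp))                      # midranks handle ties as 1/2
  u <- sum(r[seq_along(bp) + length(bc)]) - length(bp) * (length(bp) + 1) / 2
  u / (length(bc) * length(bp))
}

#' Fit the normative confound model on control data
#'
#' Linear mixed-effects model of trial-level metric values of control
#' subjects on the suspected confounds -- age, gender, tested hand, the
#' task-specific effect (movement direction, trajectory speed or presented
#' angle, as applicable) and trial number -- with a random intercept per
#' subject.  Effect significance is judged by the t-statistic
#' (Satterthwaite p-values, alpha 0.05).  Model quality is summarised by
#' `C1 = 100 * mean(|residual|) / range(observed)` and
#' `C2 = 100 * sd(|residual|) / range(observed)`; quality is "good" when
#' C1 <= 10 and C2 <= 20, "moderate" when C1 <= 15 and C2 <= 25, otherwise
#' "poor".
#'
#' @param data Trial-level data frame of control subjects with columns
#'   `value`, `subject_id`, plus the covariate columns in `fixed`.
#' @param fixed Character vector of fixed-effect column names.
#' @return Object of class `confound_model`: list with the fitted `model`,
#'   `coefficients` (estimate, SE, t, p per term), `reference` (covariate
#'   values effects are removed relative to), `c1`, `c2`, `quality`.
#' @export
fit_confound_model <- function(data,
                               fixed = c("age", "gender", "hand",
                                         "task_effect", "trial_num")) {
  stopifnot(all(c("value", "subject_id") %in% names(data)))
  fixed <- fixed[fixed %in% names(data)]
  # drop constant (collinear with intercept) terms
  keep <- vapply(fixed, function(f) length(unique(data[[f]])) > 1L, logical(1))
  if (any(!keep))
    warning("dropping constant covariate(s): ",
            paste(fixed[!keep], collapse = ", "), call. = FALSE)
  fixed <- fixed[keep]
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("value ~", rhs, "+ (1 | subject_id)"))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = data,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
  co <- as.data.frame(stats::coef(summary(fit)))
  names(co) <- c("estimate", "se", "df", "t", "p")[seq_len(ncol(co))]
  res <- stats::residuals(fit)
  rng <- diff(range(data$value))
  c1 <- if (rng > 0) 100 * mean(abs(res)) / rng else 0
  c2 <- if (rng > 0) 100 * stats::sd(abs(res)) / rng else 0
  quality <- if (c1 <= 10 && c2 <= 20) "good"
             else if (c1 <= 15 && c2 <= 25) "moderate" else "poor"
  # reference covariate values: mean for numeric, first level for categorical
  reference <- lapply(data[fixed], function(col)
    if (is.numeric(col)) mean(col) else sort(unique(as.character(col)))[1])
  xlevels <- lapply(data[fixed], function(col)
    if (is.numeric(col)) NULL else sort(unique(as.character(col))))
  structure(list(model = fit, coefficients = co, fixed = fixed,
                 reference = reference, xlevels = xlevels,
                 c1 = c1, c2 = c2, quality = quality),
            class = "confound_model")
}

# fixed-effect prediction of a confound model relative to reference
# covariate values (difference in predicted value caused by the covariates)
confound_offset <- function(object, newdata) {
  stopifnot(inherits(object, "confound_model"))
  if (!length(object$fixed)) return(rep(0, nrow(newdata)))
  ref <- as.data.frame(object$reference, stringsAsFactors = FALSE)
  both <- rbind(newdata[object$fixed],
                ref[rep(1L, nrow(newdata)), , drop = FALSE])
  for (nm in object$fixed)
    if (!is.null(object$xlevels[[nm]]))
      both[[nm]] <- factor(both[[nm]], levels = object$xlevels[[nm]])
  fe <- lme4::fixef(object$model)
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(object$fixed, collapse = " + "))), both)
  pred <- drop(mm[, names(fe), drop = FALSE] %*% fe)
  pred[seq_len(nrow(newdata))] - pred[nrow(newdata) + seq_len(nrow(newdata))]
}

#' Remove confound effects from metric values
#'
#' Subtracts the fixed-effect predictions of a fitted [fit_confound_model()]
#' relative to the reference covariate values, leaving values as if every
#' subject had been measured at the reference age, gender, hand and task
#' condition.
#'
#' @param object A `confound_model`.
#' @param values Raw metric values.
#' @param covariates Data frame with the model's covariate columns, one row
#'   per value.
#' @return Adjusted values (same length as `values`).
#' @export
adjust_values <- function(object, values, covariates) {
  stopifnot(length(values) == nrow(covariates))
  values - confound_offset(object, covariates)
}

#' Control-referenced z-scores and impairment calls
#'
#' Standardises (optionally confound-adjusted) patient values against the
#' control reference distribution and orients the z-score so that larger z
#' means worse performance.  A subject is classified impaired when they
#' perform worse than the 95th percentile of the control distribution.
#' Because that percentile is estimated from a finite control sample, the
#' default threshold (`"normative"`) is the one-sided 95% normative limit
#' `qt(0.95, n - 1) * sqrt(1 + 1/n)` on the z scale -- the prediction-bound
#' form that flags exactly 5% of new control observations under normality.
#' `threshold = "normal"` uses the plug-in normal deviate `qnorm(0.95)` and
#' `threshold = "empirical"` the empirical 95th percentile of the oriented
#' control z-scores.  The inequality is strict: a value exactly at the
#' threshold is not impaired.
#'
#' @param patient Patient metric values (adjusted if a confound model is in
#'   use).
#' @param control Control reference values on the same (adjusted) scale.
#' @param direction Direction of better performance (`"higher"`/`"lower"`).
#' @param threshold `"normative"`, `"normal"` or `"empirical"` (see Details).
#' @return List with `z` (oriented z-scores), `impaired` (logical),
#'   `cutoff` (on the oriented z scale) and `control_z` (oriented z-scores
#'   of the controls themselves).
#' @export
zscore_impairment <- function(patient, control,
                              direction = c("higher", "lower"),
                              threshold = c("normative", "normal", "empirical")) {
  direction <- match.arg(direction)
  threshold <- match.arg(threshold)
  mu <- mean(control); s <- stats::sd(control)
  if (!is.finite(s) || s == 0) stop("degenerate control reference", call. = FALSE)
  n <- length(control)
  orient <- if (direction == "lower") 1 else -1
  z <- orient * (patient - mu) / s
  cz <- orient * (control - mu) / s
  cutoff <- switch(threshold,
    normative = stats::qt(0.95, n - 1) * sqrt(1 + 1 / n),
    normal = stats::qnorm(0.95),
    empirical = unname(stats::quantile(cz, 0.95)))
  list(z = z, impaired = z > cutoff, cutoff = cutoff, control_z = cz)
}

#' Impairment classification agreement with clinical scores
#'
#' Compares robot-based impairment calls with clinical classifications
#' (impaired defined as FMA < 60 or kUDT < 2) on a per-subject basis.
#'
#' @param robot_impaired Logical vector of robot-based calls, one per subject.
#' @param clinical Numeric clinical scores, matched to subjects.
#' @param scale `"FMA"` (threshold `< 60`) or `"kUDT"` (threshold `< 2`).
#' @return List with `pct_impaired` (robot calls, over all subjects with a
#'   call), `pct_agreement` (subjects where robot and clinical flags match,
#'   over subjects with both), `n_agree`, `n`.
#' @export
#' @examples
#' classify_and_agree(rep(c(TRUE, FALSE), c(21, 9)),
#'                    rep(c(30, 65), c(21, 9)), "FMA")$pct_agreement  # 70
classify_and_agree <- function(robot_impaired, clinical,
                               scale = c("FMA", "kUDT")) {
  scale <- match.arg(scale)
  stopifnot(length(robot_impaired) == length(clinical))
  clin_flag <- switch(scale, FMA = clinical < 60, kUDT = clinical < 2)
  pct_impaired <- 100 * mean(robot_impaired, na.rm = TRUE)
  ok <- !is.na(robot_impaired) & !is.na(clin_flag)
  n <- sum(ok)
  n_agree <- sum(robot_impaired[ok] == clin_flag[ok])
  list(pct_impaired = pct_impaired,
       pct_agreement = if (n > 0) 100 * n_agree / n else NA_real_,
       n_agree = n_agree, n = n)
}

#' Correlation strength label
#'
#' Conventional interpretation bands for the absolute Spearman correlation:
#' below 0.1 negligible, 0.1-0.39 weak, 0.4-0.69 moderate, 0.7 and above
#' strong.
#'
#' @param rho Correlation coefficient(s).
#' @return Character vector of labels.
#' @export
#' @examples
#' correlation_strength(-0.48)  # "moderate"
correlation_strength <- function(rho) {
  a <- abs(rho)
  ifelse(a < 0.1, "negligible",
         ifelse(a < 0.4, "weak",
                ifelse(a < 0.7, "moderate", "strong")))
}

#' Concurrent-validity correlations with clinical scores
#'
#' Spearman correlations of one metric's values against each provided
#' clinical score, with two-sided p-values and strength labels.
#'
#' @param metric_values Numeric metric values, one per subject.
#' @param clinical Data frame of clinical scores (e.g. columns `FMA`, `BBT`,
#'   `kUDT`), rows matched to `metric_values`.
#' @return Data frame with `scale`, `rho`, `p`, `strength`, `n`.
#' @export
concurrent_correlations <- function(metric_values, clinical) {
  stopifnot(is.data.frame(clinical), nrow(clinical) == length(metric_values))
  out <- lapply(names(clinical), function(sc) {
    y <- clinical[[sc]]
    ok <- is.finite(metric_values) & is.finite(y)
    if (sum(ok) < 3L || stats::sd(metric_values[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(scale = sc, rho = NA_real_, p = NA_real_,
                        strength = NA_character_, n = sum(ok),
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(metric_values[ok], y[ok],
                                           method = "spearman", exact = FALSE))
    data.frame(scale = sc, rho = unname(ct$estimate), p = ct$p.value,
               strength = correlation_strength(unname(ct$estimate)),
               n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Partial Spearman correlation matrix
#'
#' Rank-transforms all columns, then for each pair of variables computes the
#' partial correlation controlling for a covariate set -- by default all the
#' remaining columns of the matrix.  P-values come from the t-distribution
#' with `n - 2 - n_covariates` degrees of freedom.
#'
#' @param x Data frame or matrix of metric values (complete cases are used).
#' @param control_for `"others"` (default: all remaining columns) or a
#'   character vector of column names to control every pair for.
#' @return List with matrices `rho` and `p` (diagonal NA) and `n`.
#' @export
partial_spearman <- function(x, control_for = "others") {
  x <- as.data.frame(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  p_ <- ncol(x); n <- nrow(x)
  if (n < p_ + 3L) stop("too few complete cases for partial correlations", call. = FALSE)
  r <- as.data.frame(lapply(x, rank))
  rho <- p <- matrix(NA_real_, p_, p_, dimnames = list(names(x), names(x)))
  resid_on <- function(y, covs) {
    if (!length(covs)) return(y - mean(y))
    stats::residuals(stats::lm(y ~ ., data = r[covs]))
  }
  for (i in seq_len(p_ - 1L)) for (j in seq((i + 1L), p_)) {
    covs <- if (identical(control_for, "others"))
      setdiff(names(x), names(x)[c(i, j)])
    else setdiff(control_for, names(x)[c(i, j)])
    ri <- resid_on(r[[i]], covs); rj <- resid_on(r[[j]], covs)
    if (stats::sd(ri) == 0 || stats::sd(rj) == 0) next   # singular pair, flagged NA
    pr <- stats::cor(ri, rj)
    df <- n - 2L - length(covs)
    tt <- pr * sqrt(df / max(1 - pr^2, .Machine$double.eps))
    rho[i, j] <- rho[j, i] <- pr
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), df)
  }
  list(rho = rho, p = p, n = n)
}

#' Paired comparison of the two body sides
#'
#' Two-sided paired t-test on per-subject differences between the affected
#' and less-affected side, plus the side-vs-side AUC (probability that the
#' affected side performs worse), oriented via the metric direction.
#'
#' @param affected,less_affected Paired per-subject metric values.
#' @param direction Direction of better performance.
#' @return List with `t`, `p`, `df`, `auc` and `degenerate` (TRUE when the
#'   differences have zero variance; `p` is then 0 for a nonzero constant
#'   difference and 1 for identical sides).
#' @export
paired_sides_test <- function(affected, less_affected,
                              direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  ok <- is.finite(affected) & is.finite(less_affected)
  a <- affected[ok]; b <- less_affected[ok]
  if (length(a) < 2L) stop("need at least 2 matched pairs", call. = FALSE)
  d <- a - b
  auc <- roc_auc(b, a, direction = direction)
  if (stats::sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p = if (mean(d) == 0) 1 else 0,
                df = length(d) - 1L, auc = auc, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), auc = auc, degenerate = FALSE)
}
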