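# Independent brute-force oracles used to cross-check the package's
# statistics, deliberately written along different code paths than the
# implementations they verify.

# ICC(A,k) from an aov() fit (stats's ANOVA table, not the package's own
# mean-square sums)
oracle_icc_aov <- function(s1, s2) {
  n <- length(s1)
  d <- data.frame(value = c(s1, s2),
                  subject = factor(rep(seq_len(n), 2)),
                  session = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(value ~ subject + session, data = d))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["session", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (msc - mse) / n)
}

# AUC by exhaustive pair enumeration (ties count 1/2); badness orientation
oracle_auc_enum <- function(control, patient, direction) {
  s <- if (direction == "lower") 1 else -1
  tot <- 0
  for (c_ in s * control) for (p_ in s * patient)
    tot <- tot + (p_ > c_) + 0.5 * (p_ == c_)
  tot / (length(control) * length(patient))
}

# Kruskal-Wallis H with tie correction, from first principles
oracle_kw_h <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Spearman rho as Pearson correlation of midranks
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# random test-retest panel (optionally with integer values to force ties)
random_panel <- function(n = 8, integer = FALSE) {
  gen <- function() if (integer) sample(0:5, n, replace = TRUE)
                    else rnorm(n, sd = runif(1, 0.5, 3))
  b <- if (integer) sample(0:8, n, replace = TRUE) else rnorm(n, sd = 2)
  list(s1 = b + gen(), s2 = b + gen())
}
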