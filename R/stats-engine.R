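# Supporting statistics: summary-statistics one-way ANOVA, Holm-Sidak
# step-down adjustment, Welch's t from group summaries, central-F critical
# values, and noncentral-F power / sensitivity effect size (Cohen's f,
# noncentrality lambda = f^2 * N).

#' One-way ANOVA from group summaries
#'
#' Reconstructs the classical one-way ANOVA from per-group mean, SEM and n
#' only.  The within-group sample variance of group i is recovered as
#' `n_i * sem_i^2`; the within mean square pools these by their degrees of
#' freedom, and the between sum of squares is taken about the n-weighted
#' grand mean.  For equal-n raw data this reproduces [anova_raw()] exactly.
#'
#' @param mean,sem,n Numeric vectors (one entry per group); all `sem` > 0,
#'   all `n` >= 2.
#' @param labels Optional group labels.
#'
#' @return An object of class `"anova_result"`: `f_statistic`, `df_between`,
#'   `df_within`, `p_value`, `ms_between`, `ms_within`, `degenerate`.
#' @export
#' @examples
#' # three dose groups of 6 animals, summarised as mean +/- SEM
#' anova_from_summary(c(37.35, 33.37, 61.00), c(4.10, 4.09, 4.72), c(6, 6, 6))
anova_from_summary <- function(mean, sem, n, labels = NULL) {
  if (length(mean) < 2L) stop("at least 2 groups are required", call. = FALSE)
  if (length(sem) != length(mean) || length(n) != length(mean)) {
    stop("'mean', 'sem' and 'n' must have one entry per group", call. = FALSE)
  }
  .check_number(mean, "mean")
  if (!is.numeric(sem) || any(!is.finite(sem)) || any(sem <= 0)) {
    stop("'sem' must be > 0 for every group", call. = FALSE)
  }
  if (any(n < 2) || any(n != round(n))) {
    stop("'n' must be integer >= 2 for every group", call. = FALSE)
  }
  k <- length(mean)
  s2 <- n * sem^2                       # sample variance of each group
  df_w <- sum(n) - k
  df_b <- k - 1L
  ms_within <- sum((n - 1) * s2) / df_w
  grand <- sum(n * mean) / sum(n)
  ss_between <- sum(n * (mean - grand)^2)
  ms_between <- ss_between / df_b
  .anova_result(ms_between, ms_within, df_b, df_w, labels)
}

#' One-way ANOVA on raw per-group values
#'
#' Classical fixed-effects one-way ANOVA via [stats::lm()]/[stats::anova()].
#' With equal group sizes it agrees exactly with [anova_from_summary()]
#' applied to the groups' means and SEMs.  A zero within-group variance with
#' non-identical means is reported as an infinite F with `p = 0` and
#' `degenerate = TRUE` rather than an error, so simulator edge cases surface
#' without crashing pipelines.
#'
#' @param values_by_group List of numeric vectors, one per group (each of
#'   length >= 2).
#' @return An `"anova_result"`, see [anova_from_summary()].
#' @export
anova_raw <- function(values_by_group) {
  if (!is.list(values_by_group) || length(values_by_group) < 2L) {
    stop("at least 2 groups are required", call. = FALSE)
  }
  sizes <- lengths(values_by_group)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  y <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(seq_along(values_by_group), sizes))
  k <- nlevels(g)
  df_b <- k - 1L
  df_w <- length(y) - k
  if (all(vapply(values_by_group, stats::var, numeric(1)) == 0)) {
    # no within-group variation: F is 0/0 (all means equal) or infinite
    ms_b <- sum(sizes * (vapply(values_by_group, mean, numeric(1)) -
                           mean(y))^2) / df_b
    if (ms_b == 0) return(.anova_result(0, 0, df_b, df_w, names(values_by_group),
                                        degenerate = TRUE, f_override = 0,
                                        p_override = 1))
    return(.anova_result(ms_b, 0, df_b, df_w, names(values_by_group),
                         degenerate = TRUE, f_override = Inf, p_override = 0))
  }
  tab <- anova(lm(y ~ g))
  .anova_result(tab$`Mean Sq`[1L], tab$`Mean Sq`[2L], df_b, df_w,
                names(values_by_group))
}

.anova_result <- function(ms_between, ms_within, df_b, df_w, labels = NULL,
                          degenerate = FALSE, f_override = NULL,
                          p_override = NULL) {
  f <- if (!is.null(f_override)) f_override else ms_between / ms_within
  p <- if (!is.null(p_override)) p_override else
    pf(f, df_b, df_w, lower.tail = FALSE)
  structure(list(f_statistic = f, df_between = df_b, df_within = df_w,
                 p_value = p, ms_between = ms_between, ms_within = ms_within,
                 degenerate = degenerate, labels = labels),
            class = "anova_result")
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the m raw p-values ascending, sets
#' `adjusted_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforces monotone
#' non-decreasing adjusted values, and rejects while `adjusted < alpha`.
#' Results are returned in the original input order.
#'
#' @param p Raw p-values in \[0, 1\].
#' @param alpha Significance level.
#' @return Data frame with columns `p`, `adjusted`, `reject`.
#' @export
#' @examples
#' holm_sidak(c(0.01, 0.03, 0.04))
holm_sidak <- function(p, alpha = 0.05) {
  if (!is.numeric(p) || length(p) == 0L || anyNA(p) ||
      any(p < 0) || any(p > 1)) {
    stop("'p' must be p-values in [0, 1]", call. = FALSE)
  }
  .check_prob(alpha, "alpha")
  m <- length(p)
  ord <- order(p)
  adj_sorted <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj_sorted <- pmin(cummax(adj_sorted), 1)
  adjusted <- numeric(m)
  adjusted[ord] <- adj_sorted
  # step-down: stop rejecting at the first non-rejection in sorted order
  rej_sorted <- adj_sorted < alpha
  if (any(!rej_sorted)) {
    first_fail <- which(!rej_sorted)[1L]
    rej_sorted[first_fail:m] <- FALSE
  }
  reject <- logical(m)
  reject[ord] <- rej_sorted
  data.frame(p = p, adjusted = adjusted, reject = reject)
}

#' Welch's t-test from group summaries
#'
#' `t = (mean1 - mean2) / sqrt(sem1^2 + sem2^2)` with Welch-Satterthwaite
#' degrees of freedom computed on the squared-SEM terms (each with `n - 1`
#' df) and kept continuous (not rounded).  The p-value is two-sided.
#'
#' @param mean1,sem1,n1 First group: mean, SEM (> 0), size (>= 2).
#' @param mean2,sem2,n2 Second group.
#' @return List with elements `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t_summary(701, 60, 6, 428, 56, 6)
welch_t_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  .check_number(c(mean1, mean2), "mean")
  if (!is.numeric(c(sem1, sem2)) || sem1 <= 0 || sem2 <= 0) {
    stop("'sem' must be > 0", call. = FALSE)
  }
  if (n1 < 2 || n2 < 2) stop("'n' must be >= 2", call. = FALSE)
  v1 <- sem1^2
  v2 <- sem2^2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Critical value of the central F distribution
#'
#' @param alpha Upper-tail probability.
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return The upper-alpha quantile.
#' @export
#' @examples
#' critical_f(0.05, 2, 51)
critical_f <- function(alpha, df1, df2) {
  .check_prob(alpha, "alpha")
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1", call. = FALSE)
  qf(alpha, df1, df2, lower.tail = FALSE)
}

#' Power of the fixed-effects one-way ANOVA F test
#'
#' Uses the convention of standard power software for the fixed-effects
#' one-way ANOVA: with Cohen's effect size f, the noncentrality parameter is
#' `lambda = f^2 * N` where N is the total sample size.  Power is the
#' probability that a noncentral F(k-1, N-k, lambda) variate exceeds the
#' central critical value.
#'
#' @param effect_size_f Cohen's f (>= 0).
#' @param alpha Significance level.
#' @param k_groups Number of groups (>= 2).
#' @param total_n Total sample size across groups (> k_groups).
#' @return Power in (0, 1).
#' @export
#' @examples
#' power_of_f(0.5509, 0.05, 3, 54)
power_of_f <- function(effect_size_f, alpha, k_groups, total_n) {
  .check_number(effect_size_f, "effect_size_f", lower = 0)
  .check_prob(alpha, "alpha")
  if (k_groups < 2) stop("'k_groups' must be >= 2", call. = FALSE)
  if (total_n <= k_groups) {
    stop("'total_n' must exceed 'k_groups'", call. = FALSE)
  }
  df1 <- k_groups - 1
  df2 <- total_n - k_groups
  crit <- critical_f(alpha, df1, df2)
  pf(crit, df1, df2, ncp = effect_size_f^2 * total_n, lower.tail = FALSE)
}

#' Sensitivity analysis: minimal detectable effect size
#'
#' Solves `power_of_f(f, alpha, k_groups, total_n) = power` for Cohen's f by
#' bracketed root-finding, to an absolute power tolerance of 1e-8.
#'
#' @param alpha Significance level.
#' @param power Target power, must exceed `alpha`.
#' @param k_groups,total_n As in [power_of_f()].
#' @return Cohen's f.
#' @export
#' @examples
#' sensitivity_effect_size(0.05, 0.95, 3, 54)
sensitivity_effect_size <- function(alpha, power, k_groups, total_n) {
  .check_prob(alpha, "alpha")
  .check_prob(power, "power")
  if (power <= alpha) {
    stop("'power' must exceed 'alpha' (at f = 0 the power equals alpha)",
         call. = FALSE)
  }
  gap <- function(f) power_of_f(f, alpha, k_groups, total_n) - power
  upper <- 1
  while (gap(upper) < 0 && upper < 1e4) upper <- upper * 2
  root <- uniroot(gap, c(0, upper), tol = .Machine$double.eps^0.5)$root
  # refine until the power gap itself is below 1e-8
  root <- uniroot(gap, c(max(0, root - 1e-4), root + 1e-4),
                  tol = 1e-14, extendInt = "upX")$root
  if (abs(gap(root)) > 1e-8) {
    stop("root finding failed to reach the requested power tolerance",
         call. = FALSE)
  }
  root
}

#' Percent change of an estimate relative to a reference
#'
#' `100 * (x - reference) / reference`, the convention used when reporting
#' how an otoprotectant shifts an HTDD relative to the vehicle group.
#'
#' @param x,reference Numeric; `reference` must be non-zero.
#' @return Percent change (positive = increase).
#' @export
#' @examples
#' percent_change(701, 428)   # ~ +64%
percent_change <- function(x, reference) {
  .check_number(x, "x")
  .check_number(reference, "reference")
  if (any(reference == 0)) stop("'reference' must be non-zero", call. = FALSE)
  100 * (x - reference) / reference
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d;%d) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value,
              if (x$degenerate) " [degenerate: zero within-group variance]"
              else ""))
  invisible(x)
}
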