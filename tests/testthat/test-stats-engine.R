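# Supporting statistics

test_that("summary-statistics ANOVA reproduces a published omnibus F", {
  a <- anova_from_summary(c(37.35, 33.37, 61.00), c(4.10, 4.09, 4.72),
                          c(6, 6, 6))
  expect_equal(a$f_statistic, 11.99, tolerance = 0.005)
  expect_equal(a$df_between, 2L)
  expect_equal(a$df_within, 15L)
  expect_lt(a$p_value, 0.001)
})

test_that("summary ANOVA handles identical groups and rejects bad SEMs", {
  a <- anova_from_summary(c(5, 5, 5), c(1, 1, 1), c(6, 6, 6))
  expect_equal(a$f_statistic, 0)
  expect_equal(a$p_value, 1)
  expect_error(anova_from_summary(c(1, 2), c(1, 0), c(6, 6)), "sem")
  expect_error(anova_from_summary(c(1, 2), c(1, 1), c(6, 1)), "n")
  expect_error(anova_from_summary(1, 1, 6), "2 groups")
})

test_that("raw ANOVA equals its summary reconstruction and flags degeneracy", {
  expect_equal(anova_raw(list(c(1, 2, 3), c(1, 2, 3)))$f_statistic, 0)
  deg <- anova_raw(list(c(0, 0), c(1, 1)))
  expect_true(deg$degenerate)
  expect_equal(deg$f_statistic, Inf)
  expect_equal(deg$p_value, 0)
  expect_error(anova_raw(list(1, c(1, 2))), "at least 2 values")

  set.seed(11)
  for (rep in 1:20) {
    groups <- lapply(1:3, function(i) rnorm(6, mean = i))
    raw <- anova_raw(groups)
    summ <- anova_from_summary(
      vapply(groups, mean, numeric(1)),
      vapply(groups, function(g) sd(g) / sqrt(length(g)), numeric(1)),
      lengths(groups))
    expect_equal(raw$f_statistic, summ$f_statistic, tolerance = 1e-12)
    expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
  }
  # the reconstruction also matches for unequal group sizes
  groups <- list(rnorm(5), rnorm(8, 1), rnorm(12, 2))
  raw <- anova_raw(groups)
  summ <- anova_from_summary(
    vapply(groups, mean, numeric(1)),
    vapply(groups, function(g) sd(g) / sqrt(length(g)), numeric(1)),
    lengths(groups))
  expect_equal(raw$f_statistic, summ$f_statistic, tolerance = 1e-12)
})

test_that("Holm-Sidak step-down adjustment matches hand computation", {
  expect_equal(holm_sidak(0.02)$adjusted, 0.02)
  hs <- holm_sidak(c(0.01, 0.03, 0.04), alpha = 0.05)
  expect_equal(hs$adjusted, c(1 - 0.99^3, 1 - 0.97^2, 1 - 0.97^2),
               tolerance = 1e-12)
  expect_equal(hs$reject, c(TRUE, FALSE, FALSE))
  all1 <- holm_sidak(rep(1, 4))
  expect_equal(all1$adjusted, rep(1, 4))
  expect_false(any(all1$reject))
  expect_error(holm_sidak(c(0.5, 1.2)), "p-values")
})

test_that("Holm-Sidak is monotone, dominates raw p, and order-invariant", {
  set.seed(21)
  for (rep in 1:20) {
    p <- runif(7)
    hs <- holm_sidak(p)
    expect_true(all(hs$adjusted >= hs$p))
    expect_true(all(diff(hs$adjusted[order(hs$p)]) >= -1e-15))
    perm <- sample(seq_along(p))
    expect_equal(holm_sidak(p[perm])$adjusted, hs$adjusted[perm])
  }
})

test_that("Welch t from summaries matches the direct formula", {
  id <- welch_t_summary(10, 2, 6, 10, 2, 6)
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
  expect_equal(id$df, 10)            # equal SEMs: df = n1 + n2 - 2
  w <- welch_t_summary(701, 60, 6, 428, 56, 6)
  expect_equal(w$t, 3.326301, tolerance = 1e-6)
  expect_equal(w$df, 9.952775, tolerance = 1e-6)
  expect_equal(w$p, 0.0077145, tolerance = 1e-5)
  expect_error(welch_t_summary(1, 0, 6, 2, 1, 6), "sem")
  # Satterthwaite df bounds
  set.seed(31)
  for (rep in 1:20) {
    s <- runif(2, 0.1, 5); n <- sample(3:12, 2, replace = TRUE)
    df <- welch_t_summary(0, s[1], n[1], 1, s[2], n[2])$df
    expect_gte(df, min(n) - 1)
    expect_lte(df, sum(n) - 2 + 1e-9)
  }
})

test_that("critical F matches independent quantile values", {
  expect_equal(critical_f(0.05, 1, 10), 4.9646, tolerance = 1e-4)
  expect_equal(critical_f(0.05, 2, 51), qf(0.95, 2, 51), tolerance = 1e-12)
  expect_lt(critical_f(0.999, 2, 10), 0.01)  # alpha -> 1: quantile -> 0
  expect_error(critical_f(0.05, 0, 10), "degrees of freedom")
})

test_that("noncentral-F power behaves like a power function", {
  expect_equal(power_of_f(0, 0.05, 3, 54), 0.05, tolerance = 1e-12)
  grid_f <- c(0.1, 0.25, 0.4, 0.55)
  pw <- vapply(grid_f, power_of_f, numeric(1), alpha = 0.05, k_groups = 3,
               total_n = 54)
  expect_true(all(diff(pw) > 0))
  pn <- vapply(c(18, 36, 54, 90), function(n)
    power_of_f(0.4, 0.05, 3, n), numeric(1))
  expect_true(all(diff(pn) > 0))
})

test_that("sensitivity effect size inverts the power function", {
  for (target in c(0.5, 0.8, 0.95)) {
    for (n in c(30, 54, 90)) {
      f <- sensitivity_effect_size(0.05, target, 3, n)
      expect_equal(power_of_f(f, 0.05, 3, n), target, tolerance = 1e-6)
    }
  }
  # continuity at the null: power barely above alpha needs almost no effect
  expect_lt(sensitivity_effect_size(0.05, 0.0501, 3, 54), 0.02)
  expect_error(sensitivity_effect_size(0.05, 0.04, 3, 54), "exceed")
})

test_that("percent change reporting is exact", {
  expect_equal(percent_change(701, 428), 100 * 273 / 428)
  expect_equal(percent_change(666, 797), 100 * (666 - 797) / 797)
  expect_error(percent_change(1, 0), "non-zero")
})
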