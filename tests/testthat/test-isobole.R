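# Fixed-dose isobolographic transformation

exact_line <- function(slope, intercept = 0, doses = c(1, 2, 3),
                       agent = "X") {
  fit_dose_response(data.frame(dose = doses,
                               effect = intercept + slope * doses), agent)
}

test_that("dose equivalence follows the closed form", {
  lf <- exact_line(1.0, agent = "FIX")
  lv <- exact_line(0.1, doses = c(10, 20, 30), agent = "VAR")
  expect_equal(dose_equivalent(lf, lv, 0), 0)
  expect_equal(dose_equivalent(lf, lv, 3), 30, tolerance = 1e-9)
  # zero-noise fitted lines reproduce the analytic value to machine precision
  design <- additive_design(noise_sd = 0)
  rec <- simulate_abr_study(design, seed = 4)
  lam <- fit_series(rec, "AMI", "^AMI")
  lfu <- fit_series(rec, "FUR", "^FUR")
  # effect of AMI 500 is 0.0497*500 = 24.85%; FUR equivalent = 24.85/0.3
  expect_equal(dose_equivalent(lam, lfu, 500), 24.85 / 0.3,
               tolerance = 1e-9)
})

test_that("additive point arithmetic and degenerate cases", {
  lf <- exact_line(0.1, doses = c(100, 200, 300), agent = "FIX")
  lv <- exact_line(0.1, doses = c(100, 300, 500, 700), agent = "VAR")
  mx <- mixture_design("VAR", "FIX", 200)
  h <- suppressWarnings(htdd(lv, 50))          # dose 500
  ap <- additive_point(h, lf, lv, mx)
  expect_equal(ap$dose, 300, tolerance = 1e-8) # 500 - equivalent 200
  expect_equal(ap$sem, 0, tolerance = 1e-6)

  # fixed dose 0: additive point equals the single-drug HTDD, dose and SEM
  design <- single_agent_design("V", noise_sd = 10)
  line_v <- fit_dose_response(simulate_abr_study(design, seed = 6), "V")
  hv <- htdd(line_v, 50)
  ap0 <- additive_point(hv, lf, line_v, mixture_design("V", "FIX", 0))
  expect_equal(ap0$dose, hv$dose, tolerance = 1e-12)
  expect_equal(ap0$sem, hv$sem, tolerance = 1e-12)

  # the fixed dose alone suffices: floored at 0 with a warning
  h20 <- suppressWarnings(htdd(lv, 20))        # dose 200
  expect_warning(
    ap_floor <- additive_point(h20, lf, lv, mixture_design("VAR", "FIX", 5000)),
    "floored")
  expect_equal(ap_floor$dose, 0)
})

test_that("additive dose decreases monotonically with the fixed dose", {
  lf <- exact_line(0.1, doses = c(100, 200, 300), agent = "FIX")
  lv <- exact_line(0.2, doses = c(50, 150, 250), agent = "VAR")
  h <- suppressWarnings(htdd(lv, 50))
  doses <- vapply(c(0, 50, 100, 150, 200), function(fd) {
    additive_point(h, lf, lv, mixture_design("VAR", "FIX", fd))$dose
  }, numeric(1))
  expect_true(all(diff(doses) < 0))
})

test_that("interaction classification follows the Welch comparison", {
  # identity: same dose, p = 1
  a <- isobole_point(500, 50, 6, 50, role = "additive")
  m0 <- isobole_point(500, 50, 6, 50, role = "experimental")
  id <- classify_interaction(a, m0)
  expect_equal(id$verdict, "additive")
  expect_equal(id$t_statistic, 0)
  expect_equal(id$p_value, 1)
  expect_false(id$tendency_flag)

  # frozen from the direct Welch formula: t = 300/sqrt(50^2+60^2)
  m <- isobole_point(800, 60, 6, 50, role = "experimental")
  call <- classify_interaction(a, m)
  expect_equal(call$t_statistic, 3.841106, tolerance = 1e-6)
  expect_equal(call$p_value, 0.003456552, tolerance = 1e-6)
  expect_equal(call$verdict, "antagonistic")
  expect_equal(call$direction, "above_additive")

  # synergy is the mirror image
  syn <- classify_interaction(a, isobole_point(200, 60, 6, 50))
  expect_equal(syn$verdict, "synergistic")

  expect_error(
    classify_interaction(a, isobole_point(800, 60, 6, 20)),
    "different effect levels")
})

test_that("near-significant additive calls carry the tendency flag", {
  # means/SEMs tuned to p ~ 0.054 (t = 200/sqrt(2*65^2), df = 10)
  a <- isobole_point(500, 65, 6, 50, role = "additive")
  m <- isobole_point(700, 65, 6, 50, role = "experimental")
  call <- classify_interaction(a, m, alpha = 0.05, tendency_band = 0.10)
  expect_equal(call$verdict, "additive")
  expect_gt(call$p_value, 0.05)
  expect_lt(call$p_value, 0.10)
  expect_true(call$tendency_flag)
  strict <- classify_interaction(a, m, alpha = 0.01, tendency_band = 0.02)
  expect_false(strict$tendency_flag)
})

test_that("swapping variable and fixed roles keeps additive data additive", {
  rec <- simulate_abr_study(additive_design(noise_sd = 0), seed = 10)
  lam <- fit_series(rec, "AMI", "^AMI")
  lfu <- fit_series(rec, "FUR", "^FUR")
  # orientation 1: FUR variable, AMI fixed at 500 (as simulated)
  lmix <- fit_series(rec, "FUR", "^MIX")
  mx1 <- mixture_design("FUR", "AMI", 500)
  ap1 <- additive_point(suppressWarnings(htdd(lfu, 50)), lam, lfu, mx1)
  c1 <- classify_interaction(ap1,
                             experimental_point(suppressWarnings(htdd(lmix, 50)), mx1))
  expect_equal(c1$verdict, "additive")
  expect_equal(ap1$dose, suppressWarnings(htdd(lmix, 50))$dose,
               tolerance = 1e-8)
  # orientation 2: simulate the converse design (AMI variable, FUR fixed 30)
  arms2 <- c(
    lapply(c(400, 800, 1200), function(d) abr_arm(sprintf("AMI_%d", d),
                                                  c(AMI = d))),
    lapply(c(60, 120, 180), function(d) abr_arm(sprintf("FUR_%d", d),
                                                c(FUR = d))),
    lapply(c(400, 700, 1000), function(d) abr_arm(sprintf("MIX_%d", d),
                                                  c(AMI = d, FUR = 30))))
  des2 <- abr_design(arms2, slopes = c(AMI = 0.0497, FUR = 0.3),
                     intercept = 0, noise_sd = 0)
  rec2 <- simulate_abr_study(des2, seed = 10)
  lam2 <- fit_series(rec2, "AMI", "^AMI")
  lfu2 <- fit_series(rec2, "FUR", "^FUR")
  lmix2 <- fit_series(rec2, "AMI", "^MIX")
  mx2 <- mixture_design("AMI", "FUR", 30)
  ap2 <- additive_point(suppressWarnings(htdd(lam2, 50)), lfu2, lam2, mx2)
  c2 <- classify_interaction(ap2,
                             experimental_point(suppressWarnings(htdd(lmix2, 50)), mx2))
  expect_equal(c2$verdict, "additive")
  expect_equal(ap2$dose, suppressWarnings(htdd(lmix2, 50))$dose,
               tolerance = 1e-8)
})
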