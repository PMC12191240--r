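---
title: "Isobolographic analysis of ABR hearing threshold shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isobolographic analysis of ABR hearing threshold shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otobole)
```

## The measurement and the effect metric

In acute ototoxicity studies, each animal's hearing threshold — the lowest
stimulus level (dB SPL) at which a recognisable ABR wave is detected — is
measured twice: before and after systemic drug administration. The analysis
operates on a per-animal *percent effect* derived from that pair. The
dominant convention in this literature expresses the change relative to the
pretreatment threshold,

$$E = 100 \cdot \frac{\text{post} - \text{pre}}{\text{pre}},$$

positive when hearing worsens. The literature phrase "hearing threshold
decreased by x%" is, however, not always backed by an explicit formula, so
`threshold_effect()` makes the convention an argument: the default
`"relative-pre"` above, or `"dynamic-range"`
($100 (\text{post}-\text{pre})/(90-\text{pre})$), which scales the change by
the headroom left below the 90 dB SPL stimulus ceiling. Every fitted object
records which convention produced it. Results in this vignette use the
default.

## Dose-response lines and HTDD inversion

Per agent, effects are regressed on dose by ordinary least squares
(`fit_dose_response()`), by default on the linear dose scale — graded ABR
threshold shifts over one- to two-fold dose ranges are adequately linear,
and this matches how such data are routinely assessed — with `log10` dose
offered for wider ranges. The regression uses **per-animal points, not group
means**: with 3 dose groups of 6 animals this leaves 16 residual degrees of
freedom and keeps downstream F statistics on the familiar F(2;15)-style df
structure of 18-animal designs.

The dose producing an $x\%$ effect (the *hearing threshold decrease dose*,
$\mathrm{HTDD}_x$) is the inverse prediction
$(x - b_0)/b_1$ (back-transformed for log10 lines), and its SEM comes from
the first-order delta method with gradient
$(-1/b_1,\; -(x-b_0)/b_1^2)$ applied to the coefficient covariance. Three
contracts matter in practice:

* a non-positive slope is an error — the construction presumes a toxic
  dose-effect;
* an effect level at or below the fitted intercept has no positive dose and
  is an error;
* a dose outside the fitted range is returned with an `extrapolated` flag
  and a warning, not an error, because mixture HTDDs legitimately sit near
  range edges.

Each estimate carries an *effective group size* `n_effective` (default 6,
the animals-per-dose-group of the canonical design) used only for the
degrees of freedom of later Welch comparisons; the SEM itself always comes
from the regression.

```{r htdd}
obs <- data.frame(dose = c(100, 200, 300), effect = c(12, 22, 32))
line <- fit_dose_response(obs, agent = "DRUG")
htdd(line, level = 20)
```

## The fixed-dose isobolographic transformation

The mixture design holds one agent at a constant dose $d_f$ while the other
(*variable*) agent increases. The package uses the dose-equivalence
construction for fixed-dose designs: predict the effect of $d_f$ from the
fixed agent's single-drug line, convert that effect into the equi-effective
dose of the variable agent through the inverse of the variable agent's
line (`dose_equivalent()`), and subtract:

$$A_x = \mathrm{HTDD}_x^{\text{variable alone}} - \mathrm{equiv}(d_f).$$

This is the standard Tallarida-style additive point for fixed-dose mixtures
and is an *interpretation*: published applications of the transformation
typically defer the formula to earlier methodological work, and this
reconstruction is the one consistent with the geometry of fixed-dose
isobolograms (constant dose on one axis, additive point on the mixture
line). Two boundary rules keep it total: a fixed dose of 0 contributes no
equivalent dose (the additive point then equals the single-drug HTDD, SEM
included), and an equivalent dose at or above the single-drug HTDD floors
the additive dose at 0 with a warning.

The additive point's SEM is propagated by the delta method through *both*
single-drug lines, whose coefficient estimates are treated as independent —
they come from disjoint animal cohorts — while the shared dependence of the
two terms on the variable line is handled exactly (on the linear scale the
variable intercept cancels in $A_x$; the gradient algebra reflects that).

`classify_interaction()` then applies Welch's t-test to the additive and
experimental (dose, SEM, $n_{\text{eff}}$) pairs: experimental
significantly above additive at two-sided $\alpha = 0.05$ is
**antagonistic** — in this field the desirable outcome, since more ototoxic
drug is needed for the same hearing damage — below is **synergistic**,
otherwise **additive**. An additive verdict with $p$ below the
`tendency_band` (default 0.10) is flagged as a *tendency* toward
antagonism or synergy; 0.10 is chosen because published reports label
$p \approx 0.05{-}0.10$ comparisons as tendencies while treating
$p > 0.10$ as plainly additive.

## Supporting statistics

* `anova_from_summary()` reconstructs the one-way ANOVA from (mean, SEM, n)
  only, recovering each group's sample variance as $n \cdot \mathrm{SEM}^2$;
  for equal-$n$ raw data it agrees with `anova_raw()` (a `stats::lm()`
  fit) to machine precision, which the test suite uses as a cross-check.
  A zero within-group variance is reported as an infinite F with a
  degeneracy flag rather than an exception, so simulator edge cases surface
  without crashing pipelines.
* `holm_sidak()` implements the step-down Sidak adjustment
  $1-(1-p_{(i)})^{m-i+1}$ with monotonicity enforcement, operating on
  p-values (pairwise Welch tests supply them for table-style post hoc
  comparisons).
* `welch_t_summary()` keeps the Satterthwaite df continuous; there is no
  evidence that rounding is standard here, and continuity is what
  `stats::t.test()` does.
* `power_of_f()` / `sensitivity_effect_size()` follow the convention of
  standard power software for the fixed-effects one-way ANOVA:
  noncentrality $\lambda = f^2 N$ with $N$ the *total* sample size. This
  convention is required to reproduce published sensitivity analyses (e.g.
  $f \approx 0.551$ at $\alpha = 0.05$, power 0.95, 3 groups, $N = 54$);
  the per-group convention $\lambda = f^2 n$ would not. The sensitivity
  solver brackets the root and refines until the achieved power is within
  $10^{-8}$ of the target.

```{r power}
sensitivity_effect_size(alpha = 0.05, power = 0.95, k_groups = 3,
                        total_n = 54)
```

## What the synthetic generator emulates — and what it does not

`simulate_abr_study()` reproduces the statistical structure the analysis
assumes: arms of $n$ animals (3 dose groups of 6 per line in the canonical
layout), a true percent effect that is linear in the (effective) doses with
a shared intercept, Gaussian between-animal noise **on the percent-effect
scale** (keeping the downstream linear model exact by construction),
baseline thresholds drawn from a Normal truncated to the 20–90 dB SPL
stimulus range, and post-treatment thresholds back-computed from the noisy
effect under the chosen convention (clamped to the physical 0–120 dB SPL
range). An `interaction_shift` subtracts a constant from one agent's
effective dose in mixture arms only: a positive shift models protection
(antagonism), a negative one synergy, matching the isobologram geometry in
which protection moves experimental points away from the origin.

Defaults that are assumptions rather than published values:

* `noise_sd = 15` (percent). Raw between-animal threshold variability is
  rarely reported; this value is calibrated so that the delta-method SEM of
  a recovered HTDD50 on the 3×6 design matches the ~9–10% relative SEMs of
  published HTDD tables. The suite verifies the internal consistency:
  across replicates, the empirical SD of HTDD estimates agrees with the
  mean delta-method SEM within 25%.
* `baseline_mean = 40`, `baseline_sd = 5` dB SPL — a typical anesthetised
  rodent click-ABR baseline, well inside the stimulus range.

The generator deliberately does **not** emulate: the discrete 5–10 dB
step size of threshold determination, ceiling/floor censoring of severe
losses, possible curvature of the dose-effect relation, correlation between
the pre and post measurements of one animal beyond the baseline draw, or
ABR waveform features (latencies, amplitudes). Passing tests therefore
demonstrate that the *estimators and the interaction classification* behave
correctly under the model they assume — unbiased HTDD recovery,
well-calibrated SEMs, additive data classified additive — not that real ABR
data satisfy that model.

## Validation design and numerical choices

The property and acceptance tests run at deliberately chosen problem sizes:
200 replicate studies for parameter recovery (mean recovered HTDD50 within
5% of the true 1006 mg/kg at the 3×6 design), 500 replicates for type-I
calibration of the interaction classifier, and 400–500 replicates for
coefficient coverage; these sizes put the Monte-Carlo error comfortably
below the tolerances being asserted while keeping the default test run
fast.

Two calibration subtleties are worth recording. First, with two-sided
testing at $\alpha = 0.05$ the *antagonism* false-positive rate on truly
additive data is half the nominal rate (~2.5%), the other half falling to
synergy; the suite tests the antagonism side against that split. Second,
at 3-SE half-width the coverage of regression coefficients is governed by
the Student distribution with 16 df (≈ 99.2% per coefficient, ≈ 98.5%
jointly), not the Gaussian 99.7%; the coverage test asserts the
Student-consistent bound. Using `n_effective = 6` for Welch df (rather
than the 18 animals behind each line) makes the interaction test
conservative at small samples; this mirrors how such tables are analysed
in the field and errs against false antagonism claims.

Remaining numerical choices: zero-SEM comparisons (possible only in
zero-noise simulations) short-circuit to $t = 0, p = 1$ when the doses
coincide rather than dividing by zero; reports omit timestamps by default
so identical analyses are byte-identical; TSV outputs round doses for
display (whole mg/kg at ≥ 100, two decimals below) while the JSON report
keeps full double precision.

## Known limitations

* The additive point's SEM ignores uncertainty in the *choice* of fixed
  dose (it is a design constant) and assumes the two single-drug cohorts
  are independent; shared-animal designs would need a covariance term.
* The dose-equivalence construction presumes both agents produce the effect
  through monotone dose-response lines over the relevant range; it is not a
  response-surface (Loewe/Bliss) model and does not address fixed-ratio
  designs.
* Quantal (all-or-none) endpoints are out of scope; the endpoint here is a
  graded percent threshold shift.
* With 18 animals per line, HTDD estimation is a ratio problem with
  noticeable slope uncertainty; occasional non-positive fitted slopes at
  high noise are surfaced as errors rather than silently dropped.
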