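# Fixed-dose isobolographic transformation.
#
# In the fixed-dose mixture design, increasing doses of a "variable" agent
# are co-administered with a constant dose of a "fixed" agent.  Under Loewe
# additivity the theoretically additive dose of the variable agent at effect
# level x is its single-drug HTDD_x minus the dose-equivalent of the fixed
# dose (the fixed dose's effect converted into variable-agent dose units via
# the two single-drug dose-response lines).  The experimentally observed
# mixture HTDD_x is compared with this additive prediction by Welch's t-test
# on (dose, SEM, n); a significantly larger experimental dose is antagonism
# (the desirable, otoprotective direction), a significantly smaller one
# synergy.

#' Describe a fixed-dose mixture design
#'
#' @param variable Agent administered at increasing doses.
#' @param fixed Agent administered at one constant dose.
#' @param fixed_dose Constant dose of `fixed`, mg/kg (>= 0).
#' @param modifier Optional label of a co-administered modifier
#'   (e.g. an otoprotectant at a stated dose).
#'
#' @return A list of class `"mixture_design"`.
#' @export
#' @examples
#' mixture_design("FUR", "AMI", 500, modifier = "MET 500 mg/kg")
mixture_design <- function(variable, fixed, fixed_dose, modifier = NULL) {
  stopifnot(is.character(variable), is.character(fixed))
  if (identical(variable, fixed)) {
    stop("'variable' and 'fixed' must be different agents", call. = FALSE)
  }
  .check_number(fixed_dose, "fixed_dose", lower = 0)
  structure(list(variable = variable, fixed = fixed,
                 fixed_dose = fixed_dose, modifier = modifier),
            class = "mixture_design")
}

# dose equivalent with gradients w.r.t. both lines' coefficients
.dose_equivalent_full <- function(line_fixed, line_variable, fixed_dose) {
  if (line_variable$slope <= 0) {
    stop("non-invertible variable-agent line: positive slope required",
         call. = FALSE)
  }
  zero <- list(dose = 0, grad_var = c(0, 0), grad_fix = c(0, 0))
  if (fixed_dose == 0) return(zero)  # no co-drug, no equivalence
  eff_fixed <- predict_effect(line_fixed, fixed_dose)
  if (eff_fixed <= line_variable$intercept && line_variable$scale == "linear") {
    return(zero)
  }
  inv <- .inv_predict(line_variable, eff_fixed)
  tf <- if (line_fixed$scale == "log10") log10(fixed_dose) else fixed_dose
  list(dose = inv$dose,
       grad_var = inv$grad_coef,
       grad_fix = inv$d_effect * c(1, tf))
}

#' Dose-equivalent of a fixed co-drug dose
#'
#' Predicts the effect of `fixed_dose` from the fixed agent's single-drug
#' line and converts it into the equi-effective dose of the variable agent
#' via the inverse of the variable agent's line.  Returns 0 when
#' `fixed_dose` is 0 or when the predicted effect does not exceed the
#' variable line's intercept.
#'
#' @param line_fixed,line_variable Single-drug `"dose_response_line"`s of the
#'   fixed and variable agents.
#' @param fixed_dose Constant dose of the fixed agent, mg/kg.
#'
#' @return Equivalent dose of the variable agent, mg/kg.
#' @export
#' @examples
#' lf <- fit_dose_response(data.frame(dose = 1:3, effect = 1:3), "F")
#' lv <- fit_dose_response(data.frame(dose = c(10, 20, 30),
#'                                    effect = c(1, 2, 3)), "V")
#' dose_equivalent(lf, lv, 3)  # 30
dose_equivalent <- function(line_fixed, line_variable, fixed_dose) {
  stopifnot(inherits(line_fixed, "dose_response_line"),
            inherits(line_variable, "dose_response_line"))
  .check_number(fixed_dose, "fixed_dose", lower = 0)
  .dose_equivalent_full(line_fixed, line_variable, fixed_dose)$dose
}

#' Construct an isobole point directly
#'
#' Low-level constructor used when a point's dose and SEM come from outside
#' the fitting pipeline (e.g. published summary values).
#'
#' @param dose,sem Dose and its SEM, mg/kg (`sem` >= 0).
#' @param n_effective Effective group size.
#' @param effect_level Percent effect level of the point.
#' @param role `"additive"` (theoretical point A) or `"experimental"`.
#' @param design Optional [mixture_design()].
#' @param label Optional point label (e.g. `"M"` or `"G"`).
#'
#' @return An object of class `"isobole_point"`.
#' @export
isobole_point <- function(dose, sem, n_effective, effect_level,
                          role = c("experimental", "additive"),
                          design = NULL, label = NULL) {
  role <- match.arg(role)
  .check_number(dose, "dose", lower = 0)
  .check_number(sem, "sem", lower = 0)
  .check_number(effect_level, "effect_level")
  if (!is.numeric(n_effective) || n_effective < 2) {
    stop("'n_effective' must be >= 2", call. = FALSE)
  }
  structure(list(design = design, effect_level = effect_level,
                 dose = dose, sem = sem,
                 n_effective = as.integer(n_effective),
                 role = role, label = label),
            class = "isobole_point")
}

#' Theoretically additive mixture dose (point A)
#'
#' Under Loewe additivity, the additive dose of the variable agent at the
#' effect level of `htdd_alone` is `htdd_alone$dose` minus the
#' dose-equivalent of the fixed dose.  Its SEM is propagated by the
#' first-order delta method from the coefficient covariances of both
#' single-drug lines, treated as independent (the two lines come from
#' disjoint animal cohorts); the shared dependence of the two terms on the
#' variable line is accounted for exactly.  If the dose-equivalent meets or
#' exceeds the single-drug HTDD, the additive dose is floored at 0 with a
#' warning (the fixed dose alone suffices for the effect).
#'
#' @param htdd_alone Single-drug [htdd()] estimate of the variable agent.
#' @param line_fixed,line_variable Single-drug lines of the fixed and
#'   variable agents (`line_variable` must be the source line of
#'   `htdd_alone`).
#' @param design A [mixture_design()].
#'
#' @return An `"isobole_point"` with role `"additive"`.
#' @export
additive_point <- function(htdd_alone, line_fixed, line_variable, design) {
  stopifnot(inherits(htdd_alone, "htdd_estimate"),
            inherits(design, "mixture_design"))
  inv_alone <- .inv_predict(line_variable, htdd_alone$effect_level)
  if (abs(inv_alone$dose - htdd_alone$dose) > 1e-8 * max(1, htdd_alone$dose)) {
    stop("'htdd_alone' was not derived from 'line_variable'", call. = FALSE)
  }
  eq <- .dose_equivalent_full(line_fixed, line_variable, design$fixed_dose)
  dose <- inv_alone$dose - eq$dose
  grad_var <- inv_alone$grad_coef - eq$grad_var
  grad_fix <- -eq$grad_fix
  v <- drop(t(grad_var) %*% line_variable$coef_covariance %*% grad_var) +
    drop(t(grad_fix) %*% line_fixed$coef_covariance %*% grad_fix)
  if (dose <= 0) {
    warning(sprintf(
      "additive dose floored at 0: the fixed dose of %s (%g mg/kg) alone suffices for a %g%% effect",
      design$fixed, design$fixed_dose, htdd_alone$effect_level),
      call. = FALSE)
    dose <- 0
  }
  isobole_point(dose = dose, sem = sqrt(max(v, 0)),
                n_effective = htdd_alone$n_effective,
                effect_level = htdd_alone$effect_level,
                role = "additive", design = design, label = "A")
}

#' Experimentally observed mixture dose (point M/G)
#'
#' Wraps the HTDD of the variable agent fitted on the mixture arms as an
#' experimental isobole point.
#'
#' @param htdd_mixture [htdd()] estimate from the mixture-arm line (dose axis
#'   = variable agent).
#' @param design A [mixture_design()].
#' @param label Point label, e.g. `"M"` or `"G"`.
#' @return An `"isobole_point"` with role `"experimental"`.
#' @export
experimental_point <- function(htdd_mixture, design, label = "M") {
  stopifnot(inherits(htdd_mixture, "htdd_estimate"),
            inherits(design, "mixture_design"))
  isobole_point(dose = htdd_mixture$dose, sem = htdd_mixture$sem,
                n_effective = htdd_mixture$n_effective,
                effect_level = htdd_mixture$effect_level,
                role = "experimental", design = design, label = label)
}

#' Classify a drug-drug(-otoprotectant) interaction
#'
#' Welch's t-test compares the experimentally observed mixture dose with the
#' theoretically additive one.  The verdict is `"antagonistic"` when the
#' experimental dose is significantly larger (`p < alpha`),
#' `"synergistic"` when significantly smaller, and `"additive"` otherwise.
#' An additive verdict with `p < tendency_band` is flagged as a tendency
#' toward antagonism (or synergy, by direction); the default band of 0.10
#' separates the conventional reporting of p just above 0.05 from clearly
#' non-significant comparisons.
#'
#' @param additive,experimental `"isobole_point"`s at the same effect level.
#' @param alpha Two-sided significance level (default 0.05).
#' @param tendency_band Two-sided p-value band for the tendency flag
#'   (default 0.10).
#'
#' @return An object of class `"interaction_call"`: `verdict`, `direction`
#'   (`above_additive` / `below_additive` / `at_additive`), `t_statistic`,
#'   `df`, `p_value`, `tendency_flag`, plus the two points.
#' @export
#' @examples
#' a <- isobole_point(500, 50, 6, 50, role = "additive")
#' m <- isobole_point(800, 60, 6, 50, role = "experimental")
#' classify_interaction(a, m)
classify_interaction <- function(additive, experimental, alpha = 0.05,
                                 tendency_band = 0.10) {
  stopifnot(inherits(additive, "isobole_point"),
            inherits(experimental, "isobole_point"))
  .check_prob(alpha, "alpha")
  .check_prob(tendency_band, "tendency_band")
  if (additive$effect_level != experimental$effect_level) {
    stop("points are at different effect levels", call. = FALSE)
  }
  diff <- experimental$dose - additive$dose
  if (additive$sem == 0 && experimental$sem == 0) {
    # degenerate noise-free comparison (zero-noise simulations)
    t <- if (diff == 0) 0 else sign(diff) * Inf
    df <- additive$n_effective + experimental$n_effective - 2
    p <- if (diff == 0) 1 else 0
  } else {
    wt <- welch_t_summary(experimental$dose, experimental$sem,
                          experimental$n_effective,
                          additive$dose, additive$sem,
                          additive$n_effective)
    t <- wt$t; df <- wt$df; p <- wt$p
  }
  direction <- if (diff > 0) "above_additive"
               else if (diff < 0) "below_additive" else "at_additive"
  verdict <- if (p < alpha && direction == "above_additive") "antagonistic"
             else if (p < alpha && direction == "below_additive") "synergistic"
             else "additive"
  tendency <- verdict == "additive" && p < tendency_band &&
    direction != "at_additive"
  structure(list(verdict = verdict, direction = direction,
                 t_statistic = t, df = df, p_value = p,
                 tendency_flag = tendency,
                 additive = additive, experimental = experimental),
            class = "interaction_call")
}

#' @export
print.isobole_point <- function(x, ...) {
  cat(sprintf("%s isobole point%s at %g%% effect: %.4g +/- %.3g mg/kg (n_eff = %d)\n",
              x$role, if (!is.null(x$label)) sprintf(" [%s]", x$label) else "",
              x$effect_level, x$dose, x$sem, x$n_effective))
  invisible(x)
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("Interaction at %g%% effect: %s%s\n",
              x$additive$effect_level, x$verdict,
              if (x$tendency_flag)
                sprintf(" (tendency toward %s)",
                        if (x$direction == "above_additive") "antagonism"
                        else "synergy") else ""))
  cat(sprintf("  additive %.4g +/- %.3g vs experimental %.4g +/- %.3g mg/kg\n",
              x$additive$dose, x$additive$sem,
              x$experimental$dose, x$experimental$sem))
  cat(sprintf("  Welch t = %.3f, df = %.2f, p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  invisible(x)
}
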