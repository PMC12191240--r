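# Percent threshold effects, dose-response regression, and inverse
# prediction of HTDD_x doses with delta-method standard errors.

#' Percent change in hearing threshold
#'
#' Converts a pre/post pair of ABR hearing thresholds into a percent effect.
#' Two conventions are supported:
#'
#' * `"relative-pre"` (default): `100 * (post - pre) / pre`, the percent
#'   change relative to the pretreatment threshold.
#' * `"dynamic-range"`: `100 * (post - pre) / (90 - pre)`, the change as a
#'   fraction of the remaining dynamic range up to the 90 dB SPL stimulus
#'   ceiling.
#'
#' Under both, the sign is positive when hearing worsens (the threshold
#' rises).
#'
#' @param pre,post Hearing thresholds in dB SPL; `pre` must be > 0
#'   (and < 90 under `"dynamic-range"`). Vectorized.
#' @param convention Effect convention.
#'
#' @return Percent effect(s).
#' @export
#' @examples
#' threshold_effect(40, 60)   # 50
#' threshold_effect(50, 40)   # -20: hearing improved
threshold_effect <- function(pre, post,
                             convention = c("relative-pre", "dynamic-range")) {
  convention <- match.arg(convention)
  if (!is.numeric(pre) || !is.numeric(post) || anyNA(pre) || anyNA(post)) {
    stop("'pre' and 'post' must be numeric thresholds in dB SPL",
         call. = FALSE)
  }
  if (any(pre <= 0)) {
    stop("invalid baseline: 'pre_threshold' must be > 0 dB SPL",
         call. = FALSE)
  }
  switch(convention,
    "relative-pre" = 100 * (post - pre) / pre,
    "dynamic-range" = {
      if (any(pre >= 90)) {
        stop("invalid baseline: 'pre_threshold' must be < 90 dB SPL under the dynamic-range convention",
             call. = FALSE)
      }
      100 * (post - pre) / (90 - pre)
    })
}

#' Per-animal effect observations for one agent
#'
#' @param records An `"abr_records"` data frame (see [simulate_abr_study()]
#'   or [read_abr_records()]).
#' @param agent Agent whose `dose_<agent>` column supplies the dose axis.
#' @param convention Passed to [threshold_effect()].
#'
#' @return Data frame with columns `animal_id`, `dose`, `effect`.
#' @export
abr_effects <- function(records, agent,
                        convention = c("relative-pre", "dynamic-range")) {
  convention <- match.arg(convention)
  col <- paste0("dose_", agent)
  for (needed in c(col, "pre_db", "post_db")) {
    if (!needed %in% names(records)) {
      stop(sprintf("records lack required column '%s'", needed),
           call. = FALSE)
    }
  }
  data.frame(
    animal_id = as.character(records$animal_id),
    dose = records[[col]],
    effect = threshold_effect(records$pre_db, records$post_db, convention),
    stringsAsFactors = FALSE)
}

#' Fit a linear dose-response line
#'
#' Ordinary least squares of per-animal percent effects on dose (or log10
#' dose).  Per-animal points, not group means, are used, so the residual
#' degrees of freedom reflect the full animal count.
#'
#' @param x Either an `"abr_records"` data frame (then `agent` is required)
#'   or a data frame with columns `dose` and `effect`.
#' @param agent Agent name (dose column `dose_<agent>`); also recorded in the
#'   fitted line.
#' @param scale `"linear"` (default) or `"log10"`; the latter requires all
#'   doses > 0.
#' @param convention Effect convention, see [threshold_effect()].
#' @param arms Optional character vector restricting `x` to a subset of arms
#'   (only for `"abr_records"` input).
#'
#' @return An object of class `"dose_response_line"`: a list with elements
#'   `agent`, `scale`, `convention`, `slope`, `intercept` (percent),
#'   `coef_covariance` (2x2, order intercept then slope), `residual_sd`,
#'   `n_animals` and `dose_range` (mg/kg).
#' @export
#' @examples
#' obs <- data.frame(dose = rep(c(100, 200, 300), each = 2))
#' obs$effect <- 0.05 * obs$dose
#' fit_dose_response(obs, agent = "DRUG")
fit_dose_response <- function(x, agent = NULL,
                              scale = c("linear", "log10"),
                              convention = c("relative-pre", "dynamic-range"),
                              arms = NULL) {
  scale <- match.arg(scale)
  convention <- match.arg(convention)
  if (all(c("dose", "effect") %in% names(x))) {
    obs <- x[, c("dose", "effect")]
    if (is.null(agent)) agent <- "agent"
  } else {
    if (is.null(agent)) {
      stop("'agent' is required when fitting from ABR records", call. = FALSE)
    }
    if (!is.null(arms)) x <- x[x$arm %in% arms, , drop = FALSE]
    obs <- abr_effects(x, agent, convention)
  }
  obs <- obs[is.finite(obs$dose) & is.finite(obs$effect), , drop = FALSE]
  if (nrow(obs) < 3L) {
    stop("at least 3 effect observations are required", call. = FALSE)
  }
  if (length(unique(obs$dose)) < 2L) {
    stop("singular design: all doses are identical", call. = FALSE)
  }
  if (any(obs$dose < 0)) {
    stop("doses must be >= 0", call. = FALSE)
  }
  if (scale == "log10" && any(obs$dose <= 0)) {
    stop("log10 dose scale requires all doses > 0", call. = FALSE)
  }
  d <- if (scale == "log10") log10(obs$dose) else obs$dose
  fit <- lm(obs$effect ~ d)
  cf <- coef(fit)
  # suppressWarnings: summary.lm warns on numerically perfect (zero-noise) fits
  V <- suppressWarnings(vcov(fit))
  s <- suppressWarnings(summary(fit)$sigma)
  # a numerically exact fit can leave tiny negative round-off in vcov
  if (!is.finite(s)) s <- 0
  structure(list(
    agent = agent, scale = scale, convention = convention,
    slope = unname(cf[2L]), intercept = unname(cf[1L]),
    coef_covariance = unname(V), residual_sd = s,
    n_animals = nrow(obs),
    dose_range = range(obs$dose)),
    class = "dose_response_line")
}

#' Predicted percent effect at a dose
#'
#' @param line A `"dose_response_line"`.
#' @param dose Dose(s), mg/kg. Must be > 0 for log10-scale lines.
#' @return Percent effect(s).
#' @export
predict_effect <- function(line, dose) {
  stopifnot(inherits(line, "dose_response_line"))
  .check_number(dose, "dose", lower = 0)
  d <- if (line$scale == "log10") {
    if (any(dose <= 0)) stop("log10-scale line needs dose > 0", call. = FALSE)
    log10(dose)
  } else dose
  line$intercept + line$slope * d
}

# Inverse prediction with gradient.
# Returns the dose at which the line reaches `effect`, plus the gradient of
# that dose w.r.t. (intercept, slope) and w.r.t. the target effect itself
# (needed when the target effect is an estimate from another line).
.inv_predict <- function(line, effect) {
  b0 <- line$intercept
  b1 <- line$slope
  z <- (effect - b0) / b1
  if (line$scale == "log10") {
    dose <- 10^z
    s <- dose * log(10)
  } else {
    dose <- z
    s <- 1
  }
  list(dose = dose,
       grad_coef = c(-s / b1, -s * z / b1),  # d dose / d (b0, b1)
       d_effect = s / b1)                    # d dose / d effect
}

#' Dose producing an x% hearing threshold change (HTDD_x)
#'
#' Inverts a fitted dose-response line at the requested effect level.  The
#' standard error is obtained by the first-order delta method from the
#' coefficient covariance of the fit; for log10-scale lines the inversion is
#' back-transformed to mg/kg.  Doses outside the fitted dose range are
#' returned with `extrapolated = TRUE` and a warning rather than an error,
#' since mixture HTDDs legitimately sit near range edges.
#'
#' @param line A `"dose_response_line"` with positive slope.
#' @param level Effect level in percent (20 and 50 are conventional, any
#'   value in (0, 100) is accepted).
#' @param n_effective Effective group size carried into downstream Welch
#'   tests; defaults to 6, the animals-per-dose-group of the canonical 3x6
#'   design.
#'
#' @return An object of class `"htdd_estimate"`: `agent`, `effect_level`,
#'   `dose`, `sem` (both mg/kg), `n_effective`, `extrapolated`, and the
#'   source `line`.
#' @export
#' @examples
#' obs <- data.frame(dose = c(100, 200, 300), effect = c(10, 20, 30))
#' htdd(fit_dose_response(obs, "DRUG"), level = 20)
htdd <- function(line, level, n_effective = 6L) {
  stopifnot(inherits(line, "dose_response_line"))
  .check_number(level, "effect_level")
  if (length(level) != 1L) stop("'level' must be a single value", call. = FALSE)
  if (!is.numeric(n_effective) || n_effective < 2) {
    stop("'n_effective' must be >= 2", call. = FALSE)
  }
  if (line$slope == 0) {
    stop("non-invertible line: slope is zero", call. = FALSE)
  }
  if (line$slope < 0) {
    stop("non-invertible line: a positive dose-effect slope is required",
         call. = FALSE)
  }
  inv <- .inv_predict(line, level)
  if (line$scale == "linear" && inv$dose <= 0) {
    stop(sprintf(
      "effect level %g%% is at or below the fitted intercept (%.3g%%); no positive dose attains it",
      level, line$intercept), call. = FALSE)
  }
  v <- drop(t(inv$grad_coef) %*% line$coef_covariance %*% inv$grad_coef)
  sem <- sqrt(max(v, 0))
  extrapolated <- inv$dose < line$dose_range[1L] ||
    inv$dose > line$dose_range[2L]
  if (extrapolated) {
    warning(sprintf(
      "HTDD%g of %s (%.4g mg/kg) lies outside the fitted dose range [%g, %g]",
      level, line$agent, inv$dose, line$dose_range[1L], line$dose_range[2L]),
      call. = FALSE)
  }
  structure(list(agent = line$agent, effect_level = level,
                 dose = inv$dose, sem = sem,
                 n_effective = as.integer(n_effective),
                 extrapolated = extrapolated, line = line),
            class = "htdd_estimate")
}

#' @export
print.dose_response_line <- function(x, ...) {
  cat(sprintf("Dose-response line for %s (%s dose scale, %s effects)\n",
              x$agent, x$scale, x$convention))
  cat(sprintf("  effect = %.4g + %.4g * %s\n", x$intercept, x$slope,
              if (x$scale == "log10") "log10(dose)" else "dose"))
  cat(sprintf("  n = %d animals, dose range [%g, %g] mg/kg, residual SD %.3g%%\n",
              x$n_animals, x$dose_range[1L], x$dose_range[2L], x$residual_sd))
  invisible(x)
}

#' @export
print.htdd_estimate <- function(x, ...) {
  cat(sprintf("HTDD%g of %s: %.4g +/- %.3g mg/kg (n_eff = %d%s)\n",
              x$effect_level, x$agent, x$dose, x$sem, x$n_effective,
              if (x$extrapolated) ", extrapolated" else ""))
  invisible(x)
}
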