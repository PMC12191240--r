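# Synthetic ABR studies with a known linear dose-effect structure.
#
# The generator mirrors the design of acute mouse ototoxicity experiments:
# each dose-response line is estimated from 3 dose groups of 6 animals, the
# hearing threshold of every animal is measured twice (pre/post treatment),
# and the analysis operates on the percent threshold change.  Noise is
# applied on the percent-effect scale so the linear model assumed downstream
# is exact by construction.

#' Define one treatment arm of a synthetic ABR study
#'
#' @param label Arm label, e.g. `"AMI_600"`. Must be non-empty.
#' @param doses Named numeric vector of agent doses in mg/kg, e.g.
#'   `c(AMI = 600)` or `c(FUR = 40, AMI = 500)`. All doses must be >= 0.
#' @param n Number of animals in the arm (>= 2).
#'
#' @return A list of class `"abr_arm"`.
#' @seealso [abr_design()]
#' @export
#' @examples
#' abr_arm("AMI_600", c(AMI = 600), n = 6)
abr_arm <- function(label, doses, n = 6L) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("'label' must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(doses) || is.null(names(doses)) || any(!nzchar(names(doses)))) {
    stop("'doses' must be a named numeric vector (agent = mg/kg)",
         call. = FALSE)
  }
  .check_number(doses, "doses", lower = 0)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2 || n != round(n)) {
    stop("'n_animals' must be an integer >= 2 per arm", call. = FALSE)
  }
  structure(list(label = label, doses = doses, n = as.integer(n)),
            class = "abr_arm")
}

#' Define a synthetic ABR study
#'
#' The true per-animal percent effect is
#' `intercept + sum(slopes * effective_doses)`, perturbed by Gaussian noise
#' of standard deviation `noise_sd` (percent).  An optional
#' `interaction_shift` subtracts a fixed dose offset (mg/kg) from one agent's
#' effective dose in mixture arms (arms dosing two or more agents): a
#' positive offset encodes protection/antagonism (more drug is needed for the
#' same effect), a negative one synergy.
#'
#' Baseline (pretreatment) thresholds are drawn from a Normal truncated to
#' the 20-90 dB SPL stimulus range of the ABR protocol; the post-treatment
#' threshold is back-computed from the true effect under the chosen effect
#' convention (see [threshold_effect()]).
#'
#' @param arms List of [abr_arm()] objects.
#' @param slopes Named numeric vector: percent effect per mg/kg for each
#'   agent.
#' @param intercept Shared intercept of the effect model, percent.
#' @param noise_sd Between-animal SD of the percent effect (>= 0). The
#'   default of 15 percent is an assumption (raw between-animal variability is
#'   rarely reported); it is calibrated so that delta-method HTDD50 SEMs on a
#'   3x6 design have the magnitude (around 9-10 percent of the dose) seen in
#'   published HTDD tables.
#' @param interaction_shift `NULL` for pure additivity, or a single named
#'   number, e.g. `c(AMI = 150)`, the dose offset applied to that agent in
#'   mixture arms.
#' @param baseline_mean,baseline_sd Mean and SD (dB SPL) of the pretreatment
#'   threshold distribution; `baseline_mean` must lie within the 20-90 dB SPL
#'   stimulus range.
#' @param effect_convention Convention used to back-compute post-treatment
#'   thresholds; see [threshold_effect()].
#'
#' @return A list of class `"abr_design"`.
#' @seealso [simulate_abr_study()]
#' @export
#' @examples
#' design <- abr_design(
#'   arms = lapply(c(600, 900, 1200), function(d)
#'     abr_arm(paste0("AMI_", d), c(AMI = d), n = 6)),
#'   slopes = c(AMI = 0.0497), intercept = 0, noise_sd = 18
#' )
abr_design <- function(arms, slopes, intercept = 0, noise_sd = 15,
                       interaction_shift = NULL,
                       baseline_mean = 40, baseline_sd = 5,
                       effect_convention = c("relative-pre", "dynamic-range")) {
  effect_convention <- match.arg(effect_convention)
  if (inherits(arms, "abr_arm")) arms <- list(arms)
  if (!is.list(arms) || length(arms) == 0L ||
      !all(vapply(arms, inherits, logical(1), "abr_arm"))) {
    stop("'arms' must be a non-empty list of abr_arm() objects", call. = FALSE)
  }
  labels <- vapply(arms, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("arm labels must be unique", call. = FALSE)
  }
  if (!is.numeric(slopes) || is.null(names(slopes))) {
    stop("'slopes' must be a named numeric vector (agent = percent per mg/kg)",
         call. = FALSE)
  }
  .check_number(intercept, "intercept")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) ||
      noise_sd < 0) {
    stop("'noise_sd' must be >= 0", call. = FALSE)
  }
  .check_number(baseline_mean, "baseline_mean", lower = 20, upper = 90)
  .check_number(baseline_sd, "baseline_sd", lower = 0)
  if (!is.null(interaction_shift)) {
    if (!is.numeric(interaction_shift) || length(interaction_shift) != 1L ||
        is.null(names(interaction_shift))) {
      stop("'interaction_shift' must be a single named number (agent = mg/kg)",
           call. = FALSE)
    }
    if (!names(interaction_shift) %in% names(slopes)) {
      stop("'interaction_shift' names an agent absent from 'slopes'",
           call. = FALSE)
    }
  }
  for (a in arms) {
    unknown <- setdiff(names(a$doses), names(slopes))
    if (length(unknown)) {
      stop(sprintf("arm '%s' doses agent(s) %s absent from 'slopes'",
                   a$label, paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(arms = arms, slopes = slopes, intercept = intercept,
                 noise_sd = noise_sd, interaction_shift = interaction_shift,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 effect_convention = effect_convention),
            class = "abr_design")
}

# truncated-normal draws via inverse CDF: deterministic given the RNG stream
.rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Simulate an ABR study
#'
#' Generates one record per animal.  Each animal's true percent effect
#' follows the design's linear effect model; the observed effect adds
#' Gaussian noise on the percent scale, and the post-treatment threshold is
#' back-computed from the (noisy) effect and the simulated pretreatment
#' threshold.  Thresholds are clamped to the physical 0-120 dB SPL range.
#'
#' @param design An [abr_design()].
#' @param seed Integer seed; identical seeds give identical studies.
#'
#' @return A data frame of class `"abr_records"` with columns `animal_id`,
#'   `arm`, one `dose_<agent>` column per agent, `pre_db` and `post_db`.
#' @export
#' @examples
#' design <- abr_design(
#'   arms = list(abr_arm("A200", c(DRUG = 200), n = 6)),
#'   slopes = c(DRUG = 0.1), noise_sd = 0
#' )
#' simulate_abr_study(design, seed = 1)
simulate_abr_study <- function(design, seed = NULL) {
  stopifnot(inherits(design, "abr_design"))
  if (!is.null(seed)) set.seed(seed)
  agents <- names(design$slopes)
  shift_agent <- names(design$interaction_shift)
  rows <- lapply(design$arms, function(arm) {
    doses <- setNames(rep(0, length(agents)), agents)
    doses[names(arm$doses)] <- arm$doses
    eff_doses <- doses
    n_dosed <- sum(doses > 0)
    if (!is.null(shift_agent) && n_dosed >= 2L && doses[shift_agent] > 0) {
      eff_doses[shift_agent] <- eff_doses[shift_agent] -
        unname(design$interaction_shift)
    }
    true_effect <- design$intercept + sum(design$slopes * eff_doses)
    obs_effect <- true_effect + rnorm(arm$n, 0, design$noise_sd)
    pre <- .rnorm_trunc(arm$n, design$baseline_mean, design$baseline_sd,
                        20, 90)
    post <- switch(design$effect_convention,
      "relative-pre"  = pre * (1 + obs_effect / 100),
      "dynamic-range" = pre + obs_effect / 100 * (90 - pre))
    post <- pmin(pmax(post, 0), 120)
    out <- data.frame(
      animal_id = sprintf("%s_%02d", arm$label, seq_len(arm$n)),
      arm = arm$label, stringsAsFactors = FALSE)
    for (ag in agents) out[[paste0("dose_", ag)]] <- unname(doses[ag])
    out$pre_db <- pre
    out$post_db <- post
    out
  })
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  attr(records, "effect_convention") <- design$effect_convention
  class(records) <- c("abr_records", "data.frame")
  records
}

#' Convenience constructor for a 3-dose single-agent study design
#'
#' The canonical design behind one dose-response line: `length(doses)` dose
#' groups (3 in the canonical layout) of `n` animals each.
#'
#' @param agent Agent name.
#' @param doses Numeric vector of doses, mg/kg.
#' @param slope Percent effect per mg/kg.
#' @param intercept Percent.
#' @param n Animals per dose group.
#' @inheritParams abr_design
#' @param ... Passed to [abr_design()].
#'
#' @return An [abr_design()].
#' @export
single_agent_design <- function(agent, doses = c(600, 900, 1200),
                                slope = 0.0497, intercept = 0, n = 6,
                                noise_sd = 15, ...) {
  arms <- lapply(doses, function(d) {
    abr_arm(sprintf("%s_%g", agent, d), setNames(d, agent), n = n)
  })
  abr_design(arms = arms, slopes = setNames(slope, agent),
             intercept = intercept, noise_sd = noise_sd, ...)
}
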