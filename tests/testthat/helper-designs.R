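# Canonical synthetic designs used across the suite.
#
# The single-agent design mirrors the canonical 3-dose x 6-animal layout of
# one dose-response line; the two-agent design adds a fixed-dose mixture
# series (variable FUR + constant AMI 500 mg/kg) with a shared intercept, so
# that simulated mixtures are exactly additive unless an interaction_shift
# is requested.

ami_recovery_design <- function(noise_sd = 15, n = 6) {
  # slope chosen so the true HTDD50 is 1006 mg/kg
  single_agent_design("AMI", doses = c(600, 900, 1200), slope = 50 / 1006,
                      intercept = 0, n = n, noise_sd = noise_sd)
}

two_agent_arms <- function(mix_doses = c(40, 80, 120), fixed_dose = 500) {
  c(
    lapply(c(400, 800, 1200), function(d)
      abr_arm(sprintf("AMI_%d", d), c(AMI = d))),
    lapply(c(60, 120, 180), function(d)
      abr_arm(sprintf("FUR_%d", d), c(FUR = d))),
    lapply(mix_doses, function(d)
      abr_arm(sprintf("MIX_%d", d), c(FUR = d, AMI = fixed_dose)))
  )
}

additive_design <- function(noise_sd = 15, interaction_shift = NULL,
                            mix_doses = c(40, 80, 120), fixed_dose = 500) {
  abr_design(two_agent_arms(mix_doses, fixed_dose),
             slopes = c(AMI = 0.0497, FUR = 0.3), intercept = 0,
             noise_sd = noise_sd, interaction_shift = interaction_shift)
}

# fit the three series of a two-agent study by arm-label prefix
fit_series <- function(records, agent, prefix, ...) {
  fit_dose_response(records, agent = agent,
                    arms = grep(prefix, unique(records$arm), value = TRUE),
                    ...)
}

# one replicate of the additive-study isobole comparison at a given level
classify_replicate <- function(seed, level = 50, design = additive_design()) {
  rec <- simulate_abr_study(design, seed = seed)
  lv <- suppressWarnings(fit_series(rec, "FUR", "^FUR"))
  lf <- suppressWarnings(fit_series(rec, "AMI", "^AMI"))
  lmix <- suppressWarnings(fit_series(rec, "FUR", "^MIX"))
  mx <- mixture_design("FUR", "AMI", 500)
  ha <- suppressWarnings(htdd(lv, level))
  hm <- suppressWarnings(htdd(lmix, level))
  ap <- suppressWarnings(additive_point(ha, lf, lv, mx))
  classify_interaction(ap, experimental_point(hm, mx))
}
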