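Package: otobole
Title: Isobolographic Analysis of Drug-Induced Hearing Threshold Shifts
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies ototoxic drug interactions from auditory brainstem
    response (ABR) hearing thresholds.  Computes per-animal percent threshold
    shifts, fits linear dose-response lines, and inverts them to the doses
    producing a stated percent hearing threshold change (HTDD20, HTDD50) with
    delta-method standard errors.  A fixed-dose isobolographic transformation
    compares the theoretically additive mixture dose with the experimentally
    observed one and classifies the interaction as additive, antagonistic or
    synergistic via Welch's t-test.  Supporting statistics include a one-way
    ANOVA reconstructed from group summaries (mean, SEM, n), Holm-Sidak
    step-down adjustment, central-F critical values, and noncentral-F power
    and sensitivity effect-size calculations.  A synthetic ABR study
    generator with known dose-effect structure validates every stage of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
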