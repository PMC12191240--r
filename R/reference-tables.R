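# Published HTDD group summaries used as worked-example inputs.

#' Reference HTDD summary values from a mouse ototoxicity study
#'
#' Group summaries (mean +/- SEM mg/kg, n = 6 per dose group's HTDD
#' estimate) from a published acute mouse study of amikacin (AMI) and
#' furosemide (FUR) ototoxicity with methionine (MET) or glutathione (GLUT)
#' pretreatment at 500 mg/kg.  Four dose-response series were run: AMI
#' alone, AMI with a constant 30 mg/kg of FUR, FUR alone, and FUR with a
#' constant 500 mg/kg of AMI; in each, animals received vehicle (VEH), GLUT
#' or MET.  The tabulated HTDD20/HTDD50 values are the doses of the variable
#' agent producing a 20% or 50% hearing threshold change.
#'
#' These printed summaries are inputs for the summary-statistics ANOVA
#' ([anova_from_summary()]), Welch comparisons ([welch_t_summary()]) and
#' percent-change reporting ([percent_change()]).
#'
#' @return Data frame with columns `series` (one of `"AMI"`, `"AMI+FUR30"`,
#'   `"FUR"`, `"FUR+AMI500"`), `pretreatment` (`"VEH"`, `"GLUT"`, `"MET"`),
#'   `level` (20 or 50), `mean`, `sem` (mg/kg) and `n`.
#' @export
#' @examples
#' tab <- ototox_reference_summaries()
#' g <- subset(tab, series == "FUR+AMI500" & level == 20)
#' anova_from_summary(g$mean, g$sem, g$n, g$pretreatment)
ototox_reference_summaries <- function() {
  rows <- rbind(
    c("AMI",        "VEH",  20, 797,   64),
    c("AMI",        "GLUT", 20, 666,   60),
    c("AMI",        "MET",  20, 922,   78),
    c("AMI",        "VEH",  50, 1006,  95),
    c("AMI",        "GLUT", 50, 945,   88),
    c("AMI",        "MET",  50, 1141,  91),
    c("AMI+FUR30",  "VEH",  20, 377,   58),
    c("AMI+FUR30",  "GLUT", 20, 336,   51),
    c("AMI+FUR30",  "MET",  20, 511,   65),
    c("AMI+FUR30",  "VEH",  50, 428,   56),
    c("AMI+FUR30",  "GLUT", 50, 415,   56),
    c("AMI+FUR30",  "MET",  50, 701,   60),
    c("FUR",        "VEH",  20, 56.25, 4.89),
    c("FUR",        "GLUT", 20, 59.38, 4.92),
    c("FUR",        "MET",  20, 63.07, 5.02),
    c("FUR",        "VEH",  50, 63.24, 4.68),
    c("FUR",        "GLUT", 50, 62.90, 4.83),
    c("FUR",        "MET",  50, 77.77, 5.01),
    c("FUR+AMI500", "VEH",  20, 37.35, 4.10),
    c("FUR+AMI500", "GLUT", 20, 33.37, 4.09),
    c("FUR+AMI500", "MET",  20, 61.00, 4.72),
    c("FUR+AMI500", "VEH",  50, 46.73, 4.39),
    c("FUR+AMI500", "GLUT", 50, 52.83, 4.79),
    c("FUR+AMI500", "MET",  50, 77.94, 4.93))
  data.frame(series = rows[, 1L], pretreatment = rows[, 2L],
             level = as.numeric(rows[, 3L]), mean = as.numeric(rows[, 4L]),
             sem = as.numeric(rows[, 5L]), n = 6L,
             stringsAsFactors = FALSE)
}
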