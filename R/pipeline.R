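# End-to-end driver: from per-animal ABR records to HTDD tables, isobole
# points and interaction verdicts.

#' Analysis configuration
#'
#' @param effect_convention See [threshold_effect()].
#' @param dose_scale `"linear"` or `"log10"`, see [fit_dose_response()].
#' @param alpha Two-sided significance level for interaction calls.
#' @param tendency_band p-value band for the tendency flag, see
#'   [classify_interaction()].
#' @param levels Effect levels (percent) at which HTDDs are computed; each
#'   must lie in (0, 100).
#' @param n_effective Effective group size attached to HTDD estimates.
#' @param seed Optional integer echoed into the report for provenance.
#'
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(effect_convention = c("relative-pre",
                                                  "dynamic-range"),
                            dose_scale = c("linear", "log10"),
                            alpha = 0.05, tendency_band = 0.10,
                            levels = c(20, 50), n_effective = 6L,
                            seed = NULL) {
  effect_convention <- match.arg(effect_convention)
  dose_scale <- match.arg(dose_scale)
  .check_prob(alpha, "alpha")
  .check_prob(tendency_band, "tendency_band")
  if (length(levels) == 0L || any(levels <= 0) || any(levels >= 100)) {
    stop("'levels' must be a non-empty vector of percentages in (0, 100)",
         call. = FALSE)
  }
  structure(list(effect_convention = effect_convention,
                 dose_scale = dose_scale, alpha = alpha,
                 tendency_band = tendency_band, levels = levels,
                 n_effective = as.integer(n_effective), seed = seed),
            class = "analysis_config")
}

# per-arm dose table: one row per arm, one column per agent
.arm_dose_table <- function(records) {
  dose_cols <- grep("^dose_", names(records), value = TRUE)
  if (length(dose_cols) == 0L) {
    stop("records carry no 'dose_<agent>' columns", call. = FALSE)
  }
  arms <- unique(records$arm)
  tab <- sapply(dose_cols, function(col) {
    vapply(arms, function(a) {
      d <- unique(records[[col]][records$arm == a])
      if (length(d) != 1L) {
        stop(sprintf("arm '%s' has non-constant '%s'", a, col), call. = FALSE)
      }
      d
    }, numeric(1))
  })
  tab <- matrix(tab, nrow = length(arms),
                dimnames = list(arms, sub("^dose_", "", dose_cols)))
  tab
}

#' Run the full isobolographic analysis pipeline
#'
#' Identifies single-agent and fixed-dose mixture series from the arm
#' structure of the records, fits one dose-response line per series, inverts
#' each line at the configured effect levels, builds additive and
#' experimental isobole points for every mixture, classifies the
#' interactions, and summarises HTDDs across series with the
#' summary-statistics ANOVA.
#'
#' Arms dosing exactly one agent form that agent's single-drug series; arms
#' dosing two agents are grouped by the agent held at a constant dose (the
#' fixed agent) while the other varies.  Every mixture requires single-drug
#' reference lines for both of its agents.
#'
#' The result is deterministic: running the same records with the same
#' configuration twice yields identical reports.
#'
#' @param records An `"abr_records"` data frame.
#' @param config An [analysis_config()].
#'
#' @return An object of class `"abr_run_report"`: `config`, `htdd` (data
#'   frame: series, agent, level, dose, sem, n, extrapolated), `isobole`
#'   (data frame: series, level, additive dose/sem, experimental dose/sem,
#'   t, df, p, verdict, tendency), `interaction_calls`, `anova`, `lines`,
#'   `version`.
#' @export
run_pipeline <- function(records, config = analysis_config()) {
  stopifnot(is.data.frame(records))
  if (!inherits(config, "analysis_config")) {
    stop("'config' must be an analysis_config()", call. = FALSE)
  }
  dose_tab <- .arm_dose_table(records)
  agents <- colnames(dose_tab)
  dosed <- dose_tab > 0
  n_dosed <- rowSums(dosed)

  lines <- list()
  htdd_rows <- list()
  add_htdd <- function(series, est) {
    htdd_rows[[length(htdd_rows) + 1L]] <<- data.frame(
      series = series, agent = est$agent, level = est$effect_level,
      dose = est$dose, sem = est$sem, n = est$n_effective,
      extrapolated = est$extrapolated, stringsAsFactors = FALSE)
  }

  # single-agent series
  single_lines <- list()
  for (a in agents) {
    arm_set <- rownames(dose_tab)[n_dosed == 1L & dosed[, a]]
    if (length(arm_set) == 0L) next
    doses <- dose_tab[arm_set, a]
    if (length(unique(doses)) < 2L) {
      stop(sprintf("single-agent arms of '%s' contain fewer than 2 distinct doses", a),
           call. = FALSE)
    }
    line <- fit_dose_response(records, agent = a, scale = config$dose_scale,
                              convention = config$effect_convention,
                              arms = arm_set)
    single_lines[[a]] <- line
    lines[[a]] <- line
    for (lv in config$levels) {
      add_htdd(a, htdd(line, lv, config$n_effective))
    }
  }

  # fixed-dose mixture series
  iso_rows <- list()
  calls <- list()
  mix_arms <- rownames(dose_tab)[n_dosed == 2L]
  if (any(n_dosed > 2L)) {
    stop("arms dosing more than 2 agents are not supported", call. = FALSE)
  }
  if (length(mix_arms)) {
    pair_key <- vapply(mix_arms, function(a) {
      paste(sort(agents[dosed[a, ]]), collapse = "|")
    }, character(1))
    for (key in unique(pair_key)) {
      grp <- mix_arms[pair_key == key]
      pair <- strsplit(key, "|", fixed = TRUE)[[1L]]
      varies <- vapply(pair, function(a) {
        length(unique(dose_tab[grp, a])) > 1L
      }, logical(1))
      if (sum(varies) != 1L) {
        stop(sprintf("mixture arms (%s) must vary exactly one agent's dose",
                     paste(grp, collapse = ", ")), call. = FALSE)
      }
      variable <- pair[varies]
      fixed <- pair[!varies]
      fixed_dose <- unique(dose_tab[grp, fixed])
      for (a in pair) {
        if (is.null(single_lines[[a]])) {
          stop(sprintf("mixture arms dosing '%s' lack a single-agent reference line for it", a),
               call. = FALSE)
        }
      }
      series <- sprintf("%s+%s(%g)", variable, fixed, fixed_dose)
      design <- mixture_design(variable, fixed, fixed_dose)
      mix_line <- fit_dose_response(records, agent = variable,
                                    scale = config$dose_scale,
                                    convention = config$effect_convention,
                                    arms = grp)
      mix_line$agent <- variable
      lines[[series]] <- mix_line
      for (lv in config$levels) {
        est_mix <- htdd(mix_line, lv, config$n_effective)
        add_htdd(series, est_mix)
        est_alone <- htdd(single_lines[[variable]], lv, config$n_effective)
        addp <- additive_point(est_alone, single_lines[[fixed]],
                               single_lines[[variable]], design)
        expp <- experimental_point(est_mix, design)
        call <- classify_interaction(addp, expp, alpha = config$alpha,
                                     tendency_band = config$tendency_band)
        calls[[sprintf("%s@%g", series, lv)]] <- call
        iso_rows[[length(iso_rows) + 1L]] <- data.frame(
          series = series, level = lv,
          additive_dose = addp$dose, additive_sem = addp$sem,
          experimental_dose = expp$dose, experimental_sem = expp$sem,
          t = call$t_statistic, df = call$df, p = call$p_value,
          verdict = call$verdict, tendency = call$tendency_flag,
          stringsAsFactors = FALSE)
      }
    }
  }

  htdd_df <- do.call(rbind, htdd_rows)
  iso_df <- if (length(iso_rows)) do.call(rbind, iso_rows) else NULL

  # summary-statistics ANOVA across series sharing a variable agent
  anovas <- list()
  if (!is.null(htdd_df)) {
    for (a in unique(htdd_df$agent)) {
      for (lv in config$levels) {
        sub <- htdd_df[htdd_df$agent == a & htdd_df$level == lv &
                         htdd_df$sem > 0, , drop = FALSE]
        if (nrow(sub) >= 2L) {
          anovas[[sprintf("%s@%g", a, lv)]] <-
            anova_from_summary(sub$dose, sub$sem, sub$n, sub$series)
        }
      }
    }
  }

  structure(list(config = config, htdd = htdd_df, isobole = iso_df,
                 interaction_calls = calls, anova = anovas, lines = lines,
                 version = as.character(packageVersion("otobole")),
                 timestamp = NULL),
            class = "abr_run_report")
}

# drop S3 classes (but keep data frames) so jsonlite serialises plainly
.strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), .strip_classes))
  x
}

# display rounding used by the TSV outputs: whole mg/kg for large doses,
# two decimals otherwise (purely presentational)
.display_round <- function(x) {
  ifelse(abs(x) >= 100, sprintf("%.0f", x), sprintf("%.2f", x))
}

#' Write a run report to disk
#'
#' Emits `report.json` (full double precision) plus two TSV summaries:
#' `htdd_summary.tsv` (one row per series and level: dose +/- SEM, n,
#' ANOVA F and p of the across-series comparison) and, when mixtures are
#' present, `isobole.tsv` (additive vs experimental points with Welch t, df,
#' p, verdict and tendency flag).  TSV doses are rounded for display; the
#' JSON carries the exact values.
#'
#' @param report An `"abr_run_report"`.
#' @param dir Output directory (created if needed).
#' @param stamp If `TRUE`, add a timestamp to the JSON (off by default so
#'   identical analyses produce byte-identical reports).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir, stamp = FALSE) {
  stopifnot(inherits(report, "abr_run_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rep <- report
  rep$interaction_calls <- NULL   # fully contained in $isobole
  rep$lines <- lapply(report$lines, function(l) {
    l$coef_covariance <- as.vector(l$coef_covariance)
    l
  })
  if (stamp) rep$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(.strip_classes(rep), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  htdd <- report$htdd
  if (!is.null(htdd)) {
    f_col <- p_col <- rep(NA_character_, nrow(htdd))
    for (key in names(report$anova)) {
      parts <- strsplit(key, "@", fixed = TRUE)[[1L]]
      sel <- htdd$agent == parts[1L] & htdd$level == as.numeric(parts[2L])
      f_col[sel] <- sprintf("%.4g", report$anova[[key]]$f_statistic)
      p_col[sel] <- sprintf("%.4g", report$anova[[key]]$p_value)
    }
    out <- data.frame(series = htdd$series, level = htdd$level,
                      dose = .display_round(htdd$dose),
                      sem = .display_round(htdd$sem),
                      n = htdd$n, extrapolated = htdd$extrapolated,
                      anova_f = f_col, anova_p = p_col,
                      stringsAsFactors = FALSE)
    write.table(out, file.path(dir, "htdd_summary.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  iso <- report$isobole
  if (!is.null(iso)) {
    out <- data.frame(series = iso$series, level = iso$level,
                      additive_dose = .display_round(iso$additive_dose),
                      additive_sem = .display_round(iso$additive_sem),
                      experimental_dose = .display_round(iso$experimental_dose),
                      experimental_sem = .display_round(iso$experimental_sem),
                      t = sprintf("%.3f", iso$t), df = sprintf("%.2f", iso$df),
                      p = sprintf("%.4g", iso$p), verdict = iso$verdict,
                      tendency = iso$tendency, stringsAsFactors = FALSE)
    write.table(out, file.path(dir, "isobole.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @export
print.abr_run_report <- function(x, ...) {
  cat(sprintf("ABR isobolographic run report (otobole %s)\n", x$version))
  cat(sprintf("  %d dose-response line(s), levels: %s\n", length(x$lines),
              paste(x$config$levels, collapse = ", ")))
  if (!is.null(x$htdd)) {
    cat("\nHTDD estimates (mg/kg):\n")
    print(within(x$htdd, {dose <- round(dose, 2); sem <- round(sem, 2)}),
          row.names = FALSE)
  }
  if (!is.null(x$isobole)) {
    cat("\nIsobolographic comparisons:\n")
    iso <- x$isobole
    iso$additive_dose <- round(iso$additive_dose, 2)
    iso$additive_sem <- round(iso$additive_sem, 2)
    iso$experimental_dose <- round(iso$experimental_dose, 2)
    iso$experimental_sem <- round(iso$experimental_sem, 2)
    iso$t <- round(iso$t, 3); iso$df <- round(iso$df, 2)
    iso$p <- signif(iso$p, 4)
    print(iso, row.names = FALSE)
  }
  invisible(x)
}
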