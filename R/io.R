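# CSV dialect for ABR records: UTF-8, comma-separated, header
#   animal_id, arm, dose_<agent>..., pre_db, post_db

#' Write ABR records to CSV
#'
#' @param records An `"abr_records"` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_abr_records <- function(records, path) {
  required <- c("animal_id", "arm", "pre_db", "post_db")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop(sprintf("records lack required column '%s'", missing[1L]),
         call. = FALSE)
  }
  dose_cols <- grep("^dose_", names(records), value = TRUE)
  out <- records[, c("animal_id", "arm", dose_cols, "pre_db", "post_db")]
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate ABR records from CSV
#'
#' Validates the schema (required columns, at least one `dose_<agent>`
#' column) and each row (doses >= 0, thresholds in 0-120 dB SPL, positive
#' baseline); malformed rows are reported with their row numbers.  A file
#' containing only the header yields an empty record set with a warning.
#'
#' @param path CSV file in the dialect written by [write_abr_records()].
#' @return An `"abr_records"` data frame.
#' @export
read_abr_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (needed in c("animal_id", "arm", "pre_db", "post_db")) {
    if (!needed %in% names(df)) {
      stop(sprintf("schema error: missing required column '%s'", needed),
           call. = FALSE)
    }
  }
  dose_cols <- grep("^dose_", names(df), value = TRUE)
  if (length(dose_cols) == 0L) {
    stop("schema error: no 'dose_<agent>' column present", call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning(sprintf("'%s' contains a header but no records", path),
            call. = FALSE)
    class(df) <- c("abr_records", "data.frame")
    return(df)
  }
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      stop(sprintf("invalid record(s) in row(s) %s: %s",
                   paste(idx, collapse = ", "), what), call. = FALSE)
    }
  }
  for (col in c(dose_cols, "pre_db", "post_db")) {
    bad(!is.finite(suppressWarnings(as.numeric(df[[col]]))),
        sprintf("non-numeric '%s'", col))
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in dose_cols) bad(df[[col]] < 0, sprintf("negative '%s'", col))
  bad(df$pre_db <= 0, "pre_db must be > 0 dB SPL")
  bad(df$pre_db > 120 | df$post_db < 0 | df$post_db > 120,
      "thresholds must lie in [0, 120] dB SPL")
  df$animal_id <- as.character(df$animal_id)
  df$arm <- as.character(df$arm)
  class(df) <- c("abr_records", "data.frame")
  df
}
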