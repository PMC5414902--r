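# CSV dialects and validated readers/writers.
#
# All tables are long-format, UTF-8, decimal-point CSV/TSV:
#   tacs:     subject, session, region, side, frame_start_s, frame_end_s,
#             kBq_per_mL
#   blood:    subject, session, time_min, blood_kBq_per_mL,
#             plasma_kBq_per_mL (optional), parent_fraction (empty where
#             unmeasured)
#   sessions: subject, session, dose_MBq, weight_g
# Input functions travel as two-column CSV (time_min, kBq_per_mL) plus a
# JSON sidecar with provenance and conventions.

#' @noRd
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @noRd
require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s table: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")))
}

#' Read and validate the pipeline input tables
#'
#' Readers for the three study tables. Schema violations are reported with
#' the offending column; row-level violations cite the subject/session.
#'
#' @param path File path (CSV, or TSV by extension).
#' @return The validated data frame.
#' @export
read_tac_table <- function(path) {
  df <- read_delim_auto(path)
  require_columns(df, c("subject", "session", "region", "side",
                        "frame_start_s", "frame_end_s", "kBq_per_mL"), "TAC")
  key <- paste(df$subject, df$session, df$region, df$side)
  for (k in unique(key)) {
    sub <- df[key == k, ]
    ord <- order(sub$frame_start_s)
    sub <- sub[ord, ]
    if (any(diff(sub$frame_start_s) <= 0) ||
        any(sub$frame_end_s <= sub$frame_start_s) ||
        any(sub$frame_start_s[-1] < sub$frame_end_s[-nrow(sub)] - 1e-9))
      stop(sprintf("TAC table: non-monotone or overlapping frames for %s / %s",
                   sub$subject[1], sub$session[1]))
    if (any(!is.finite(sub$kBq_per_mL)))
      stop(sprintf("TAC table: non-finite activity for %s / %s",
                   sub$subject[1], sub$session[1]))
  }
  df
}

#' @rdname read_tac_table
#' @export
read_blood_table <- function(path) {
  df <- read_delim_auto(path)
  require_columns(df, c("subject", "session", "time_min", "blood_kBq_per_mL",
                        "parent_fraction"), "blood")
  if (is.null(df$plasma_kBq_per_mL)) df$plasma_kBq_per_mL <- NA_real_
  key <- paste(df$subject, df$session)
  for (k in unique(key)) {
    sub <- df[key == k, ]
    if (any(diff(sub$time_min) <= 0))
      stop(sprintf("blood table: sample times not strictly increasing for %s / %s",
                   sub$subject[1], sub$session[1]))
    pf <- sub$parent_fraction
    if (any(pf < 0 | pf > 1, na.rm = TRUE))
      stop(sprintf("blood table: parent_fraction outside [0, 1] for %s / %s",
                   sub$subject[1], sub$session[1]))
  }
  df
}

#' @rdname read_tac_table
#' @export
read_session_table <- function(path) {
  df <- read_delim_auto(path)
  require_columns(df, c("subject", "session", "dose_MBq", "weight_g"),
                  "session")
  bad <- !is.finite(df$dose_MBq) | df$dose_MBq <= 0 |
    !is.finite(df$weight_g) | df$weight_g <= 0
  if (any(bad))
    stop(sprintf("session table: non-positive dose or weight for %s / %s",
                 df$subject[which(bad)[1]], df$session[which(bad)[1]]))
  df
}

#' @param paths Named list with elements `tacs`, `blood` (optional, may be
#'   `NULL`) and `sessions`.
#' @rdname read_tac_table
#' @export
read_tables <- function(paths) {
  list(
    tacs = read_tac_table(paths$tacs),
    blood = if (!is.null(paths$blood) && file.exists(paths$blood))
      read_blood_table(paths$blood) else NULL,
    sessions = read_session_table(paths$sessions)
  )
}

#' Write or read an input function as CSV plus JSON sidecar
#'
#' @param aif An [input_function()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_input_function()` returns `path` invisibly;
#'   `read_input_function()` returns an [input_function()].
#' @export
write_input_function <- function(aif, path) {
  utils::write.csv(data.frame(time_min = aif$time_min,
                              kBq_per_mL = aif$plasma_kBq_per_mL,
                              blood_kBq_per_mL = aif$blood_kBq_per_mL),
                   path, row.names = FALSE)
  side <- list(provenance = aif$provenance)
  if (!is.null(aif$meta)) side$meta <- unclass(aif$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_input_function
#' @export
read_input_function <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta <- if (!is.null(side$meta))
    session_meta(side$meta$subject, side$meta$session, side$meta$dose_MBq,
                 side$meta$weight_g) else NULL
  input_function(df$time_min, df$kBq_per_mL, df$blood_kBq_per_mL,
                 provenance = side$provenance, meta = meta)
}
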