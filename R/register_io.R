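#' Write a stroke register to a delimited text file
#'
#' One row per patient (CSV, UTF-8, header row). Ward episodes are
#' serialized in a single column in the dialect
#' `"STATE:entry-exit|STATE:entry-exit|..."` with integer days; missing
#' values (death day, 90-day Barthel) are empty fields.
#'
#' @param records Register `data.frame` as produced by [generate_cohort()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_register <- function(records, path) {
  cols <- c("patient_id", "period", "age", "sex", "stroke_type",
            "thrombolysis", "admission_day", "ward_episodes",
            "discharge_destination", "death_day", "censor_day",
            "barthel_admission", "barthel_90d")
  if (nrow(records) > 0) {
    missing <- setdiff(cols, names(records))
    if (length(missing))
      stop("register is missing columns: ", paste(missing, collapse = ", "))
    records <- records[, cols]
  } else {
    records <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  utils::write.csv(records, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# parse one serialized episode string into a 3-column data.frame
.parse_episodes <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(s, "|", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Z_]+):(-?[0-9]+)-(-?[0-9]+)$", parts))
  if (any(lengths(m) != 4)) return(NA)     # malformed
  data.frame(ward_state = vapply(m, `[`, "", 2),
             entry_day = as.integer(vapply(m, `[`, "", 3)),
             exit_day = as.integer(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Parse the ward-episode column of a register
#'
#' @param records A register `data.frame`.
#' @return A list (one element per patient) of data.frames with columns
#'   `ward_state`, `entry_day`, `exit_day`.
#' @export
register_episodes <- function(records) {
  lapply(records$ward_episodes, .parse_episodes)
}

#' Read and validate a stroke register file
#'
#' Reads the CSV dialect written by [write_register()] and validates every
#' row: episodes must be contiguous, non-overlapping, start at day 0 and
#' satisfy `exit_day >= entry_day`; the death day, when present, must equal
#' the last episode's exit day and not exceed the censor day; Barthel scores
#' must lie in \[0, 20\]; thrombolysis is only valid for ischemic stroke.
#' Violations raise an error naming the offending data line.
#'
#' @param path File path to read.
#' @return A validated register `data.frame`.
#' @export
read_register <- function(path) {
  if (!file.exists(path)) stop("register file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = c(patient_id = "character"))
  if (nrow(df) == 0) {
    df$thrombolysis <- logical(0)
    return(df)
  }
  df$thrombolysis <- as.logical(df$thrombolysis)
  for (col in c("admission_day", "death_day", "censor_day",
                "barthel_admission", "barthel_90d"))
    df[[col]] <- as.integer(df[[col]])
  validate_register(df)
  df
}

#' Validate register invariants
#'
#' @param df Register `data.frame`.
#' @param line_offset Added to row indices in error messages (2 accounts for
#'   the header line when the register came from a file).
#' @return `df`, invisibly, if valid; otherwise an error.
#' @export
validate_register <- function(df, line_offset = 1L) {
  for (i in seq_len(nrow(df))) {
    line <- i + line_offset
    ep <- .parse_episodes(df$ward_episodes[i])
    if (is.null(ep) || (length(ep) == 1 && is.na(ep)))
      stop(sprintf("parse error at line %d: malformed ward_episodes '%s'",
                   line, df$ward_episodes[i]), call. = FALSE)
    if (any(ep$exit_day < ep$entry_day))
      stop(sprintf("validation error at line %d: episode exit_day < entry_day", line),
           call. = FALSE)
    if (ep$entry_day[1] != 0L)
      stop(sprintf("validation error at line %d: first episode must start at day 0", line),
           call. = FALSE)
    if (nrow(ep) > 1 && any(ep$entry_day[-1] != ep$exit_day[-nrow(ep)]))
      stop(sprintf("validation error at line %d: episodes not contiguous", line),
           call. = FALSE)
    dd <- df$death_day[i]
    if (!is.na(dd)) {
      if (dd != ep$exit_day[nrow(ep)])
        stop(sprintf("validation error at line %d: death_day != last episode exit", line),
             call. = FALSE)
      if (dd > df$censor_day[i])
        stop(sprintf("validation error at line %d: death_day > censor_day", line),
             call. = FALSE)
    }
    for (col in c("barthel_admission", "barthel_90d")) {
      b <- df[[col]][i]
      if (!is.na(b) && (b < 0 || b > 20))
        stop(sprintf("validation error at line %d: %s out of [0, 20]", line, col),
             call. = FALSE)
    }
    if (isTRUE(df$thrombolysis[i]) && df$stroke_type[i] != "ischemic")
      stop(sprintf("validation error at line %d: thrombolysis for non-ischemic stroke", line),
           call. = FALSE)
  }
  invisible(df)
}
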