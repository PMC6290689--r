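#' Long-format metrics table
#'
#' The cohort's per-(team, case, parameter) values, in the long layout used
#' for all summaries: one row per entry, with team-metadata columns carried
#' alongside. Missing values are representable (`NA`) and are distinct from
#' zero. At most one value may exist per (team, case, parameter) key.
#'
#' @param df data frame with at least columns `team`, `case`, `parameter`,
#'   `value`; any further columns (e.g. `experience`, `viscosity`) are kept
#'   as metadata.
#' @return the validated data frame, classed `metrics_table`.
#' @export
metrics_table <- function(df) {
  req <- c("team", "case", "parameter", "value")
  if (!all(req %in% names(df)))
    stop("metrics table needs columns team, case, parameter, value")
  df$team <- as.character(df$team)
  df$case <- as.character(df$case)
  df$parameter <- as.character(df$parameter)
  df$value <- as.numeric(df$value)
  key <- paste(df$team, df$case, df$parameter, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), req[1:3], drop = FALSE]
    stop(sprintf("duplicate (team, case, parameter) rows, e.g. (%s, %s, %s)",
                 d$team[1L], d$case[1L], d$parameter[1L]))
  }
  class(df) <- c("metrics_table", "data.frame")
  df
}

#' Write a metrics table to CSV
#'
#' Missing entries are written as empty cells and survive a round trip.
#'
#' @param table a [metrics_table()] (or plain data frame with the required
#'   columns).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(table, path) {
  table <- metrics_table(as.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a metrics table from CSV
#'
#' @param path CSV written by [write_metrics_table()] (header row; columns
#'   `team`, `case`, `parameter`, `value` plus metadata columns; empty cells
#'   are missing values).
#' @return a [metrics_table()].
#' @export
read_metrics_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(team = "character",
                                       case = "character",
                                       parameter = "character"),
                        na.strings = "")
  metrics_table(df)
}
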