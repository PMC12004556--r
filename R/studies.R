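#' Validate and order a table of study-level 2x2 data
#'
#' A study record holds one randomized trial's 2x2 table (events and totals
#' in the intervention and control arms) plus an `order_key` (an integer or
#' a year) that fixes the accumulation sequence of the cumulative
#' meta-analysis. Ties in `order_key` are broken by `study_id`
#' (lexicographic), then by input order, so the cumulative z-curve is
#' deterministic.
#'
#' @param data data.frame with columns `study_id`, `order_key`,
#'   `events_int`, `total_int`, `events_ctl`, `total_ctl`, and optionally
#'   `subgroup`.
#' @return The validated data.frame, rows sorted into accumulation order,
#'   with class `"study_records"` prepended.
#' @examples
#' study_records(data.frame(
#'   study_id = c("B", "A"), order_key = c(2001, 1999),
#'   events_int = c(3, 1), total_int = c(50, 40),
#'   events_ctl = c(7, 4), total_ctl = c(50, 40)))
#' @export
study_records <- function(data) {
  required <- c("study_id", "order_key", "events_int", "total_int",
                "events_ctl", "total_ctl")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  data <- as.data.frame(data)
  data$study_id <- as.character(data$study_id)
  for (col in c("order_key", "events_int", "total_int",
                "events_ctl", "total_ctl")) {
    x <- data[[col]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x != round(x))) {
      bad <- which(!is.numeric(x) | !is.finite(x) | x != round(x))
      stop("column '", col, "' must hold integers; offending row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    data[[col]] <- as.integer(round(x))
  }
  check_arm <- function(events, total, arm) {
    bad <- which(total <= 0L | events < 0L | events > total)
    if (length(bad) > 0L) {
      stop("invalid ", arm, " arm counts (need 0 <= events <= total, ",
           "total > 0) on row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  check_arm(data$events_int, data$total_int, "intervention")
  check_arm(data$events_ctl, data$total_ctl, "control")
  data$subgroup <- if (is.null(data$subgroup)) NA_character_ else
    as.character(data$subgroup)
  ord <- order(data$order_key, data$study_id, seq_len(nrow(data)))
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  class(data) <- c("study_records", "data.frame")
  data
}

#' Read study-level 2x2 tables from CSV
#'
#' Expects a header row with columns `study_id`, `order_key`, `events_int`,
#' `total_int`, `events_ctl`, `total_ctl` and optionally `subgroup`.
#' Rows are validated (counts are integers, `0 <= events <= total`,
#' `total > 0`) with errors naming the offending row, and returned sorted
#' by `order_key`.
#'
#' @param path path to a CSV file.
#' @return A `study_records` data.frame.
#' @seealso [write_studies_csv()], [study_records()]
#' @export
read_studies_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  study_records(raw)
}

#' Write study records to CSV
#'
#' Writes the same schema [read_studies_csv()] reads, so generated datasets
#' round-trip losslessly.
#'
#' @param records a `study_records` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_studies_csv <- function(records, path) {
  records <- study_records(records)
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
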