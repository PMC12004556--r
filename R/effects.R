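#' Per-study log odds ratios with within-study variances
#'
#' Converts each 2x2 table to a log odds ratio `y = ln(ad/(bc))` and its
#' within-study variance `v = 1/a + 1/b + 1/c + 1/d`, where
#' `a = events_int`, `b = total_int - events_int`, `c = events_ctl`,
#' `d = total_ctl - events_ctl`.
#'
#' Sparse tables are handled by the continuity rule: with
#' `correction = "add_half"` (default), 0.5 is added to all four cells of
#' any study with at least one zero cell. Studies carrying no information
#' on the odds ratio — zero events in both arms, or all events in both
#' arms — are returned with `included = FALSE`, never dropped and never an
#' error. With `correction = "none"` any study whose uncorrected table
#' yields a non-finite `y` or `v` is likewise flagged `included = FALSE`.
#'
#' @param records a `study_records` data.frame (see [study_records()]), or
#'   a data.frame coercible to one.
#' @param correction continuity rule, `"add_half"` or `"none"`.
#' @param increment cell increment used by `"add_half"` (default 0.5).
#' @return data.frame with one row per study in accumulation order:
#'   `study_id`, `y`, `v`, `n` (total participants both arms),
#'   `events_ctl`, `total_ctl`, `corrected`, `included`.
#' @examples
#' rec <- study_records(data.frame(
#'   study_id = "x", order_key = 1,
#'   events_int = 10, total_int = 100, events_ctl = 20, total_ctl = 100))
#' log_odds_ratio(rec)
#' @export
log_odds_ratio <- function(records, correction = c("add_half", "none"),
                           increment = 0.5) {
  correction <- match.arg(correction)
  records <- study_records(records)
  a <- as.numeric(records$events_int)
  b <- as.numeric(records$total_int - records$events_int)
  c_ <- as.numeric(records$events_ctl)
  d <- as.numeric(records$total_ctl - records$events_ctl)

  double_zero <- (a == 0 & c_ == 0)
  double_full <- (b == 0 & d == 0)
  included <- !(double_zero | double_full)

  has_zero_cell <- (a == 0 | b == 0 | c_ == 0 | d == 0)
  corrected <- rep(FALSE, length(a))
  if (correction == "add_half") {
    fix <- has_zero_cell & included
    a[fix] <- a[fix] + increment
    b[fix] <- b[fix] + increment
    c_[fix] <- c_[fix] + increment
    d[fix] <- d[fix] + increment
    corrected <- fix
  }

  y <- log((a * d) / (b * c_))
  v <- 1 / a + 1 / b + 1 / c_ + 1 / d
  included <- included & is.finite(y) & is.finite(v) & v > 0
  y[!included] <- NA_real_
  v[!included] <- NA_real_

  data.frame(
    study_id = records$study_id,
    y = y,
    v = v,
    n = records$total_int + records$total_ctl,
    events_ctl = records$events_ctl,
    total_ctl = records$total_ctl,
    corrected = corrected,
    included = included,
    stringsAsFactors = FALSE
  )
}

# Included rows of an effects table, with basic checks.
included_effects <- function(effects) {
  if (!all(c("y", "v", "included") %in% names(effects))) {
    stop("effects must have columns y, v, included")
  }
  eff <- effects[effects$included, , drop = FALSE]
  if (nrow(eff) == 0L) stop("no included effect estimates")
  if (any(!is.finite(eff$y)) || any(!is.finite(eff$v)) || any(eff$v <= 0)) {
    stop("included effects must have finite y and v > 0")
  }
  eff
}
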