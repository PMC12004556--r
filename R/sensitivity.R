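#' Quartile coefficient of variation
#'
#' `QCV = (Q3 - Q1) / (Q3 + Q1)`, reported as a percentage: a robust
#' relative-variability summary used to quantify how much a TSA quantity
#' disagrees across tau2 estimators. Quartiles are computed by linear
#' interpolation between order statistics (`rule = "linear"`, the usual
#' scientific-computing default) or by Tukey's inclusive-median hinges
#' (`rule = "tukey"`).
#'
#' All summarized TSA quantities are non-negative magnitudes; negative
#' inputs are an error. When `Q1 = Q3` (including the all-zero case) the
#' QCV is 0 by definition; a zero lower quartile with `Q3 > 0` gives
#' 100%.
#'
#' @param values numeric vector (>= 2 values, all >= 0).
#' @param rule quartile convention.
#' @return QCV in percent.
#' @examples
#' qcv(c(1, 2, 3, 4, 5, 6))  # 35.71
#' qcv(c(0, 0, 0, 1, 2, 3))  # 100
#' @export
qcv <- function(values, rule = c("linear", "tukey")) {
  rule <- match.arg(rule)
  if (length(values) < 2L || any(!is.finite(values))) {
    stop("qcv needs >= 2 finite values")
  }
  if (any(values < 0)) stop("qcv is defined for non-negative values")
  q <- if (rule == "linear") {
    stats::quantile(values, probs = c(0.25, 0.75), names = FALSE, type = 7)
  } else {
    stats::fivenum(values)[c(2L, 4L)]
  }
  if (q[2L] == q[1L]) return(0)
  100 * (q[2L] - q[1L]) / (q[2L] + q[1L])
}

#' Range of a set of values
#'
#' @param values numeric vector (>= 1 value).
#' @return named vector `c(min, max)`.
#' @export
range_summary <- function(values) {
  if (length(values) < 1L || any(!is.finite(values))) {
    stop("range_summary needs >= 1 finite value")
  }
  c(min = min(values), max = max(values))
}

#' Sensitivity of a trial sequential analysis to the tau2 estimator
#'
#' Runs the full TSA ([run_tsa()]) once per between-study variance
#' estimator on the same data and configuration, and summarizes how the
#' key quantities — tau2, diversity, adjustment factor, adjusted RIS,
#' the most extreme monitoring boundary, and the most extreme cumulative
#' z-score — vary across estimators, using ranges and the quartile
#' coefficient of variation. Signed quantities (boundaries, z-scores)
#' are summarized on their magnitudes; signs are carried in the rows.
#'
#' A failure under one estimator is recorded in that estimator's row
#' (column `error`) and does not abort the sweep.
#'
#' @param records a `study_records` data.frame.
#' @param config a [tsa_config()]; its `estimator` field is overridden.
#' @param estimators estimators to sweep (default all six).
#' @return list of class `"sensitivity_report"`: `rows` (one data.frame
#'   row per estimator: `estimator`, `tau2`, `d2`, `af`, `ris_adjusted`,
#'   `min_boundary`, `extreme_z`, `conclusion`, `error`), `summaries`
#'   (per quantity: `min`, `max`, `qcv`), `agreement` (all conclusions
#'   identical), `conclusive_estimators`, and `results` (the underlying
#'   `tsa_result` objects).
#' @export
sweep_estimators <- function(records, config = tsa_config(),
                             estimators = c("DL", "REML", "ML",
                                            "PM", "SJ", "HS")) {
  stopifnot(inherits(config, "tsa_config"), length(estimators) >= 1L)
  results <- vector("list", length(estimators))
  names(results) <- estimators
  rows <- data.frame(
    estimator = estimators, tau2 = NA_real_, d2 = NA_real_, af = NA_real_,
    ris_adjusted = NA_real_, min_boundary = NA_real_, extreme_z = NA_real_,
    conclusion = NA_character_, error = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(estimators)) {
    cfg <- config
    cfg$estimator <- estimators[i]
    res <- tryCatch(run_tsa(records, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      rows$error[i] <- conditionMessage(res)
      next
    }
    results[[i]] <- res
    rows$tau2[i] <- res$tau2$value
    rows$d2[i] <- res$d2
    rows$af[i] <- res$af
    rows$ris_adjusted[i] <- res$ris$ris_adjusted
    rows$min_boundary[i] <- res$min_boundary
    rows$extreme_z[i] <- res$extreme_z
    rows$conclusion[i] <- res$conclusion
  }
  ok <- is.na(rows$error)
  quantities <- c("tau2", "d2", "af", "ris_adjusted",
                  "min_boundary", "extreme_z")
  summaries <- data.frame(quantity = quantities, min = NA_real_,
                          max = NA_real_, qcv = NA_real_,
                          stringsAsFactors = FALSE)
  for (j in seq_along(quantities)) {
    vals <- rows[[quantities[j]]][ok]
    if (length(vals) == 0L) next
    r <- range_summary(vals)
    summaries$min[j] <- r[["min"]]
    summaries$max[j] <- r[["max"]]
    if (length(vals) >= 2L) {
      summaries$qcv[j] <- qcv(abs(vals), rule = config$quartile_rule)
    }
  }
  concl <- rows$conclusion[ok]
  structure(list(
    rows = rows, summaries = summaries,
    agreement = length(unique(concl)) <= 1L,
    conclusive_estimators =
      rows$estimator[ok & rows$conclusion == "conclusive_crossed"],
    results = results, config = config
  ), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, digits = 3, ...) {
  cat("TSA sensitivity to the between-study variance estimator\n\n")
  rows <- x$rows
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], round, digits = digits)
  print(rows, row.names = FALSE)
  cat("\nVariability across estimators:\n")
  print(transform(x$summaries,
                  min = signif(min, 4), max = signif(max, 4),
                  qcv = round(qcv, 1)),
        row.names = FALSE)
  cat(sprintf("\nconclusions agree: %s", x$agreement))
  if (length(x$conclusive_estimators) > 0L) {
    cat(sprintf("; conclusive under: %s",
                paste(x$conclusive_estimators, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}
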