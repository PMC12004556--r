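#' Bundle a sensitivity sweep into a serializable report
#'
#' Collects everything needed to reproduce and inspect a run: the
#' per-estimator TSA traces (look tables), the sensitivity rows and
#' summaries, an echo of the configuration, the package version, and an
#' MD5 checksum of the input file when one was used.
#'
#' @param sweep a `sensitivity_report` from [sweep_estimators()].
#' @param input_path optional path of the input CSV (checksummed).
#' @return list of class `"report_bundle"`.
#' @export
make_report_bundle <- function(sweep, input_path = NULL) {
  stopifnot(inherits(sweep, "sensitivity_report"))
  checksum <- if (!is.null(input_path) && file.exists(input_path)) {
    unname(tools::md5sum(input_path))
  } else {
    NA_character_
  }
  traces <- lapply(sweep$results, function(res) {
    if (is.null(res)) return(NULL)
    list(estimator = res$estimator,
         tau2 = res$tau2$value,
         tau2_converged = res$tau2$converged,
         d2 = res$d2, af = res$af,
         ris_unadjusted = res$ris$ris_unadjusted,
         ris_adjusted = res$ris$ris_adjusted,
         ris_mode = res$ris$mode,
         mu = res$ris$mu,
         p_control = res$ris$p_control,
         conclusion = res$conclusion,
         min_boundary = res$min_boundary,
         extreme_z = res$extreme_z,
         looks = res$looks)
  })
  cfg <- sweep$config
  structure(list(
    version = as.character(utils::packageVersion("tsasens")),
    input_checksum = checksum,
    config = cfg[setdiff(names(cfg), NULL)],
    rows = sweep$rows,
    summaries = sweep$summaries,
    agreement = sweep$agreement,
    conclusive_estimators = sweep$conclusive_estimators,
    traces = traces
  ), class = "report_bundle")
}

#' Write a report bundle to disk
#'
#' `format = "json"` serializes the whole bundle (full precision,
#' deterministic field order; round-trips through [read_report()]).
#' `format = "csv_table"` writes only the per-estimator sensitivity rows
#' as a flat table.
#'
#' @param bundle a [make_report_bundle()] result (or a
#'   `sensitivity_report`, which is bundled first).
#' @param path output file path.
#' @param format `"json"` or `"csv_table"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(bundle, path, format = c("json", "csv_table")) {
  format <- match.arg(format)
  if (inherits(bundle, "sensitivity_report")) {
    bundle <- make_report_bundle(bundle)
  }
  stopifnot(inherits(bundle, "report_bundle"))
  if (format == "csv_table") {
    utils::write.csv(bundle$rows, path, row.names = FALSE)
  } else {
    jsonlite::write_json(unclass(bundle), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE,
                         dataframe = "rows")
  }
  invisible(path)
}

#' Read back a JSON report bundle
#'
#' @param path path written by [write_report()] with `format = "json"`.
#' @return list of class `"report_bundle"`.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$rows <- as.data.frame(raw$rows, stringsAsFactors = FALSE)
  raw$summaries <- as.data.frame(raw$summaries, stringsAsFactors = FALSE)
  structure(raw, class = "report_bundle")
}

#' Plot a trial sequential analysis
#'
#' The canonical TSA picture: the cumulative z-curve over accumulated
#' participants, the symmetric alpha-spending monitoring boundaries, the
#' conventional two-sided 1.96 significance lines, and a vertical line
#' at the adjusted required information size (when it falls inside the
#' plotted range). Given a `sensitivity_report`, draws one panel per
#' estimator.
#'
#' @param result a `tsa_result` or a `sensitivity_report`.
#' @param path optional file path; when supplied the plot is saved there
#'   (format from the extension, e.g. `.png`, `.pdf`).
#' @param width,height device size in inches for saving.
#' @return the ggplot object, invisibly.
#' @export
plot_tsa <- function(result, path = NULL, width = 9, height = 6) {
  if (inherits(result, "tsa_result")) {
    looks <- result$looks
    looks$estimator <- result$estimator
    ris <- result$ris$ris_adjusted
    ris_df <- data.frame(estimator = result$estimator, ris = ris)
  } else if (inherits(result, "sensitivity_report")) {
    keep <- !vapply(result$results, is.null, logical(1))
    looks <- do.call(rbind, lapply(result$results[keep], function(r) {
      lk <- r$looks
      lk$estimator <- r$estimator
      lk
    }))
    ris_df <- data.frame(
      estimator = vapply(result$results[keep], `[[`, "", "estimator"),
      ris = vapply(result$results[keep],
                   function(r) r$ris$ris_adjusted, 0))
  } else {
    stop("result must be a tsa_result or sensitivity_report")
  }
  if (nrow(looks) == 0L) stop("nothing to plot: no looks")
  bound <- rbind(
    transform(looks, side = "upper", b = boundary_z),
    transform(looks, side = "lower", b = -boundary_z)
  )
  p <- ggplot2::ggplot(looks, ggplot2::aes(x = cum_n, y = z)) +
    ggplot2::geom_hline(yintercept = c(-1.959964, 1.959964),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::geom_line(data = bound,
                       ggplot2::aes(y = b, group = side),
                       colour = "firebrick", linetype = "dashed") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue", size = 1.2) +
    ggplot2::geom_vline(data = ris_df,
                        ggplot2::aes(xintercept = ris),
                        colour = "grey30", linetype = "longdash") +
    ggplot2::facet_wrap(~estimator) +
    ggplot2::labs(x = "Cumulative participants",
                  y = "Cumulative z-score",
                  title = "Trial sequential analysis",
                  subtitle = paste("alpha-spending boundaries (dashed),",
                                   "conventional 1.96 (dotted),",
                                   "adjusted RIS (vertical)")) +
    ggplot2::theme_bw()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height)
  }
  invisible(p)
}
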