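#' Configuration for a trial sequential analysis
#'
#' Collects the design quantities of a TSA: the overall two-sided type-I
#' error `alpha`, the type-II error `beta`, and the anticipated
#' intervention effect, given either as a relative risk reduction `rrr`
#' in (0, 1) (converted to the log-odds-ratio scale via
#' [implied_log_or()] at the control event rate) or directly as
#' `expected_log_or`. The control event rate is either the pooled
#' observed control-arm proportion (`control_rate = "observed_pooled"`)
#' or a user value in (0, 1).
#'
#' `ris_mode` selects the scale of the required information size:
#' `"proportion"` (default) gives a participant count from the classical
#' two-proportion sample-size formula, multiplied by the diversity-based
#' adjustment factor; `"eq1_literal"` gives
#' `4 (z_{1-alpha/2} + z_{1-beta})^2 * nu_random / mu^2` in statistical
#' information units.
#'
#' @param alpha two-sided overall type-I error (default 0.05).
#' @param beta type-II error (default 0.20, i.e. 80% power).
#' @param rrr assumed relative risk reduction in (0, 1) (default 0.20).
#' @param expected_log_or optional expected effect on the log-OR scale;
#'   overrides `rrr` when supplied (its magnitude is used).
#' @param control_rate `"observed_pooled"` or a number in (0, 1).
#' @param ris_mode `"proportion"` or `"eq1_literal"`.
#' @param estimator default tau2 estimator for [run_tsa()].
#' @param correction continuity rule passed to [log_odds_ratio()].
#' @param reestimate_tau2 re-estimate tau2 at every look of the
#'   cumulative z-curve (default) or hold the final-data estimate fixed.
#' @param cap,grid boundary options passed to [compute_boundaries()].
#' @param heterogeneity_threshold p-value threshold for flagging
#'   heterogeneity (default 0.10).
#' @param quartile_rule quartile convention for [qcv()] summaries.
#' @return list of class `"tsa_config"`.
#' @export
tsa_config <- function(alpha = 0.05, beta = 0.20, rrr = 0.20,
                       expected_log_or = NULL,
                       control_rate = "observed_pooled",
                       ris_mode = c("proportion", "eq1_literal"),
                       estimator = "DL",
                       correction = c("add_half", "none"),
                       reestimate_tau2 = TRUE,
                       cap = 8, grid = 512L,
                       heterogeneity_threshold = 0.10,
                       quartile_rule = c("linear", "tukey")) {
  ris_mode <- match.arg(ris_mode)
  correction <- match.arg(correction)
  quartile_rule <- match.arg(quartile_rule)
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1)
  if (is.null(expected_log_or)) {
    stopifnot(is.numeric(rrr), length(rrr) == 1L, rrr > 0, rrr < 1)
  } else {
    stopifnot(is.numeric(expected_log_or), length(expected_log_or) == 1L,
              is.finite(expected_log_or), expected_log_or != 0)
  }
  if (is.numeric(control_rate)) {
    stopifnot(length(control_rate) == 1L, control_rate > 0, control_rate < 1)
  } else if (!identical(control_rate, "observed_pooled")) {
    stop("control_rate must be \"observed_pooled\" or a number in (0, 1)")
  }
  structure(list(alpha = alpha, beta = beta, rrr = rrr,
                 expected_log_or = expected_log_or,
                 control_rate = control_rate, ris_mode = ris_mode,
                 estimator = estimator, correction = correction,
                 reestimate_tau2 = reestimate_tau2,
                 cap = cap, grid = as.integer(grid),
                 heterogeneity_threshold = heterogeneity_threshold,
                 quartile_rule = quartile_rule),
            class = "tsa_config")
}

#' Diversity of a random-effects meta-analysis
#'
#' `D2 = (nu_random - nu_fixed) / nu_random`: the relative increase in
#' the pooled-effect variance when moving from the common-effect to the
#' random-effects model. It is 0 when the estimated between-study
#' variance is 0 and approaches 1 as heterogeneity dominates.
#'
#' @param variance_fixed pooled variance under the common-effect model.
#' @param variance_random pooled variance under the random-effects model
#'   (must be >= `variance_fixed`).
#' @return D2 in [0, 1).
#' @examples
#' diversity(0.04, 0.07)  # 0.42857
#' @export
diversity <- function(variance_fixed, variance_random) {
  stopifnot(is.numeric(variance_fixed), is.numeric(variance_random),
            variance_fixed > 0)
  if (variance_random < variance_fixed * (1 - 1e-12)) {
    stop("variance_random must be >= variance_fixed")
  }
  d2 <- (variance_random - variance_fixed) / variance_random
  min(max(d2, 0), 1 - .Machine$double.eps)
}

#' Diversity-based adjustment factor
#'
#' `AF = 1 / (1 - D2)`; multiplies the unadjusted required information
#' size to compensate for between-study heterogeneity.
#'
#' @param d2 diversity in [0, 1).
#' @return AF >= 1.
#' @examples
#' adjustment_factor(0.43)  # 1.754386
#' @export
adjustment_factor <- function(d2) {
  if (!is.numeric(d2) || length(d2) != 1L || is.na(d2) || d2 < 0 || d2 >= 1) {
    stop("d2 must lie in [0, 1)")
  }
  1 / (1 - d2)
}

#' Expected log odds ratio implied by a relative risk reduction
#'
#' Converts an anticipated relative risk reduction at control event rate
#' `p_control` to the magnitude of the corresponding log odds ratio:
#' `p_int = p_control * (1 - rrr)` and
#' `mu = |ln( (p_int/(1-p_int)) / (p_control/(1-p_control)) )|`.
#'
#' @param p_control control-arm event proportion in (0, 1).
#' @param rrr relative risk reduction in (0, 1).
#' @return `mu` > 0 (log-OR scale).
#' @examples
#' implied_log_or(0.1, 0.2)  # 0.24512
#' @export
implied_log_or <- function(p_control, rrr) {
  stopifnot(is.numeric(p_control), length(p_control) == 1L,
            p_control > 0, p_control < 1,
            is.numeric(rrr), length(rrr) == 1L, rrr > 0, rrr < 1)
  p_int <- p_control * (1 - rrr)
  abs(log((p_int / (1 - p_int)) / (p_control / (1 - p_control))))
}

#' Required information size
#'
#' The information a meta-analysis needs to detect the anticipated
#' effect with power `1 - beta` at two-sided level `alpha`, and its
#' diversity-adjusted version `ris_adjusted = ris_unadjusted * AF`.
#'
#' Two scales are supported. `"proportion"` (default) is the
#' participant scale: `4 (z_{1-alpha/2} + z_{1-beta})^2 *
#' pbar (1 - pbar) / (p_control - p_int)^2` with
#' `pbar = (p_control + p_int)/2`, rounded up to whole participants.
#' `"eq1_literal"` is the information scale:
#' `4 (z_{1-alpha/2} + z_{1-beta})^2 * nu_random / mu^2` (unrounded),
#' where `nu_random` is the random-effects pooled variance.
#'
#' @param config a [tsa_config()].
#' @param pooled_random a `pooled_result` from [pool_random()]; required
#'   for `ris_mode = "eq1_literal"`.
#' @param af adjustment factor from [adjustment_factor()] (default 1).
#' @param p_control control event rate; required for the proportion mode
#'   and for deriving `mu` from `rrr`.
#' @return list with `ris_unadjusted`, `ris_adjusted`, their unrounded
#'   values (`unadjusted_raw`, `adjusted_raw`), `mu`, `p_control`,
#'   `p_int`, `af`, `mode`.
#' @export
required_information_size <- function(config, pooled_random = NULL, af = 1,
                                      p_control = NULL) {
  stopifnot(inherits(config, "tsa_config"), af >= 1)
  zsum2 <- (stats::qnorm(1 - config$alpha / 2) +
            stats::qnorm(1 - config$beta))^2
  p_int <- NA_real_
  if (!is.null(p_control)) {
    stopifnot(p_control > 0, p_control < 1)
    p_int <- p_control * (1 - config$rrr)
  }
  mu <- if (!is.null(config$expected_log_or)) {
    abs(config$expected_log_or)
  } else {
    if (is.null(p_control)) {
      stop("p_control is needed to derive the expected effect from rrr")
    }
    implied_log_or(p_control, config$rrr)
  }
  if (mu == 0) stop("expected effect must be non-zero")

  if (config$ris_mode == "eq1_literal") {
    if (is.null(pooled_random)) {
      stop("eq1_literal mode needs the random-effects pooled result")
    }
    raw <- 4 * zsum2 * pooled_random$variance / mu^2
    adj <- raw * af
    list(ris_unadjusted = raw, ris_adjusted = adj,
         unadjusted_raw = raw, adjusted_raw = adj,
         mu = mu, p_control = p_control, p_int = p_int, af = af,
         mode = "eq1_literal")
  } else {
    if (is.null(p_control)) stop("proportion mode needs p_control")
    pbar <- (p_control + p_int) / 2
    raw <- 4 * zsum2 * pbar * (1 - pbar) / (p_control - p_int)^2
    adj <- raw * af
    list(ris_unadjusted = ceiling(raw), ris_adjusted = ceiling(adj),
         unadjusted_raw = raw, adjusted_raw = adj,
         mu = mu, p_control = p_control, p_int = p_int, af = af,
         mode = "proportion")
  }
}

#' Cumulative z-curve of a meta-analysis
#'
#' Re-runs the random-effects meta-analysis on every prefix of the
#' accumulation order: after each added study the between-study variance
#' is re-estimated on the data so far (single-study prefixes use
#' `tau2 = 0`), the prefix is pooled with [pool_random()], and the
#' pooled z-score and cumulative participant count are recorded.
#' Excluded (double-zero) studies contribute neither information nor
#' participants.
#'
#' @param records a `study_records` data.frame.
#' @param estimator tau2 estimator label for [estimate_tau2()].
#' @param correction continuity rule for [log_odds_ratio()].
#' @param tau2_fixed optional fixed tau2 used at every look instead of
#'   re-estimation (sensitivity mode).
#' @return data.frame with one row per included study, in order:
#'   `look`, `study_id`, `k`, `cum_n`, `tau2`, `z`.
#' @export
cumulative_z_curve <- function(records, estimator = "DL",
                               correction = "add_half", tau2_fixed = NULL) {
  effects <- log_odds_ratio(records, correction = correction)
  eff <- effects[effects$included, , drop = FALSE]
  if (nrow(eff) == 0L) stop("no included studies")
  J <- nrow(eff)
  out <- data.frame(look = seq_len(J), study_id = eff$study_id,
                    k = seq_len(J), cum_n = cumsum(eff$n),
                    tau2 = NA_real_, z = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(J)) {
    prefix <- eff[seq_len(j), , drop = FALSE]
    tau2 <- if (!is.null(tau2_fixed)) {
      tau2_fixed
    } else if (j == 1L) {
      0
    } else {
      estimate_tau2(prefix, method = estimator)$value
    }
    pooled <- pool_random(prefix, tau2, estimator = estimator)
    out$tau2[j] <- tau2
    out$z[j] <- pooled$z_score
  }
  out
}

#' Run a full trial sequential analysis
#'
#' Assembles, for one tau2 estimator, the whole TSA: final-data pooling
#' (common- and random-effects), diversity `D2` and adjustment factor
#' `AF`, the diversity-adjusted required information size, the
#' cumulative z-curve with one look per accumulated study, alpha-spending
#' boundaries at the realized information fractions, and the verdict:
#'
#' * `conclusive_crossed` — the cumulative z-curve reached or crossed the
#'   monitoring boundary at some look;
#' * `ris_reached_not_crossed` — the accumulated participants reached the
#'   adjusted RIS without a crossing;
#' * `inconclusive` — neither.
#'
#' @param records a `study_records` data.frame (k >= 2 included studies).
#' @param config a [tsa_config()].
#' @return list of class `"tsa_result"`: `estimator`, `tau2`
#'   (a `tau2_estimate`), `pooled_fixed`, `pooled_random`, `d2`, `af`,
#'   `ris`, `looks` (data.frame with `look`, `study_id`, `k`, `cum_n`,
#'   `tau2`, `z`, `frac_raw`, `frac`, `boundary_z`, `capped`, `crossed`),
#'   `conclusion`, `min_boundary`, `extreme_z`, `config`.
#' @export
run_tsa <- function(records, config = tsa_config()) {
  stopifnot(inherits(config, "tsa_config"))
  records <- study_records(records)
  effects <- log_odds_ratio(records, correction = config$correction)
  eff <- effects[effects$included, , drop = FALSE]
  if (nrow(eff) < 2L) stop("TSA needs at least 2 included studies")

  tau2 <- estimate_tau2(eff, method = config$estimator)
  fixed <- pool_fixed(eff)
  random <- pool_random(eff, tau2$value, estimator = config$estimator)
  d2 <- diversity(fixed$variance, random$variance)
  af <- adjustment_factor(d2)

  p_control <- if (is.numeric(config$control_rate)) {
    config$control_rate
  } else {
    sum(eff$events_ctl) / sum(eff$total_ctl)
  }
  if (p_control <= 0 || p_control >= 1) {
    stop("observed pooled control rate is degenerate; supply control_rate")
  }
  ris <- required_information_size(config, pooled_random = random, af = af,
                                   p_control = p_control)

  looks <- cumulative_z_curve(
    records, estimator = config$estimator, correction = config$correction,
    tau2_fixed = if (config$reestimate_tau2) NULL else tau2$value)

  looks$frac_raw <- looks$cum_n / ris$ris_adjusted
  schedule <- look_schedule(looks$frac_raw)
  bounds <- compute_boundaries(schedule, alpha = config$alpha,
                               grid = config$grid, cap = config$cap)
  # map computed looks back onto all looks (post-RIS looks reuse the
  # final boundary)
  idx <- cumsum(schedule$kept)
  looks$frac <- bounds$t[idx]
  looks$boundary_z <- bounds$boundary_z[idx]
  looks$capped <- bounds$capped[idx]
  looks$crossed <- abs(looks$z) >= looks$boundary_z

  conclusion <- if (any(looks$crossed)) {
    "conclusive_crossed"
  } else if (looks$cum_n[nrow(looks)] >= ris$ris_adjusted) {
    "ris_reached_not_crossed"
  } else {
    "inconclusive"
  }
  effect_sign <- if (random$theta_hat < 0) -1 else 1
  # most extreme boundary on the effect's side, ignoring looks where the
  # spend underflowed and the value is just the numerical cap
  real_b <- looks$boundary_z[!looks$capped]
  min_boundary <- effect_sign *
    (if (length(real_b) > 0L) max(real_b) else max(looks$boundary_z))
  extreme_z <- looks$z[which.max(abs(looks$z))]

  structure(list(estimator = config$estimator, tau2 = tau2,
                 pooled_fixed = fixed, pooled_random = random,
                 d2 = d2, af = af, ris = ris, looks = looks,
                 conclusion = conclusion, min_boundary = min_boundary,
                 extreme_z = extreme_z, config = config),
            class = "tsa_result")
}

#' @export
print.tsa_result <- function(x, ...) {
  cat(sprintf("Trial sequential analysis (tau2 estimator: %s)\n", x$estimator))
  cat(sprintf("  tau2 = %.4f, D2 = %.2f, AF = %.2f\n",
              x$tau2$value, x$d2, x$af))
  cat(sprintf("  RIS: %s unadjusted, %s adjusted (%s scale)\n",
              format(x$ris$ris_unadjusted, big.mark = ","),
              format(x$ris$ris_adjusted, big.mark = ","), x$ris$mode))
  cat(sprintf("  looks: %d, accumulated N = %s (information fraction %.2f)\n",
              nrow(x$looks), format(max(x$looks$cum_n), big.mark = ","),
              max(x$looks$frac_raw)))
  cat(sprintf("  pooled log OR = %.4f (z = %.3f), min boundary = %.3f\n",
              x$pooled_random$theta_hat, x$pooled_random$z_score,
              x$min_boundary))
  cat(sprintf("  conclusion: %s\n", x$conclusion))
  invisible(x)
}
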