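#' Specification of a synthetic binomial meta-analysis
#'
#' Describes the generative model the estimators and the TSA both
#' assume: `k` trials whose true log odds ratios are drawn from
#' `N(theta, tau2)`, control event rates fixed or drawn uniformly from a
#' range, per-arm sizes drawn uniformly from `n_range`, and per-arm
#' event counts binomial. The generation order is the accumulation
#' order.
#'
#' @param k number of trials (>= 2).
#' @param theta true pooled log odds ratio.
#' @param tau2 true between-study variance (>= 0).
#' @param p_control control event rate: a single value or a range
#'   `c(lo, hi)` sampled uniformly per trial.
#' @param n_range per-arm size: a single value or an integer range
#'   `c(lo, hi)` sampled uniformly per trial per arm; all sizes >= 2.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(k, theta = 0, tau2 = 0, p_control = 0.1,
                            n_range = c(50L, 200L), seed = 1L) {
  stopifnot(k >= 2, tau2 >= 0,
            all(p_control > 0), all(p_control < 1),
            length(p_control) %in% 1:2, length(n_range) %in% 1:2,
            all(n_range >= 2))
  if (length(p_control) == 2L) stopifnot(p_control[1L] <= p_control[2L])
  if (length(n_range) == 2L) stopifnot(n_range[1L] <= n_range[2L])
  structure(list(k = as.integer(k), theta = theta, tau2 = tau2,
                 p_control = p_control, n_range = as.integer(n_range),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# One draw from the generative model; does NOT touch the seed, so
# replicated simulations can stream from a single seeded generator.
generate_one <- function(spec) {
  k <- spec$k
  theta_i <- stats::rnorm(k, mean = spec$theta, sd = sqrt(spec$tau2))
  p_c <- if (length(spec$p_control) == 2L) {
    stats::runif(k, spec$p_control[1L], spec$p_control[2L])
  } else {
    rep(spec$p_control, k)
  }
  odds_i <- exp(theta_i) * p_c / (1 - p_c)
  p_i <- odds_i / (1 + odds_i)
  draw_n <- function() {
    if (length(spec$n_range) == 2L) {
      sample(spec$n_range[1L]:spec$n_range[2L], k, replace = TRUE)
    } else {
      rep(spec$n_range, k)
    }
  }
  n_int <- draw_n()
  n_ctl <- draw_n()
  data.frame(
    study_id = sprintf("S%03d", seq_len(k)),
    order_key = seq_len(k),
    events_int = stats::rbinom(k, n_int, p_i),
    total_int = n_int,
    events_ctl = stats::rbinom(k, n_ctl, p_c),
    total_ctl = n_ctl,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic meta-analysis dataset
#'
#' Draws one dataset from [simulation_spec()]'s random-effects binomial
#' model. The result is a valid `study_records` table (writable with
#' [write_studies_csv()]) whose accumulation order is the generation
#' order. Deterministic given the spec's seed.
#'
#' @param spec a [simulation_spec()].
#' @return A `study_records` data.frame with `k` rows.
#' @examples
#' head(generate_meta_dataset(simulation_spec(k = 5, theta = -0.5, seed = 7)))
#' @export
generate_meta_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  study_records(generate_one(spec))
}

#' Preset scenarios mirroring small and large meta-analyses
#'
#' Four named [simulation_spec()]s spanning the study-size and
#' heterogeneity patterns the sensitivity analysis targets: a small
#' meta-analysis with negligible heterogeneity (k = 7), a small one with
#' marked heterogeneity (k = 9), a large one with negligible
#' heterogeneity (k = 48), and a large heterogeneous one (k = 62).
#'
#' @param seed base seed; each preset offsets it deterministically.
#' @return named list of `simulation_spec` objects.
#' @export
preset_specs <- function(seed = 20240401L) {
  list(
    small_homogeneous = simulation_spec(
      k = 7, theta = -0.45, tau2 = 0, p_control = c(0.08, 0.20),
      n_range = c(40L, 300L), seed = seed + 1L),
    small_heterogeneous = simulation_spec(
      k = 9, theta = -0.70, tau2 = 0.15, p_control = c(0.05, 0.25),
      n_range = c(30L, 250L), seed = seed + 2L),
    large_homogeneous = simulation_spec(
      k = 48, theta = -0.40, tau2 = 0, p_control = c(0.03, 0.15),
      n_range = c(30L, 400L), seed = seed + 3L),
    large_heterogeneous = simulation_spec(
      k = 62, theta = -0.50, tau2 = 0.10, p_control = c(0.03, 0.20),
      n_range = c(30L, 400L), seed = seed + 4L)
  )
}

#' Monte-Carlo error rates of sequential versus naive monitoring
#'
#' Simulates replicate meta-analyses from `spec` and reports the
#' proportion whose cumulative z-curve crosses, at any look, either
#' (a) the alpha-spending monitoring boundaries (`mode =
#' "tsa_boundaries"`) or (b) a fixed two-sided 1.959964 threshold
#' applied at every look (`mode = "naive_repeated"`). Under a null spec
#' with looks spanning the full required information size, (a) is
#' calibrated near `alpha` while (b) inflates well above it — the
#' multiplicity problem sequential monitoring exists to fix. Under an
#' effect spec matching the design effect, (a) approaches `1 - beta`
#' when the RIS is reached.
#'
#' The RIS anchoring uses the design values: `p_control` must be a
#' fixed value in `spec`, and the expected effect comes from `config`
#' (its `rrr` at that control rate, or `expected_log_or`). When the
#' look schedule is the same for every replicate (fixed arm sizes) the
#' boundaries are computed once and reused.
#'
#' @param spec a [simulation_spec()] with fixed `p_control`.
#' @param config a [tsa_config()].
#' @param n_replicates number of replicate meta-analyses (>= 100).
#' @param mode `"tsa_boundaries"` or `"naive_repeated"`.
#' @param tau2_fixed optional between-study variance held fixed when
#'   computing every replicate's z-curve. Setting it to the spec's true
#'   `tau2` gives the oracle-variance calibration experiment in which
#'   the cumulative z-statistic satisfies the Brownian assumptions the
#'   boundaries are derived under; the default (`NULL`) re-estimates
#'   tau2 at every look with `config$estimator`, which is the practical
#'   procedure and is conservative under the null because estimation
#'   noise inflates the pooled variance.
#' @param seed seed for the replicate stream (default `spec$seed`).
#' @return list: `proportion` of crossing replicates, `crossed`
#'   (logical per replicate), `n_replicates`, `mode`, `ris`
#'   (participant-scale, unadjusted), and `boundaries` (when fixed
#'   across replicates).
#' @export
simulate_error_rates <- function(spec, config = tsa_config(),
                                 n_replicates = 1000L,
                                 mode = c("tsa_boundaries", "naive_repeated"),
                                 tau2_fixed = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "simulation_spec"),
            inherits(config, "tsa_config"), n_replicates >= 100L)
  if (length(spec$p_control) != 1L) {
    stop("error-rate simulation needs a fixed p_control in the spec")
  }
  ris <- required_information_size(config, af = 1,
                                   p_control = spec$p_control)
  ris_n <- ris$ris_unadjusted

  fixed_arms <- length(spec$n_range) == 1L
  bounds <- NULL
  if (fixed_arms && mode == "tsa_boundaries") {
    cum_n <- cumsum(rep(2L * spec$n_range, spec$k))
    bounds <- compute_boundaries(look_schedule(cum_n / ris_n),
                                 alpha = config$alpha,
                                 grid = config$grid, cap = config$cap)
  }
  zcrit <- stats::qnorm(1 - config$alpha / 2)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(if (is.null(seed)) spec$seed else seed)

  crossed <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    records <- study_records(generate_one(spec))
    curve <- cumulative_z_curve(records, estimator = config$estimator,
                                correction = config$correction,
                                tau2_fixed = tau2_fixed)
    if (mode == "naive_repeated") {
      crossed[r] <- any(abs(curve$z) >= zcrit)
    } else {
      # the precomputed schedule assumes all k studies informative; fall
      # back to a per-replicate computation if any study was excluded
      b <- if (!is.null(bounds) && nrow(curve) == spec$k) bounds else NULL
      if (is.null(b)) {
        b <- compute_boundaries(look_schedule(curve$cum_n / ris_n),
                                alpha = config$alpha,
                                grid = config$grid, cap = config$cap)
      }
      idx <- cumsum(attr(b, "kept"))
      crossed[r] <- any(abs(curve$z) >= b$boundary_z[idx])
    }
  }
  list(proportion = mean(crossed), crossed = crossed,
       n_replicates = n_replicates, mode = mode, ris = ris_n,
       boundaries = bounds)
}
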