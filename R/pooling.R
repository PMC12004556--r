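#' Cochran's Q test for heterogeneity
#'
#' `Q = sum(w_i (y_i - theta_fixed)^2)` with inverse-variance weights
#' `w_i = 1/v_i`, referred to a chi-square distribution on `k - 1` degrees
#' of freedom. Following common meta-analytic practice the default
#' significance threshold is 0.10 rather than 0.05, because the test has
#' low power with few or small studies.
#'
#' @param effects effects table from [log_odds_ratio()] (or any data.frame
#'   with columns `y`, `v`, `included`).
#' @param threshold significance threshold for the heterogeneity flag
#'   (default 0.10).
#' @return list with `Q`, `df`, `p_value`, `significant`.
#' @export
cochran_q <- function(effects, threshold = 0.10) {
  eff <- included_effects(effects)
  k <- nrow(eff)
  if (k < 2L) stop("Cochran's Q needs at least 2 included studies")
  w <- 1 / eff$v
  theta <- sum(w * eff$y) / sum(w)
  Q <- sum(w * (eff$y - theta)^2)
  df <- k - 1L
  p <- stats::pchisq(Q, df = df, lower.tail = FALSE)
  list(Q = Q, df = df, p_value = p, significant = p < threshold)
}

pooled_result <- function(model, estimator, theta_hat, variance, k,
                          Q = NA_real_, q_df = NA_integer_,
                          q_pvalue = NA_real_, tau2_hat = 0) {
  se <- sqrt(variance)
  zq <- stats::qnorm(0.975)
  out <- list(
    model = model, estimator = estimator,
    theta_hat = theta_hat, variance = variance, se = se,
    z_score = theta_hat / se,
    ci_low = theta_hat - zq * se, ci_high = theta_hat + zq * se,
    k = k, Q = Q, q_df = q_df, q_pvalue = q_pvalue,
    tau2_hat = tau2_hat
  )
  class(out) <- "pooled_result"
  out
}

#' Common-effect (fixed-effect) inverse-variance pooling
#'
#' Weights `w_i = 1/v_i`; pooled effect `sum(w y)/sum(w)` with variance
#' `1/sum(w)`. Heterogeneity fields (`Q`, `q_df`, `q_pvalue`) are filled
#' from [cochran_q()] when at least two studies are included.
#'
#' @inheritParams cochran_q
#' @return A `pooled_result` list: `model`, `estimator`, `theta_hat`,
#'   `variance`, `se`, `z_score`, `ci_low`, `ci_high`, `k`, `Q`, `q_df`,
#'   `q_pvalue`, `tau2_hat`.
#' @export
pool_fixed <- function(effects) {
  eff <- included_effects(effects)
  w <- 1 / eff$v
  theta <- sum(w * eff$y) / sum(w)
  variance <- 1 / sum(w)
  k <- nrow(eff)
  q <- if (k >= 2L) cochran_q(effects) else list(Q = NA_real_, df = NA_integer_,
                                                 p_value = NA_real_)
  pooled_result("common", "none", theta, variance, k,
                Q = q$Q, q_df = q$df, q_pvalue = q$p_value, tau2_hat = 0)
}

#' Random-effects inverse-variance pooling at a given tau-squared
#'
#' Weights `W_i = 1/(v_i + tau2)`; the pooled variance is
#' `1/sum(W_i)`, which can only grow as `tau2` grows, so the
#' random-effects variance is never below the common-effect variance on
#' the same data. `pool_random(effects, 0)` reproduces [pool_fixed()]
#' apart from the model label.
#'
#' @inheritParams cochran_q
#' @param tau2 between-study variance (>= 0), typically from
#'   [estimate_tau2()].
#' @param estimator label recorded in the result (e.g. `"DL"`).
#' @return A `pooled_result` list; see [pool_fixed()].
#' @export
pool_random <- function(effects, tau2, estimator = "user") {
  if (!is.numeric(tau2) || length(tau2) != 1L || is.na(tau2) || tau2 < 0) {
    stop("tau2 must be a single non-negative number")
  }
  eff <- included_effects(effects)
  w <- 1 / (eff$v + tau2)
  theta <- sum(w * eff$y) / sum(w)
  variance <- 1 / sum(w)
  k <- nrow(eff)
  q <- if (k >= 2L) cochran_q(effects) else list(Q = NA_real_, df = NA_integer_,
                                                 p_value = NA_real_)
  pooled_result("random", estimator, theta, variance, k,
                Q = q$Q, q_df = q$df, q_pvalue = q$p_value, tau2_hat = tau2)
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("%s-effect pooled log OR (%s): %.4f [%.4f, %.4f], z = %.3f\n",
              x$model, x$estimator, x$theta_hat, x$ci_low, x$ci_high,
              x$z_score))
  if (!is.na(x$Q)) {
    cat(sprintf("k = %d, tau2 = %.4f, Q = %.3f (df = %d, p = %.4f)\n",
                x$k, x$tau2_hat, x$Q, x$q_df, x$q_pvalue))
  } else {
    cat(sprintf("k = %d, tau2 = %.4f\n", x$k, x$tau2_hat))
  }
  invisible(x)
}
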