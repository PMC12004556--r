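#' Generalized Q statistic at a candidate tau-squared
#'
#' `sum((y_i - mu(t))^2 / (v_i + t))` where `mu(t)` is the random-effects
#' pooled mean using weights `1/(v_i + t)`. At `t = 0` this is Cochran's
#' Q; it decreases strictly to 0 as `t` grows, which is what makes the
#' Paule-Mandel estimator a bracketed root-finding problem.
#'
#' @inheritParams cochran_q
#' @param tau2 candidate between-study variance (>= 0).
#' @return The statistic (a single number).
#' @export
generalized_q <- function(effects, tau2) {
  if (!is.numeric(tau2) || length(tau2) != 1L || is.na(tau2) || tau2 < 0) {
    stop("tau2 must be a single non-negative number")
  }
  eff <- included_effects(effects)
  w <- 1 / (eff$v + tau2)
  mu <- sum(w * eff$y) / sum(w)
  sum(w * (eff$y - mu)^2)
}

tau2_estimate <- function(value, method, iterations = 0L, converged = TRUE) {
  out <- list(value = max(0, value), method = method,
              iterations = as.integer(iterations), converged = converged)
  class(out) <- "tau2_estimate"
  out
}

#' @export
print.tau2_estimate <- function(x, ...) {
  cat(sprintf("tau2 (%s): %.6g%s\n", x$method, x$value,
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' Estimate the between-study variance
#'
#' Six estimators of the between-study variance tau-squared of a
#' random-effects meta-analysis, on the log-odds-ratio scale:
#'
#' * `DL` (DerSimonian-Laird, method of moments):
#'   `max(0, (Q - (k-1)) / C)` with `C = sum(w) - sum(w^2)/sum(w)`,
#'   `w_i = 1/v_i`.
#' * `HS` (Hunter-Schmidt): `max(0, (Q - k) / sum(w))`.
#' * `SJ` (Sidik-Jonkman): initial estimate
#'   `t0 = sum((y - mean(y))^2) / k` (unweighted, divisor `k` as in the
#'   original proposal; `k - 1` available via `sj_divisor`), then
#'   `q_i = v_i/t0 + 1` and `tau2 = sum((y - mu)^2 / q_i) / (k - 1)` with
#'   `mu` the `1/q_i`-weighted mean.
#' * `PM` (Paule-Mandel): the root of `generalized_q(effects, t) = k - 1`,
#'   truncated to 0 when `generalized_q(effects, 0) <= k - 1`.
#' * `ML` / `REML`: (restricted) maximum likelihood under
#'   `y_i ~ N(theta, v_i + tau2)`, by fixed-point iteration (tolerance
#'   `tol` on tau2, at most `max_iter` iterations) with a bisection
#'   fallback on the score function; estimates truncated at 0.
#'
#' @inheritParams cochran_q
#' @param method one of `"DL"`, `"REML"`, `"ML"`, `"PM"`, `"SJ"`, `"HS"`.
#' @param tol convergence tolerance on tau2 for the iterative methods.
#' @param max_iter iteration cap before the bisection fallback.
#' @param sj_divisor divisor of the Sidik-Jonkman initial estimate.
#' @return A `tau2_estimate` list: `value` (>= 0), `method`,
#'   `iterations`, `converged`.
#' @examples
#' eff <- data.frame(y = c(0, 2), v = c(1, 1), included = TRUE)
#' estimate_tau2(eff, "DL")$value  # 1
#' estimate_tau2(eff, "HS")$value  # 0
#' @export
estimate_tau2 <- function(effects,
                          method = c("DL", "REML", "ML", "PM", "SJ", "HS"),
                          tol = 1e-10, max_iter = 100L,
                          sj_divisor = c("k", "k-1")) {
  method <- match.arg(method)
  sj_divisor <- match.arg(sj_divisor)
  eff <- included_effects(effects)
  k <- nrow(eff)
  if (k < 2L) stop("tau2 estimation needs at least 2 included studies")
  y <- eff$y
  v <- eff$v

  switch(method,
    DL = {
      w <- 1 / v
      theta <- sum(w * y) / sum(w)
      Q <- sum(w * (y - theta)^2)
      C <- sum(w) - sum(w^2) / sum(w)
      tau2_estimate((Q - (k - 1)) / C, "DL")
    },
    HS = {
      w <- 1 / v
      theta <- sum(w * y) / sum(w)
      Q <- sum(w * (y - theta)^2)
      tau2_estimate((Q - k) / sum(w), "HS")
    },
    SJ = {
      div <- if (sj_divisor == "k") k else k - 1L
      t0 <- sum((y - mean(y))^2) / div
      if (t0 <= 0) return(tau2_estimate(0, "SJ"))
      q <- v / t0 + 1
      mu <- sum(y / q) / sum(1 / q)
      tau2_estimate(sum((y - mu)^2 / q) / (k - 1), "SJ")
    },
    PM = tau2_pm(eff, tol = tol),
    ML = tau2_likelihood(eff, restricted = FALSE, tol = tol,
                         max_iter = max_iter),
    REML = tau2_likelihood(eff, restricted = TRUE, tol = tol,
                           max_iter = max_iter)
  )
}

# Paule-Mandel: bracketed root of generalized Q = k - 1.
tau2_pm <- function(eff, tol = 1e-10) {
  k <- nrow(eff)
  gq <- function(t) {
    w <- 1 / (eff$v + t)
    mu <- sum(w * eff$y) / sum(w)
    sum(w * (eff$y - mu)^2)
  }
  if (gq(0) <= k - 1) return(tau2_estimate(0, "PM"))
  upper <- max(stats::var(eff$y), .Machine$double.eps)
  it <- 0L
  while (gq(upper) > k - 1 && it < 60L) {
    upper <- upper * 2
    it <- it + 1L
  }
  if (gq(upper) > k - 1) {
    return(tau2_estimate(upper, "PM", iterations = it, converged = FALSE))
  }
  root <- stats::uniroot(function(t) gq(t) - (k - 1), c(0, upper),
                         tol = min(tol, 1e-12))
  tau2_estimate(root$root, "PM", iterations = it + root$iter)
}

# ML/REML score in tau2 (profile over theta). Zero at the optimum when
# interior; negative everywhere on [0, Inf) means truncation at 0.
likelihood_score <- function(t, y, v, restricted) {
  w <- 1 / (v + t)
  theta <- sum(w * y) / sum(w)
  s <- sum(w^2 * (y - theta)^2) - sum(w)
  if (restricted) s <- s + sum(w^2) / sum(w)
  s / 2
}

# Fixed-point iteration for ML/REML with bisection fallback on the score.
tau2_likelihood <- function(eff, restricted, tol = 1e-10, max_iter = 100L) {
  y <- eff$y
  v <- eff$v
  label <- if (restricted) "REML" else "ML"
  if (likelihood_score(0, y, v, restricted) <= 0) {
    return(tau2_estimate(0, label))
  }
  t_cur <- max(stats::var(y) - mean(v), mean(v) * 1e-3)
  iter <- 0L
  repeat {
    w <- 1 / (v + t_cur)
    theta <- sum(w * y) / sum(w)
    t_new <- sum(w^2 * ((y - theta)^2 - v)) / sum(w^2)
    if (restricted) t_new <- t_new + 1 / sum(w)
    t_new <- max(0, t_new)
    iter <- iter + 1L
    if (abs(t_new - t_cur) < tol) {
      return(tau2_estimate(t_new, label, iterations = iter))
    }
    if (iter >= max_iter) break
    t_cur <- t_new
  }
  # bisection on the score: score(0) > 0, find upper with score < 0
  upper <- max(stats::var(y), mean(v))
  nd <- 0L
  while (likelihood_score(upper, y, v, restricted) > 0 && nd < 60L) {
    upper <- upper * 2
    nd <- nd + 1L
  }
  if (likelihood_score(upper, y, v, restricted) > 0) {
    return(tau2_estimate(t_cur, label, iterations = iter + nd,
                         converged = FALSE))
  }
  root <- stats::uniroot(likelihood_score, c(0, upper), y = y, v = v,
                         restricted = restricted, tol = min(tol, 1e-12))
  tau2_estimate(root$root, label, iterations = iter + nd + root$iter)
}
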