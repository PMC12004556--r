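#' O'Brien-Fleming-type alpha-spending function
#'
#' The Lan-DeMets spending function that mimics O'Brien-Fleming group
#' sequential boundaries: cumulative type-I error available by
#' information fraction `t` is `2 * (1 - pnorm(qnorm(1 - alpha/2) / sqrt(t)))`.
#' It spends almost nothing early and releases the full `alpha` at
#' `t = 1`, so early boundaries are very conservative and the final
#' boundary approaches the fixed-sample critical value.
#'
#' @param t information fraction(s) in (0, 1].
#' @param alpha overall two-sided significance level in (0, 1).
#' @return Cumulative alpha spent at each `t` (same length as `t`).
#' @examples
#' obf_alpha_spent(1, 0.05)    # 0.05
#' obf_alpha_spent(0.5, 0.05)  # 0.005574
#' @export
obf_alpha_spent <- function(t, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0) || any(t > 1)) {
    stop("information fractions must lie in (0, 1]")
  }
  2 * (1 - stats::pnorm(stats::qnorm(1 - alpha / 2) / sqrt(t)))
}

#' Build a monitoring look schedule
#'
#' Clips raw information fractions into the numerically workable range:
#' fractions below `floor` are floored to `floor`, fractions above 1 are
#' clipped to 1 (all remaining alpha is spent at the first such look, and
#' any later looks share that final boundary). After clipping, fractions
#' are nudged minimally upward where flooring created ties, so the
#' schedule is strictly increasing.
#'
#' @param fractions raw information fractions, strictly increasing, > 0.
#' @param floor smallest usable fraction (default 0.01).
#' @return list of class `"look_schedule"` with `fractions` (clipped,
#'   strictly increasing, in (0, 1]) and `raw_fractions`.
#' @export
look_schedule <- function(fractions, floor = 0.01) {
  if (length(fractions) == 0L || any(!is.finite(fractions)) ||
      any(fractions <= 0)) {
    stop("fractions must be positive finite numbers")
  }
  if (is.unsorted(fractions, strictly = TRUE)) {
    stop("fractions must be strictly increasing")
  }
  raw <- fractions
  t <- pmin(pmax(fractions, floor), 1)
  # drop looks after the first that reaches full information
  keep <- rep(TRUE, length(t))
  full <- which(t >= 1)
  if (length(full) > 1L) keep[full[-1L]] <- FALSE
  t <- t[keep]
  # resolve ties introduced by the floor
  if (length(t) > 1L) {
    for (i in 2:length(t)) {
      if (t[i] <= t[i - 1L]) t[i] <- min(1, t[i - 1L] + 1e-6)
    }
  }
  structure(list(fractions = t, raw_fractions = raw, kept = keep),
            class = "look_schedule")
}

trapezoid_weights <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  h <- diff(x)
  w <- numeric(n)
  w[1L] <- h[1L] / 2
  w[n] <- h[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (h[-(n - 1L)] + h[-1L]) / 2
  w
}

#' Two-sided alpha-spending monitoring boundaries
#'
#' Computes symmetric boundaries `+/- b_j` at the scheduled information
#' fractions such that, for a Brownian motion under the null on the
#' information scale, the probability of first crossing at look `j`
#' equals the increment of the spending function at `t_j`. Uses the
#' standard group-sequential recursion: the sub-density of paths that
#' have not yet crossed is propagated across looks by convolution with
#' the Gaussian increment kernel on a numeric grid (trapezoid rule), and
#' each boundary is found by bracketed root-finding on the incremental
#' crossing probability.
#'
#' When the incremental spend at a look underflows (common at very small
#' fractions under O'Brien-Fleming-type spending), the boundary is capped
#' at `cap` and flagged.
#'
#' @param schedule a [look_schedule()], or a numeric vector of raw
#'   fractions which will be passed through `look_schedule()`.
#' @param alpha overall two-sided level (default 0.05).
#' @param grid number of grid points per look for the numerical
#'   integration (default 512).
#' @param cap largest admissible boundary z (default 8).
#' @param spend_floor incremental spends below this are treated as zero
#'   and capped (default 1e-12).
#' @param spending optional spending function `f(t)` returning the
#'   cumulative two-sided spend at fraction `t`; defaults to
#'   [obf_alpha_spent()] at level `alpha`. Useful for comparing boundary
#'   conventions (e.g. per-side alpha/2 spending as used by classic
#'   group-sequential tables).
#' @return data.frame of class `"boundary_result"`: per look `t`,
#'   `cum_spend`, `incr_spend`, `boundary_z`, `capped`.
#' @examples
#' compute_boundaries(c(0.5, 1))  # approx 2.963, 1.969
#' @export
compute_boundaries <- function(schedule, alpha = 0.05, grid = 512L,
                               cap = 8, spend_floor = 1e-12,
                               spending = NULL) {
  if (!inherits(schedule, "look_schedule")) schedule <- look_schedule(schedule)
  t <- schedule$fractions
  J <- length(t)
  if (is.null(spending)) spending <- function(tt) obf_alpha_spent(tt, alpha)
  cum_spend <- spending(t)
  cum_spend[t >= 1] <- spending(1)
  incr <- diff(c(0, cum_spend))
  incr[incr < 0] <- 0

  b <- numeric(J)
  capped <- logical(J)

  # look 1 is exact: P(|Z| > b) = incr[1] with Z ~ N(0, 1) scaled
  if (incr[1L] < spend_floor) {
    b[1L] <- cap
    capped[1L] <- TRUE
  } else {
    b[1L] <- min(cap, stats::qnorm(1 - incr[1L] / 2))
    capped[1L] <- b[1L] >= cap
  }
  # non-crossing sub-density on the Brownian (S = B(t)) scale
  u <- seq(-b[1L] * sqrt(t[1L]), b[1L] * sqrt(t[1L]), length.out = grid)
  f <- stats::dnorm(u, mean = 0, sd = sqrt(t[1L]))

  if (J > 1L) {
    for (j in 2:J) {
      dt <- t[j] - t[j - 1L]
      wu <- trapezoid_weights(u)
      mass_prev <- sum(wu * f)
      cmax <- cap * sqrt(t[j])
      # propagated density on a solving grid covering the admissible range
      s <- seq(-cmax, cmax, length.out = grid)
      K <- stats::dnorm(outer(s, u, "-"), mean = 0, sd = sqrt(dt))
      fs <- as.vector(K %*% (wu * f))
      ws <- trapezoid_weights(s)
      cum_fs <- cumsum(ws * fs)  # integral from -cmax up to s[i] (approx)
      inside <- function(c_) {
        # integral of fs over [-c, c] by interpolation of the cumulative
        hi <- stats::approx(s, cum_fs, xout = c_, rule = 2)$y
        lo <- stats::approx(s, cum_fs, xout = -c_, rule = 2)$y
        hi - lo
      }
      cross <- function(c_) mass_prev - inside(c_)
      if (incr[j] < spend_floor || cross(cmax) >= incr[j]) {
        b[j] <- cap
        capped[j] <- TRUE
      } else {
        root <- stats::uniroot(function(c_) cross(c_) - incr[j],
                               c(0, cmax), tol = 1e-12)
        b[j] <- root$root / sqrt(t[j])
      }
      # truncate: recompute the density on the surviving interval
      c_j <- b[j] * sqrt(t[j])
      u_new <- seq(-c_j, c_j, length.out = grid)
      K2 <- stats::dnorm(outer(u_new, u, "-"), mean = 0, sd = sqrt(dt))
      f <- as.vector(K2 %*% (wu * f))
      u <- u_new
    }
  }

  out <- data.frame(t = t, cum_spend = cum_spend, incr_spend = incr,
                    boundary_z = b, capped = capped)
  class(out) <- c("boundary_result", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "raw_fractions") <- schedule$raw_fractions
  attr(out, "kept") <- schedule$kept
  out
}
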