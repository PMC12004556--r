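# Independent high-resolution recursion on the standardized z-scale with
# Simpson quadrature; oracle for compute_boundaries (which works on the
# Brownian scale with trapezoid integration).
oracle_boundaries <- function(fractions, alpha = 0.05, n_grid = 4001,
                              zmax = 8.5, spend = NULL) {
  if (is.null(spend)) spend <- function(t) tsasens::obf_alpha_spent(t, alpha)
  t <- fractions
  J <- length(t)
  cum <- spend(t)
  incr <- diff(c(0, cum))
  simpson_w <- function(n, h) {
    w <- rep(c(2, 4), length.out = n)
    w[1] <- 1
    w[n] <- 1
    w * h / 3
  }
  z <- seq(-zmax, zmax, length.out = n_grid)
  h <- z[2] - z[1]
  w <- simpson_w(n_grid, h)
  b <- numeric(J)
  g <- dnorm(z)
  mass <- 1
  for (j in seq_len(J)) {
    if (j > 1) {
      dt <- t[j] - t[j - 1]
      ratio <- sqrt(t[j] / dt)
      K <- dnorm(outer(z * sqrt(t[j]), z * sqrt(t[j - 1]), "-") / sqrt(dt)) *
        ratio
      g <- as.vector(K %*% (w * g))
    }
    cumg <- cumsum(w * g)
    inside <- function(bb) {
      hi <- approx(z, cumg, xout = bb, rule = 2)$y
      lo <- approx(z, cumg, xout = -bb, rule = 2)$y
      hi - lo
    }
    lo_b <- 0
    hi_b <- zmax
    for (it in 1:80) {
      mid <- (lo_b + hi_b) / 2
      if (mass - inside(mid) > incr[j]) lo_b <- mid else hi_b <- mid
    }
    b[j] <- (lo_b + hi_b) / 2
    g[abs(z) > b[j]] <- 0
    mass <- mass - incr[j]
  }
  b
}

# Monte-Carlo first-crossing probability of Brownian paths at +/- b
mc_crossing <- function(fractions, boundary_z, n_paths, seed = 555) {
  withr::local_seed(seed)
  J <- length(fractions)
  dt <- diff(c(0, fractions))
  crossed <- rep(FALSE, n_paths)
  s <- numeric(n_paths)
  for (j in seq_len(J)) {
    s <- s + rnorm(n_paths, 0, sqrt(dt[j]))
    crossed <- crossed | abs(s) >= boundary_z[j] * sqrt(fractions[j])
  }
  mean(crossed)
}
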