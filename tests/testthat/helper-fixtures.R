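# Small fixtures built in code, shared across test files.

# effects table from bare y/v vectors
make_effects <- function(y, v) {
  data.frame(y = y, v = v, included = TRUE)
}

toy_effects <- function() make_effects(c(0, 2), c(1, 1))

# a deterministic k-study 2x2 table set with a clear ordering
toy_records <- function() {
  study_records(data.frame(
    study_id = c("alpha", "bravo", "charlie"),
    order_key = c(1998L, 2003L, 2010L),
    events_int = c(4L, 10L, 7L),
    total_int = c(60L, 120L, 90L),
    events_ctl = c(9L, 18L, 15L),
    total_ctl = c(55L, 115L, 95L)
  ))
}

# seeded heterogeneous effects for the iterative-estimator checks
seeded_effects <- function(k = 20, tau2 = 0.2, seed = 42) {
  withr::local_seed(seed)
  v <- runif(k, 0.02, 0.3)
  y <- rnorm(k, mean = -0.4, sd = sqrt(tau2 + v))
  make_effects(y, v)
}
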