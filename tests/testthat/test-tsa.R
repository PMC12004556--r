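test_that("diversity and the adjustment factor follow their definitions", {
  expect_equal(diversity(0.5, 0.5), 0)
  expect_equal(diversity(0.04, 0.07), 3 / 7, tolerance = 1e-9)
  expect_error(diversity(0.07, 0.04), "variance_random")

  expect_equal(adjustment_factor(0), 1)
  expect_equal(adjustment_factor(0.5), 2)
  expect_equal(round(adjustment_factor(0.43), 2), 1.75)
  expect_error(adjustment_factor(1), "d2")
  expect_error(adjustment_factor(-0.1), "d2")

  # D2 strictly increases with tau2 on fixed data
  eff <- seeded_effects(k = 10)
  vf <- pool_fixed(eff)$variance
  d2s <- vapply(c(0, 0.05, 0.1, 0.3, 1),
                function(t) diversity(vf, pool_random(eff, t)$variance),
                numeric(1))
  expect_true(all(diff(d2s) > 0))
})

test_that("the implied log odds ratio matches direct arithmetic", {
  expect_equal(implied_log_or(0.1, 0.2),
               abs(log((0.08 / 0.92) / (0.1 / 0.9))), tolerance = 1e-12)
  expect_equal(round(implied_log_or(0.1, 0.2), 5), 0.24512)
  # p_C = 0.5 has even odds in the control arm, so mu = |ln(OR_int)|
  expect_equal(implied_log_or(0.5, 0.2), abs(log(0.4 / 0.6)),
               tolerance = 1e-12)
  expect_error(implied_log_or(0, 0.2))
  expect_error(implied_log_or(0.1, 1))
})

test_that("required information size obeys both modes and the AF scaling", {
  cfg_lit <- tsa_config(ris_mode = "eq1_literal", expected_log_or = 0.5)
  # two studies with v = 2 pool to a random-effects variance of exactly 1
  pooled <- pool_random(make_effects(c(0, -0.6), c(2, 2)), 0)
  r <- required_information_size(cfg_lit, pooled_random = pooled)
  expect_equal(r$ris_unadjusted,
               4 * (qnorm(0.975) + qnorm(0.8))^2 * 1 / 0.25, tolerance = 1e-9)
  expect_equal(round(r$ris_unadjusted, 2), 125.58)

  cfg_prop <- tsa_config(ris_mode = "proportion", rrr = 0.2)
  rp <- required_information_size(cfg_prop, p_control = 0.1)
  expect_equal(round(rp$unadjusted_raw, 1), 6428.2)
  expect_equal(rp$ris_unadjusted, 6429)

  rp2 <- required_information_size(cfg_prop, af = 2, p_control = 0.1)
  expect_equal(rp2$adjusted_raw, 2 * rp2$unadjusted_raw, tolerance = 1e-12)

  # adjusted RIS grows with tau2; with equal within-study variances
  # AF = (v + tau2)/v, so the growth is exactly linear there
  ris_at <- function(eff, t) {
    vf <- pool_fixed(eff)$variance
    pr <- pool_random(eff, t)
    af <- adjustment_factor(diversity(vf, pr$variance))
    required_information_size(cfg_prop, pr, af = af,
                              p_control = 0.1)$adjusted_raw
  }
  tau2s <- seq(0, 0.4, 0.05)
  eq <- make_effects(c(-0.2, 0.1, -0.5, -0.8), rep(0.12, 4))
  ris_eq <- vapply(tau2s, function(t) ris_at(eq, t), numeric(1))
  slopes <- diff(ris_eq) / diff(tau2s)
  expect_equal(max(slopes), min(slopes), tolerance = 1e-9)
  expect_true(all(slopes > 0))

  het <- seeded_effects(k = 12)
  ris_het <- vapply(tau2s, function(t) ris_at(het, t), numeric(1))
  expect_true(all(diff(ris_het) > 0))
})

test_that("the cumulative z-curve matches a prefix-loop oracle", {
  one <- study_records(data.frame(
    study_id = "only", order_key = 1L,
    events_int = 10L, total_int = 50L, events_ctl = 20L, total_ctl = 50L))
  eff1 <- log_odds_ratio(one)
  c1 <- cumulative_z_curve(one)
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$z, eff1$y / sqrt(eff1$v), tolerance = 1e-12)
  expect_equal(c1$tau2, 0)

  rec <- toy_records()
  for (m in c("DL", "REML", "SJ")) {
    curve <- cumulative_z_curve(rec, estimator = m)
    eff <- log_odds_ratio(rec)
    expect_equal(nrow(curve), 3L)
    for (j in 2:3) {
      prefix <- eff[1:j, ]
      t_j <- estimate_tau2(prefix, m)$value
      oracle <- pool_random(prefix, t_j)$z_score
      expect_equal(curve$z[j], oracle, tolerance = 1e-10,
                   label = paste(m, "look", j))
    }
    expect_equal(curve$cum_n, cumsum(eff$n))
  }

  # two opposite equal studies cancel under any estimator
  sym <- make_effects(c(1, -1), c(0.3, 0.3))
  for (m in c("DL", "SJ", "PM")) {
    t_j <- estimate_tau2(sym, m)$value
    expect_equal(pool_random(sym, t_j)$z_score, 0, tolerance = 1e-10)
  }
})

test_that("run_tsa assembles a coherent result and verdicts behave", {
  # strong homogeneous effect, ample information: conclusive
  strong <- generate_meta_dataset(simulation_spec(
    k = 8, theta = -1, tau2 = 0, p_control = 0.2,
    n_range = c(900L, 1100L), seed = 5))
  cfg_fixed_pc <- tsa_config(control_rate = 0.2)
  res <- run_tsa(strong, cfg_fixed_pc)
  expect_s3_class(res, "tsa_result")
  expect_equal(res$conclusion, "conclusive_crossed")
  expect_true(any(res$looks$crossed))

  # final-look z equals the plain random-effects meta-analysis z
  expect_equal(res$looks$z[nrow(res$looks)], res$pooled_random$z_score,
               tolerance = 1e-10)
  expect_equal(res$ris$ris_adjusted,
               ceiling(res$ris$unadjusted_raw * res$af))

  # null data far below the RIS: inconclusive
  null_small <- generate_meta_dataset(simulation_spec(
    k = 4, theta = 0, tau2 = 0, p_control = 0.1,
    n_range = c(40L, 60L), seed = 6))
  res0 <- run_tsa(null_small, tsa_config())
  expect_equal(res0$conclusion, "inconclusive")
  expect_lt(max(res0$looks$frac_raw), 1)

  # null data beyond the RIS: ris_reached_not_crossed
  null_big <- generate_meta_dataset(simulation_spec(
    k = 12, theta = 0, tau2 = 0, p_control = 0.1,
    n_range = c(2000L, 2000L), seed = 8))
  resb <- run_tsa(null_big, tsa_config())
  expect_true(resb$conclusion %in%
                c("ris_reached_not_crossed", "conclusive_crossed"))
  expect_gte(max(resb$looks$cum_n), resb$ris$ris_adjusted)

  # conclusion invariant to swapping intervention and control arms
  # (control rate held at the design value so only effect signs flip)
  flipped <- strong
  flipped[, c("events_int", "total_int", "events_ctl", "total_ctl")] <-
    flipped[, c("events_ctl", "total_ctl", "events_int", "total_int")]
  resf <- run_tsa(study_records(flipped), cfg_fixed_pc)
  expect_equal(resf$conclusion, res$conclusion)
  expect_equal(resf$min_boundary, -res$min_boundary, tolerance = 1e-6)
})

test_that("larger tau2 propagates monotonically through D2, AF, RIS and boundaries", {
  eff <- seeded_effects(k = 10, tau2 = 0.3, seed = 21)
  vf <- pool_fixed(eff)$variance
  cfg <- tsa_config()
  tau2s <- c(0, 0.02, 0.08, 0.2, 0.5)
  d2 <- af <- ris <- bound <- numeric(length(tau2s))
  for (i in seq_along(tau2s)) {
    pr <- pool_random(eff, tau2s[i])
    d2[i] <- diversity(vf, pr$variance)
    af[i] <- adjustment_factor(d2[i])
    ris[i] <- required_information_size(cfg, pr, af = af[i],
                                        p_control = 0.1)$adjusted_raw
    # boundary at a fixed accumulated-N look becomes more extreme as the
    # RIS (hence a smaller information fraction) grows
    frac <- min(1, 2000 / ris[i])
    bound[i] <- compute_boundaries(frac)$boundary_z
  }
  expect_true(all(diff(d2) > 0))
  expect_true(all(diff(af) > 0))
  expect_true(all(diff(ris) > 0))
  expect_true(all(diff(bound) >= 0))
})
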