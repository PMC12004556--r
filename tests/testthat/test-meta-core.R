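test_that("log odds ratios and variances follow the 2x2 arithmetic", {
  rec <- study_records(data.frame(
    study_id = c("sym", "asym", "zero", "double_zero"),
    order_key = 1:4,
    events_int = c(5L, 10L, 0L, 0L),
    total_int = c(10L, 100L, 10L, 10L),
    events_ctl = c(5L, 20L, 5L, 0L),
    total_ctl = c(10L, 100L, 10L, 10L)
  ))
  eff <- log_odds_ratio(rec)

  # symmetric table forces OR = 1
  expect_equal(eff$y[1], 0)
  expect_equal(eff$v[1], 0.8)
  # direct arithmetic: ln(10*80 / (90*20)), 1/10+1/90+1/20+1/80
  expect_equal(eff$y[2], log(800 / 1800), tolerance = 1e-12)
  expect_equal(eff$v[2], 0.1 + 1 / 90 + 0.05 + 0.0125, tolerance = 1e-12)
  expect_false(eff$corrected[2])
  # continuity-corrected cells (0.5, 10.5, 5.5, 5.5)
  expect_equal(eff$y[3], log(0.5 / 10.5), tolerance = 1e-5)
  expect_equal(eff$v[3], 1 / 0.5 + 1 / 10.5 + 1 / 5.5 + 1 / 5.5,
               tolerance = 1e-6)
  expect_true(eff$corrected[3])
  # double-zero study carries no information but raises no error
  expect_false(eff$included[4])
  expect_true(all(is.finite(eff$y[eff$included])))
  expect_true(all(eff$v[eff$included] > 0))
})

test_that("double-full studies and the no-correction rule are flagged out", {
  rec <- study_records(data.frame(
    study_id = c("full", "sparse"), order_key = 1:2,
    events_int = c(10L, 0L), total_int = c(10L, 20L),
    events_ctl = c(8L, 4L), total_ctl = c(8L, 20L)
  ))
  eff <- log_odds_ratio(rec)
  expect_false(eff$included[1])
  expect_true(eff$included[2])
  eff_none <- log_odds_ratio(rec, correction = "none")
  expect_false(any(eff_none$included))
})

test_that("fixed-effect pooling is the inverse-variance weighted mean", {
  expect_equal(pool_fixed(make_effects(c(0, 2), c(1, 1)))$theta_hat, 1)
  expect_equal(pool_fixed(make_effects(c(0, 2), c(1, 1)))$variance, 0.5)
  expect_equal(pool_fixed(make_effects(c(1, 1, 1), c(0.2, 1, 3)))$theta_hat, 1)
  p <- pool_fixed(make_effects(c(0, 1), c(0.5, 1)))
  expect_equal(p$theta_hat, 1 / 3, tolerance = 1e-12)
  expect_equal(p$variance, 1 / 3, tolerance = 1e-12)
  expect_equal(p$z_score, p$theta_hat / p$se)
  expect_error(pool_fixed(data.frame(y = 1, v = 1, included = FALSE)),
               "no included")
})

test_that("random-effects pooling collapses to fixed at tau2 = 0 and widens with tau2", {
  eff <- seeded_effects(k = 12)
  f <- pool_fixed(eff)
  r0 <- pool_random(eff, 0)
  expect_equal(r0$theta_hat, f$theta_hat)
  expect_equal(r0$variance, f$variance)
  expect_equal(r0$z_score, f$z_score)

  r1 <- pool_random(make_effects(c(0, 2), c(1, 1)), tau2 = 1)
  expect_equal(r1$theta_hat, 1)
  expect_equal(r1$variance, 1)

  # variance non-decreasing in tau2
  vs <- vapply(c(0, 0.05, 0.2, 1, 5), function(t) pool_random(eff, t)$variance,
               numeric(1))
  expect_true(all(diff(vs) > 0))
  expect_true(all(vs >= f$variance))
})

test_that("Cochran's Q matches the chi-square oracle and the 0.10 rule", {
  q <- cochran_q(make_effects(c(0, 2), c(1, 1)))
  expect_equal(q$Q, 2)
  expect_equal(q$df, 1)
  expect_equal(q$p_value, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(q$p_value, 5), 0.15730)

  expect_equal(cochran_q(make_effects(rep(0.7, 4), c(1, 2, 3, 4)))$Q, 0)

  # p just under 0.10 is significant under the meta-analytic convention,
  # not under 0.05
  eff <- make_effects(c(0, 2.335), c(1, 1))
  q2 <- cochran_q(eff)
  expect_true(q2$p_value < 0.1 && q2$p_value > 0.05)
  expect_true(q2$significant)
  expect_false(cochran_q(eff, threshold = 0.05)$significant)

  expect_error(cochran_q(make_effects(1, 1)), "at least 2")

  # Q is invariant to shifting all effects
  eff3 <- seeded_effects(k = 8)
  shifted <- eff3
  shifted$y <- shifted$y + 3.2
  expect_equal(cochran_q(eff3)$Q, cochran_q(shifted)$Q, tolerance = 1e-9)
})

test_that("pooling agrees with metafor on seeded data", {
  skip_if_not_installed("metafor")
  eff <- seeded_effects(k = 15, seed = 99)
  f <- pool_fixed(eff)
  m <- metafor::rma(yi = eff$y, vi = eff$v, method = "FE")
  expect_equal(f$theta_hat, as.numeric(m$beta), tolerance = 1e-10)
  expect_equal(f$se, m$se, tolerance = 1e-10)
  expect_equal(f$Q, m$QE, tolerance = 1e-10)
})

test_that("study records validate counts and order deterministically", {
  expect_error(study_records(data.frame(
    study_id = "a", order_key = 1, events_int = 5, total_int = 4,
    events_ctl = 1, total_ctl = 10)), "row")
  expect_error(study_records(data.frame(
    study_id = "a", order_key = 1, events_int = 1, total_int = 10,
    events_ctl = 1, total_ctl = 0)), "control")
  expect_error(study_records(data.frame(
    study_id = "a", order_key = 1, events_int = 1.5, total_int = 10,
    events_ctl = 1, total_ctl = 10)), "integers")

  # tie in order_key broken by study_id
  rec <- study_records(data.frame(
    study_id = c("zed", "ann"), order_key = c(2000L, 2000L),
    events_int = c(1L, 2L), total_int = c(10L, 10L),
    events_ctl = c(1L, 2L), total_ctl = c(10L, 10L)))
  expect_equal(rec$study_id, c("ann", "zed"))
})
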