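test_that("qcv follows the stated quartile rules", {
  expect_equal(qcv(c(2, 2, 2, 2)), 0)
  expect_equal(qcv(c(0, 0, 0, 1, 2, 3)), 100)
  expect_equal(qcv(c(1, 2, 3, 4, 5, 6)), 100 * 2.5 / 7, tolerance = 1e-9)
  expect_equal(round(qcv(c(1, 2, 3, 4, 5, 6)), 2), 35.71)
  # Tukey hinges give different quartiles on the same data
  expect_equal(qcv(c(1, 2, 3, 4, 5, 6), rule = "tukey"), 100 * 3 / 7,
               tolerance = 1e-9)
  expect_error(qcv(c(-1, 2, 3)), "non-negative")
  expect_error(qcv(1), ">= 2")
  # scale invariance and the Q1 = Q3 characterization of zero
  x <- c(0.2, 0.7, 1.3, 4)
  expect_equal(qcv(10 * x), qcv(x), tolerance = 1e-12)
  expect_equal(qcv(c(0, 0, 0, 0, 0, 1)), 0)  # Q1 = Q3 = 0
})

test_that("range_summary matches a sort-based oracle", {
  expect_equal(range_summary(c(1.75, 1, 1.2)), c(min = 1, max = 1.75))
  expect_equal(range_summary(3.3), c(min = 3.3, max = 3.3))
  withr::local_seed(9)
  x <- rnorm(25)
  s <- sort(x)
  expect_equal(unname(range_summary(x)), c(s[1], s[25]))
  expect_error(range_summary(numeric(0)))
})

test_that("homogeneous data yield six identical rows with zero QCV", {
  rec <- generate_meta_dataset(simulation_spec(
    k = 10, theta = -0.4, tau2 = 0, p_control = 0.15,
    n_range = c(1500L, 1500L), seed = 31))
  sw <- sweep_estimators(rec, tsa_config())
  expect_equal(nrow(sw$rows), 6L)
  expect_true(all(is.na(sw$rows$error)))
  # with large homogeneous trials every estimator lands at (or near) 0
  if (all(sw$rows$tau2 < 1e-10)) {
    expect_equal(sw$summaries$qcv[sw$summaries$quantity == "d2"], 0)
    expect_true(sw$agreement)
    expect_equal(length(unique(sw$rows$ris_adjusted)), 1L)
  }
  # summaries recomputed independently agree exactly
  for (q in sw$summaries$quantity) {
    vals <- sw$rows[[q]]
    expect_equal(sw$summaries$min[sw$summaries$quantity == q], min(vals))
    expect_equal(sw$summaries$max[sw$summaries$quantity == q], max(vals))
    expect_equal(sw$summaries$qcv[sw$summaries$quantity == q],
                 qcv(abs(vals)), tolerance = 1e-12)
  }
})

test_that("SJ tends to dominate the sweep on heterogeneous synthetic data", {
  # the Sidik-Jonkman tendency to produce the largest tau2 is a
  # tendency, not a per-dataset theorem: assert it across replicates
  ms <- c("DL", "REML", "ML", "PM", "SJ", "HS")
  n_rep <- 20
  sj_is_max <- logical(n_rep)
  means <- setNames(numeric(6), ms)
  for (r in seq_len(n_rep)) {
    rec <- generate_meta_dataset(simulation_spec(
      k = 9, theta = -0.7, tau2 = 0.15, p_control = c(0.05, 0.25),
      n_range = c(30L, 250L), seed = 5000 + r))
    eff <- log_odds_ratio(rec)
    vals <- vapply(ms, function(m) estimate_tau2(eff, m)$value, numeric(1))
    sj_is_max[r] <- vals["SJ"] == max(vals)
    means <- means + vals / n_rep
  }
  expect_gt(mean(sj_is_max), 0.5)
  expect_equal(names(which.max(means)), "SJ")

  # within one sweep, monotone propagation across estimators: ordering
  # by tau2 matches ordering by D2, AF and RIS
  rec <- generate_meta_dataset(preset_specs()$small_heterogeneous)
  sw <- sweep_estimators(rec, tsa_config())
  expect_true(all(is.na(sw$rows$error)))
  ord <- order(sw$rows$tau2)
  expect_equal(order(sw$rows$d2), ord)
  expect_equal(order(sw$rows$af), ord)
  expect_equal(order(sw$rows$ris_adjusted), ord)
})

test_that("a borderline effect splits the verdict across estimators", {
  # tuned near the boundary: some estimators cross, others do not
  rec <- generate_meta_dataset(simulation_spec(
    k = 9, theta = -0.35, tau2 = 0.12, p_control = 0.12,
    n_range = c(400L, 900L), seed = 2217))
  sw <- sweep_estimators(rec, tsa_config())
  expect_true(all(is.na(sw$rows$error)))
  expect_gt(length(unique(sw$rows$conclusion)), 1L)
  expect_false(sw$agreement)
  expect_true(length(sw$conclusive_estimators) >= 1L)
  expect_lt(length(sw$conclusive_estimators), 6L)
  # each row's verdict matches its own run_tsa output
  for (i in seq_len(nrow(sw$rows))) {
    cfg <- sw$config
    cfg$estimator <- sw$rows$estimator[i]
    expect_equal(sw$rows$conclusion[i], run_tsa(rec, cfg)$conclusion)
  }
})

test_that("per-estimator failures are recorded, not fatal", {
  rec <- toy_records()
  sw <- sweep_estimators(rec, tsa_config(), estimators = c("DL", "nope"))
  expect_true(is.na(sw$rows$error[1]))
  expect_false(is.na(sw$rows$error[2]))
  expect_true(is.na(sw$rows$tau2[2]))
})
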