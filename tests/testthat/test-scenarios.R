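# Scenario experiments: normalization helpers, envelope runs, and the
# protection orderings the model predicts for clinical situations.

test_that("percent normalization and mean centering behave as defined", {
  expect_equal(normalize_percent(1, 1), 0)
  expect_equal(normalize_percent(c(1.5, 0.5), 1), c(50, -50))
  expect_error(normalize_percent(c(1, 2), 0), class = "hpt_domain_error")
  expect_error(normalize_percent(c(1, 2), -1), class = "hpt_domain_error")
  expect_equal(mean_center(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(mean_center(rep(2.5, 4)), rep(0, 4))
  expect_error(mean_center(numeric(0)), class = "hpt_domain_error")
  set.seed(9)
  for (i in 1:100) {
    expect_lt(abs(mean(mean_center(runif(sample(2:20, 1), -5, 5)))), 1e-12)
  }
  # a perfect-homeostasis branch normalizes to (essentially) zero percent
  sw <- hpt_sweep("sys1", from = 0.3, to = 3, n = 20)
  pct <- normalize_percent(sw$branch$FT3, hpt_equilibrium("sys1")$state[["FT3"]])
  expect_lt(max(abs(pct)), 1e-4)
})

test_that("hypothyroid onset protects FT3 while FT4 declines", {
  res <- hpt_run_scenario("hypothyroid_onset", n_samples = 50)
  expect_true(res$ft3_protected)
  expect_lt(res$ft3_decline_low, res$ft4_decline_low)
  # FT3 stays in a narrow band relative to the k32 decline itself
  expect_lt(res$ft3_decline_low, 15)
  expect_gt(res$ft4_decline_low, 30)
  # envelopes are ordered pointwise
  with(res$ft3_envelope, {
    expect_true(all(min <= median & median <= max))
  })
})

test_that("non-thyroidal illness reverses the ordering: FT3 falls more than FT4", {
  res <- hpt_run_scenario("ntis", n_samples = 50)
  expect_false(res$ft3_protected)
  expect_gt(res$ft3_decline_low, res$ft4_decline_low)
  # FT3 sits far below the euthyroid reference across the whole sweep
  expect_true(all(res$normalized_ft3$median < -20))
})

test_that("the T3 drug is more FT3-protective at low k32 than the T4 drug", {
  run_drug <- function(drug3, drug4) {
    hpt_run_scenario(hpt_scenario_spec("drug",
                                       fixed = list(drug3 = drug3, drug4 = drug4)))
  }
  t3 <- run_drug(0.5, 0)
  t4 <- run_drug(0, 0.8)
  combo <- run_drug(0.3, 0.8)
  # with the T3 drug, FT3 never drops below its own euthyroid level as
  # k32 collapses; with the T4 drug (or the combination) it does
  expect_lte(t3$ft3_decline_low, 0)
  expect_gt(t4$ft3_decline_low, 0)
  expect_gt(combo$ft3_decline_low, 0)
  expect_lt(t3$ft3_decline_low, t4$ft3_decline_low)
  expect_lt(t3$ft3_decline_low, combo$ft3_decline_low)
  # and its FT3 branch is flatter over the sweep
  span <- function(r) {
    f <- r$ft3_envelope$median
    (max(f) - min(f)) / min(f)
  }
  expect_lt(span(t3), span(t4))
  expect_lt(span(t3), span(combo))
})

test_that("seasonality yields three flat FT3 branches at the printed levels", {
  res <- hpt_run_scenario("seasonality")
  for (col in c("min", "median", "max")) {
    branch <- res$ft3_envelope[[col]]
    expect_lt(max(branch) - min(branch), 1e-6)   # flat in k32
  }
  expect_equal(res$ft3_envelope$min[1], 1.2247, tolerance = 1e-4)
  expect_equal(res$ft3_envelope$median[1], 1.4142, tolerance = 1e-4)
  expect_equal(res$ft3_envelope$max[1], 1.5811, tolerance = 1e-4)
})

test_that("rising peripheral conversion disjoins FT3 and FT4", {
  pc <- hpt_peripheral_conversion(0, 1, 50)
  expect_true(all(diff(pc$FT3) > 0))
  expect_true(all(diff(pc$FT4) < 0))
  expect_error(hpt_peripheral_conversion(0, 0, 1), class = "hpt_usage_error")
  expect_error(hpt_peripheral_conversion(-0.5, 1), class = "hpt_usage_error")
  # at k43 = 0 the conversion term vanishes and sys9 collapses onto the
  # baseline network with the same k423
  eq1 <- hpt_equilibrium("sys1", hpt_parameters(k423 = 0.5))
  expect_equal(as.numeric(pc[1, c("TRH", "TSH", "FT4", "FT3")]),
               as.numeric(eq1$state), tolerance = 1e-8)
})

test_that("a reduced central drive shifts the de novo FT3 envelope down", {
  base <- hpt_run_scenario(hpt_scenario_spec("denovo_t3", n_samples = 40))
  low_s1 <- hpt_run_scenario(hpt_scenario_spec(
    "denovo_t3", ranges = list(k43 = c(0, 1), s1 = c(0.1, 0.5)),
    n_samples = 40))
  expect_true(all(low_s1$ft3_envelope$median < base$ft3_envelope$median))
  expect_true(all(low_s1$ft3_envelope$max < base$ft3_envelope$max))
})

test_that("scenario runs are reproducible given the seed", {
  a <- hpt_run_scenario(hpt_scenario_spec("hypothyroid_onset",
                                          n_samples = 10, seed = 77))
  b <- hpt_run_scenario(hpt_scenario_spec("hypothyroid_onset",
                                          n_samples = 10, seed = 77))
  expect_identical(a$ft3_envelope, b$ft3_envelope)
  expect_identical(a$normalized_ft4, b$normalized_ft4)
  c_ <- hpt_run_scenario(hpt_scenario_spec("hypothyroid_onset",
                                           n_samples = 10, seed = 78))
  expect_false(identical(a$ft3_envelope, c_$ft3_envelope))
})

test_that("scenario specifications are validated", {
  expect_error(hpt_scenario_spec("nope"), class = "hpt_lookup_error")
  expect_error(hpt_scenario_spec("ntis", ranges = list(s1 = c(0.8, 0.2))),
               class = "hpt_usage_error")
  expect_error(hpt_scenario_spec("ntis", ranges = list(s1 = c(0, 0.8))),
               class = "hpt_usage_error")
  expect_error(hpt_scenario_spec("seasonality", n_samples = 5),
               class = "hpt_usage_error")
})
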