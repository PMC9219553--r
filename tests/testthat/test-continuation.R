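# Natural-parameter continuation, stability along branches, and the
# homeostasis classification.

test_that("the baseline k32 sweep preserves FT3 homeostasis on a stable branch", {
  sw <- hpt_sweep("sys1", param = "k32", from = 0.3, to = 3, n = 50)
  expect_lt(sw$ft3_relative_span, 1e-8)
  expect_identical(sw$classification, "preserved")
  expect_true(sw$all_stable)
  st <- hpt_assess_stability(sw)
  expect_true(st$all_stable)
  expect_equal(nrow(st$failures), 0L)
  expect_true(all(sw$branch$residual < 1e-10))
})

test_that("removing the TSH feedforward onto FT3 gives the cube-root branch", {
  sw <- hpt_sweep("sys8", param = "k32", from = 0.3, to = 3, n = 50)
  expect_identical(sw$classification, "adapted")
  expect_equal(sw$branch$FT3[1], (2 * 0.3)^(1 / 3), tolerance = 1e-6)
  expect_equal(sw$branch$FT3[50], 6^(1 / 3), tolerance = 1e-6)
  # endpoints as printed-scale values
  expect_equal(sw$branch$FT3[1], 0.8434, tolerance = 1e-3)
  expect_equal(sw$branch$FT3[50], 1.8171, tolerance = 1e-3)
})

test_that("sweep preconditions are enforced", {
  expect_error(hpt_sweep("sys1", from = 1, to = 1, n = 2),
               class = "hpt_usage_error")
  expect_error(hpt_sweep("sys1", from = 3, to = 0.3), class = "hpt_usage_error")
  expect_error(hpt_sweep("sys1", from = 0, to = 3), class = "hpt_usage_error")
  expect_error(hpt_sweep("sys1", from = 0.3, to = 3, n = 1),
               class = "hpt_usage_error")
  expect_error(hpt_sweep("sys1", param = "k43", from = 0, to = 1),
               class = "hpt_param_error")  # k43 is not a sys1 constant
  # zero lower bound is legal for a pure production constant
  sw <- hpt_sweep("sys9", param = "k43", from = 0, to = 1, n = 5)
  expect_equal(sw$grid[1], 0)
})

test_that("branches of swept adaptation parameters stay stable", {
  for (args in list(list(v = "sys5", param = "k32"),
                    list(v = "sys9", param = "k43"))) {
    sw <- hpt_sweep(args$v, param = args$param,
                    from = 0.3, to = 3, n = 30)
    expect_true(sw$all_stable, label = args$v)
  }
})

test_that("sys10's FT3 branch is symmetric-minimal at k32 = 1 with a steeper left limb", {
  sw <- hpt_sweep("sys10", param = "k32", from = 0.3, to = 3, n = 28)
  ft3 <- sw$branch$FT3
  g <- sw$grid
  # strictly decreasing towards 1, strictly increasing beyond it
  expect_true(all(diff(ft3[g < 1 + 1e-9]) < 0))
  expect_true(all(diff(ft3[g > 1 - 1e-9]) > 0))
  # on the linear k32 scale the rise at the low end is the sharper one
  f <- function(k) equilibrium_ft3("sys10", k32 = k)
  expect_gt(f(0.3) - f(1), f(3) - f(1))
  # the branch is exactly symmetric under k32 -> 1/k32
  expect_equal(f(0.5), f(2), tolerance = 1e-10)
})

test_that("ascending and descending continuation land on the same branch", {
  up <- hpt_sweep("sys2", param = "k32", from = 0.3, to = 3, n = 25)
  # descending pass with manual warm starts
  guess <- NULL
  down <- matrix(NA_real_, 25, 4)
  for (i in 25:1) {
    p <- hpt_parameters(k32 = up$grid[i])
    eq <- hpt_equilibrium("sys2", p, guess = guess)
    down[i, ] <- eq$state
    guess <- eq$state
  }
  expect_equal(down[, 4], up$branch$FT3, tolerance = 1e-9)
  # no branch jumping: adjacent equilibria change smoothly
  expect_lt(max(abs(diff(up$branch$FT3))), 10 * stats::median(abs(diff(up$branch$FT3))))
})

test_that("the classification matrix separates homeostatic from adaptive variants", {
  preserved <- c("sys1", "sys4", "sys6", "sys12")
  adapted <- c("sys1mod", "sys2", "sys3", "sys5", "sys7", "sys8", "sys9", "sys10")
  for (id in preserved) {
    sw <- hpt_sweep(id, param = "k32", from = 0.3, to = 3, n = 25)
    expect_identical(hpt_classify_homeostasis(sw)$classification, "preserved")
  }
  for (id in adapted) {
    sw <- hpt_sweep(id, param = "k32", from = 0.3, to = 3, n = 25)
    cls <- hpt_classify_homeostasis(sw)
    expect_identical(cls$classification, "adapted")
    # sys10's compensatory de novo secretion damps (but does not remove)
    # the FT3 shift; the other broken-loop variants drift by >10%
    expect_gt(cls$ft3_relative_span, if (id == "sys10") 0.01 else 0.1)
  }
})
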