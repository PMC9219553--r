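# Printed equilibrium levels, closed-form and polynomial solutions, and
# the cross-checks between the three solution routes.

test_that("clamped-FT3 feedback shifts the homeostatic level to the printed values", {
  # sys4: FT3 = (sqrt(4c^2+1)+1)/(2c), printed 1.6180 / 2.4142 / 1.3874
  exact4 <- function(c_) (sqrt(4 * c_^2 + 1) + 1) / (2 * c_)
  for (c_ in c(1, 0.5, 1.5)) {
    ft3_root <- equilibrium_ft3("sys4", FT3_const = c_)
    ft3_closed <- hpt_analytic_ft3("sys4", hpt_parameters(FT3_const = c_))
    expect_equal(ft3_root, exact4(c_), tolerance = 1e-9)
    expect_equal(ft3_closed, exact4(c_), tolerance = 1e-12)
    # sys6 (clamp at the pituitary instead of the hypothalamus) prints
    # the same three numbers
    expect_equal(equilibrium_ft3("sys6", FT3_const = c_), exact4(c_),
                 tolerance = 1e-9)
    expect_equal(hpt_analytic_ft3("sys6", hpt_parameters(FT3_const = c_)),
                 exact4(c_), tolerance = 1e-12)
  }
  expect_equal(exact4(1), 1.6180, tolerance = 1e-4)
  expect_equal(exact4(0.5), 2.4142, tolerance = 1e-4)
  expect_equal(exact4(1.5), 1.3874, tolerance = 1e-4)
})

test_that("seasonal modulation scales equilibrium FT3 as sqrt(1 + ptTSH)", {
  for (pt in c(1, 0.5, 1.5)) {
    p <- hpt_parameters(ptTSH = pt)
    expect_equal(equilibrium_ft3("sys12", ptTSH = pt), sqrt(1 + pt),
                 tolerance = 1e-9)
    expect_equal(hpt_analytic_ft3("sys12", p), sqrt(1 + pt), tolerance = 1e-12)
  }
  # printed values: 1.4142, 1.2247, 1.5811
  expect_equal(sqrt(2), 1.4142, tolerance = 1e-4)
  expect_equal(sqrt(1.5), 1.2247, tolerance = 1e-4)
  expect_equal(sqrt(2.5), 1.5811, tolerance = 1e-4)
  # FT3(ptTSH)^2 is linear in ptTSH on a 5-point grid
  grid <- seq(0.25, 2, length.out = 5)
  ft3sq <- vapply(grid, function(pt) equilibrium_ft3("sys12", ptTSH = pt)^2,
                  numeric(1))
  fit <- lm(ft3sq ~ grid)
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("perfect homeostasis: FT3 is invariant to k32 and a3 in sys1/4/6/12", {
  for (id in c("sys1", "sys4", "sys6", "sys12")) {
    ft3_k <- vapply(c(0.3, 0.5, 1, 2, 3),
                    function(k) equilibrium_ft3(id, k32 = k), numeric(1))
    expect_lt((max(ft3_k) - min(ft3_k)) / min(ft3_k), 1e-8)
    ft3_a <- vapply(c(0.5, 1, 2),
                    function(a) equilibrium_ft3(id, a3 = a), numeric(1))
    expect_lt((max(ft3_a) - min(ft3_a)) / min(ft3_a), 1e-8)
  }
  # while FT3 is pinned, its precursor FT4 moves with k32
  eq1 <- hpt_equilibrium("sys1")
  eq3 <- hpt_equilibrium("sys1", hpt_parameters(k32 = 3))
  expect_equal(eq3$state[["FT3"]], eq1$state[["FT3"]], tolerance = 1e-9)
  expect_equal(eq3$state[["FT4"]] / eq1$state[["FT4"]], sqrt(3),
               tolerance = 1e-8)
})

test_that("homeostasis is lost when critical feedback/feedforward loops are cut", {
  for (id in c("sys1mod", "sys2", "sys3", "sys5", "sys7", "sys8")) {
    lo <- equilibrium_ft3(id, k32 = 0.3)
    hi <- equilibrium_ft3(id, k32 = 3)
    expect_gt(abs(hi - lo) / min(hi, lo), 0.1)
  }
  # sys8's cube-root law, exactly
  expect_equal(equilibrium_ft3("sys8"), 2^(1 / 3), tolerance = 1e-9)
  expect_equal(hpt_analytic_ft3("sys8", hpt_parameters(k32 = 2, base = hpt_default_parameters("sys8"))),
               4^(1 / 3), tolerance = 1e-12)
  # sys1mod's seventh-root law
  expect_equal(hpt_analytic_ft3("sys1mod", hpt_parameters(k32 = 2)),
               0.5^(1 / 7), tolerance = 1e-12)
})

test_that("polynomial solutions return the admissible root of the printed quartics", {
  # sys9 baseline: z^4 - 4z^2 - 2z + 4 has the admissible root z = 2
  expect_equal(hpt_polynomial_ft3("sys9"), 2, tolerance = 1e-10)
  # the quartics carry a second, spurious positive root from the squaring step
  all9 <- hpt_polynomial_ft3("sys9", return_all = TRUE)
  expect_equal(length(all9$positive_roots), 2L)
  # polynomial vs Newton across the validity grid
  for (k in c(0.3, 1, 3)) {
    for (id in c("sys2", "sys5", "sys7")) {
      p <- hpt_parameters(k32 = k, base = hpt_default_parameters(id))
      expect_equal(hpt_polynomial_ft3(id, p),
                   hpt_equilibrium(id, p)$state[["FT3"]], tolerance = 1e-8)
    }
    p3 <- hpt_parameters(k32 = k, FT3_const = 0.8, FT4_const = 1.2,
                         base = hpt_default_parameters("sys3"))
    expect_equal(hpt_polynomial_ft3("sys3", p3),
                 hpt_equilibrium("sys3", p3)$state[["FT3"]], tolerance = 1e-8)
  }
  for (a3 in c(0.5, 1, 2)) {
    for (id in c("sys9", "sys10")) {
      p <- hpt_parameters(a3 = a3, base = hpt_default_parameters(id))
      expect_equal(hpt_polynomial_ft3(id, p),
                   hpt_equilibrium(id, p)$state[["FT3"]], tolerance = 1e-8)
    }
  }
})

test_that("closed forms hold at general parameters, not only the unit baseline", {
  set.seed(31)
  for (id in c("sys1", "sys1mod", "sys4", "sys6", "sys8", "sys12")) {
    v <- hpt_system(id)
    for (rep in 1:5) {
      p <- random_params(id, v$required)
      expect_equal(hpt_analytic_ft3(id, p),
                   hpt_equilibrium(id, p)$state[["FT3"]],
                   tolerance = 1e-8, label = id)
    }
  }
})

test_that("solution routes are guarded outside their validity", {
  # printed polynomials require the non-free constants at 1
  expect_error(hpt_polynomial_ft3("sys2", hpt_parameters(s1 = 2)),
               "hpt_equilibrium", class = "hpt_poly_validity_error")
  expect_error(hpt_polynomial_ft3("sys9", hpt_parameters(k32 = 2, base = hpt_default_parameters("sys9"))),
               class = "hpt_poly_validity_error")
  # variants without the corresponding solution route refuse
  expect_error(hpt_analytic_ft3("sys2"), class = "hpt_unsupported_error")
  expect_error(hpt_polynomial_ft3("sys1"), class = "hpt_unsupported_error")
  expect_error(hpt_analytic_ft3("sys11"), class = "hpt_unsupported_error")
  expect_error(hpt_crosscheck("sys11"), class = "hpt_unsupported_error")
})

test_that("root finding and closed-form/polynomial routes cross-check", {
  for (id in setdiff(hpt_systems()$id, "sys11")) {
    cc <- hpt_crosscheck(id)
    expect_true(cc$pass, label = id)
    expect_lt(cc$max_discrepancy, 1e-7)
  }
  # baseline agreement is essentially exact
  expect_lt(hpt_crosscheck("sys1")$max_discrepancy, 1e-10)
  # sys8 at k32 = 2: both routes give 4^(1/3)
  cc8 <- hpt_crosscheck("sys8", hpt_parameters(k32 = 2, base = hpt_default_parameters("sys8")))
  expect_true(cc8$pass)
  expect_equal(unname(cc8$ft3["analytic"]), 4^(1 / 3), tolerance = 1e-10)
  # sys10 against the printed quartic
  cc10 <- hpt_crosscheck("sys10")
  expect_true(cc10$pass)
})

test_that("equilibria are stable with eigenvalues clear of the margin", {
  for (id in hpt_systems()$id) {
    eq <- hpt_equilibrium(id)
    expect_true(eq$stable, label = id)
    expect_lt(max(Re(eq$eigenvalues)), -1e-8)
    expect_lt(eq$residual, 1e-10)
    expect_true(all(eq$state > 0))
  }
})

test_that("the solver validates guesses and reports equilibrium metadata", {
  expect_error(hpt_equilibrium("sys1", guess = c(1, 1, -1, 1)),
               class = "hpt_domain_error")
  eq <- hpt_equilibrium("sys1")
  expect_identical(eq$method, "root-find")
  expect_identical(eq$variant_id, "sys1")
  expect_length(eq$eigenvalues, 4L)
})
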