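test_that("delta-G^2 is additive over chained restrictions", {
  tab <- table2()
  spec <- base_model_spec(rownames(tab))
  base <- fit_2ht(spec, tab, compute_se = FALSE)

  a_dp <- compare_2ht(spec, tab, "dP", base_fit = base, compute_se = FALSE)
  spec_dp <- a_dp$restricted_fit$spec
  b_g <- compare_2ht(spec_dp, tab, "g", base_fit = a_dp$restricted_fit,
                     compute_se = FALSE)
  both <- compare_2ht(spec, tab, list(eq_constraint("dP", spec$conditions),
                                      eq_constraint("g", spec$conditions)),
                      base_fit = base, compute_se = FALSE)
  expect_identical(both$delta_df, 2L)
  expect_lt(abs(both$delta_g_squared -
                  (a_dp$delta_g_squared + b_g$delta_g_squared)), 1e-6)
})

test_that("a restriction that already holds in truth yields a vanishing delta-G^2", {
  # expected counts generated with dP equal across conditions: the
  # asymptotic null case, where the extra restriction costs nothing
  spec <- base_model_spec(c("fyc", "control"))
  truth <- interior_params()
  truth[, "dP"] <- 0.45
  tab <- expected_table(spec, truth, n_cp = 2e5, n_ca = 2e5, round_counts = FALSE)
  cmp <- compare_2ht(spec, tab, "dP", compute_se = FALSE)
  expect_lt(cmp$delta_g_squared, 1e-4)
  expect_identical(cmp$delta_df, 1L)
})

test_that("non-nested or degenerate restrictions are rejected", {
  tab <- table1()
  spec <- base_model_spec(rownames(tab))
  # b is already equated in the base model
  expect_error(compare_2ht(spec, tab, "b"), "not nested")
  expect_error(compare_2ht(spec, tab, list()), "does not reduce")
})

test_that("base fits are reused, not recomputed, when supplied", {
  tab <- table1()
  spec <- base_model_spec(rownames(tab))
  base <- fit_2ht(spec, tab, compute_se = FALSE)
  cmp <- compare_2ht(spec, tab, "g", base_fit = base, compute_se = FALSE)
  expect_identical(cmp$base_fit, base)
  wrong_spec <- model_spec(spec$design, spec$conditions)
  wrong <- fit_2ht(wrong_spec, tab, compute_se = FALSE)
  expect_error(compare_2ht(spec, tab, "g", base_fit = wrong), "does not match")
})

test_that("the noncentrality solver matches a bisection oracle", {
  # independent bisection on the noncentral chi-square power equation
  crit <- qchisq(0.95, df = 1)
  lo <- 0; hi <- 100
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (pchisq(crit, df = 1, ncp = mid, lower.tail = FALSE) < 0.95) lo <- mid
    else hi <- mid
  }
  lambda_oracle <- (lo + hi) / 2
  expect_equal(lambda_oracle, 12.995, tolerance = 1e-4)

  w <- sensitivity_w(0.05, 0.95, n_total = 1420, df = 1)
  expect_equal(1420 * w^2, lambda_oracle, tolerance = 1e-6)
  # the solved w satisfies the power equation to high precision
  expect_lt(abs(power_of_test(0.05, 1420, 1, w) - 0.95), 1e-8)
})

test_that("sensitivity scales as 1/sqrt(n) and round-trips with power", {
  w1 <- sensitivity_w(0.05, 0.95, 1000, df = 1)
  w4 <- sensitivity_w(0.05, 0.95, 4000, df = 1)
  expect_equal(w4, w1 / 2, tolerance = 1e-12)

  expect_equal(power_of_test(0.05, 1420, 1, sensitivity_w(0.05, 0.95, 1420, 1)),
               0.95, tolerance = 1e-6)
  # central null: with no effect the rejection probability is alpha
  expect_equal(power_of_test(0.05, 500, 1, 0), 0.05, tolerance = 1e-12)
  # monotone in n and w
  expect_gt(power_of_test(0.05, 2000, 1, 0.1), power_of_test(0.05, 1000, 1, 0.1))
  expect_gt(power_of_test(0.05, 1000, 1, 0.2), power_of_test(0.05, 1000, 1, 0.1))
  expect_gt(sensitivity_w(0.05, 0.99, 1000, 1), sensitivity_w(0.05, 0.8, 1000, 1))

  expect_error(sensitivity_w(0.05, 0.04, 1000, 1), "exceed")
  expect_error(sensitivity_w(1.2, 0.9, 1000, 1), "alpha")
})

test_that("implied effect size vanishes under the null and grows with the difference", {
  spec <- base_model_spec(c("fyc", "control"))
  truth <- interior_params()
  truth[, "dP"] <- 0.45
  w0 <- implied_effect_size(spec, truth, "dP", n_cp = 355, n_ca = 355,
                            n_restarts = 3)
  expect_lt(w0, 1e-4)
  truth[, "dP"] <- c(0.35, 0.55)
  w1 <- implied_effect_size(spec, truth, "dP", n_cp = 355, n_ca = 355,
                            n_restarts = 3)
  expect_gt(w1, 0.05)
})
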