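test_that("the log-likelihood honours multinomial kernel conventions", {
  spec <- model_spec(lineup_design(6), "only")
  # all mass on rejections, all rejections observed: kernel is ln(1) * n
  tab <- response_table(matrix(c(0, 0, 40, 0, 0, 25), 1), conditions = "only")
  expect_identical(model_loglik(rep(0, 4), spec, tab), 0)
  # empty data contribute nothing
  empty <- suppressWarnings(
    response_table(matrix(0, 1, 6), conditions = "only"))
  expect_identical(model_loglik(c(0.3, 0.2, 0.1, 0.5), spec, empty), 0)
  # a zero-probability category with a positive count is a support violation
  tab2 <- response_table(matrix(c(10, 5, 5, 2, 3, 15), 1), conditions = "only")
  ll <- model_loglik(rep(0, 4), spec, tab2)
  expect_identical(as.numeric(ll), -Inf)
  expect_true(attr(ll, "support_violation"))
  # condition mismatch is an error
  expect_error(model_loglik(rep(0.5, 4), spec, table1()), "do not match")
})

test_that("fitting expected counts recovers the generating parameters", {
  spec <- base_model_spec(c("fyc", "control"))
  truth <- interior_params()
  tab <- expected_table(spec, truth, n_cp = 5e4, n_ca = 5e4)
  fit <- fit_2ht(spec, tab, compute_se = FALSE)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$estimates - truth)), 0.01)
  expect_lt(fit$g_squared, 0.01)
})

test_that("G^2 equals twice the log-likelihood gap to the saturated model", {
  tab <- table1()
  spec <- base_model_spec(rownames(tab))
  fit <- fit_2ht(spec, tab, compute_se = FALSE)
  lr <- 2 * (lineup2ht:::saturated_loglik(tab) - fit$loglik)
  expect_lt(abs(fit$g_squared - lr), 1e-8)
})

test_that("fits are invariant to condition order and count scaling", {
  tab <- table1()
  spec <- base_model_spec(c("fyc", "control"))
  fit <- fit_2ht(spec, tab, compute_se = FALSE)

  flipped <- response_table(lineup2ht:::flat_counts(tab)[2:1, ],
                            conditions = c("control", "fyc"))
  fit_flip <- fit_2ht(spec, flipped, compute_se = FALSE)
  expect_equal(fit_flip$estimates, fit$estimates, tolerance = 1e-6)
  expect_equal(fit_flip$g_squared, fit$g_squared, tolerance = 1e-8)

  tripled <- response_table(3L * lineup2ht:::flat_counts(tab),
                            conditions = rownames(tab))
  fit3 <- fit_2ht(spec, tripled, compute_se = FALSE)
  expect_equal(fit3$estimates, fit$estimates, tolerance = 1e-4)
})

test_that("EM and quasi-Newton routes agree on the fixture likelihoods", {
  for (tab in list(table1(), table2())) {
    spec <- base_model_spec(rownames(tab))
    em <- fit_2ht(spec, tab, method = "em", compute_se = FALSE)
    qn <- fit_2ht(spec, tab, method = "lbfgsb", compute_se = FALSE)
    expect_lt(abs(em$loglik - qn$loglik), 1e-6)
  }
})

test_that("a 2-D grid search attains the fitter's log-likelihood", {
  # two conditions; dP in condition 1 and a shared g free, everything else
  # fixed, so the likelihood surface is genuinely two-dimensional
  conds <- c("one", "two")
  spec <- model_spec(lineup_design(6), conds, restriction_map(
    fix_constraint("b", "one", 0.1), fix_constraint("b", "two", 0.1),
    fix_constraint("dA", "one", 0.2), fix_constraint("dA", "two", 0.2),
    fix_constraint("dP", "two", 0.5),
    eq_constraint("g", conds)
  ))
  expect_identical(spec$n_free, 2L)
  expect_identical(spec$free_names, c("dP[one]", "g"))
  sc <- generating_scenario(spec, expand_parameters(c(0.45, 0.55), spec),
                            n_cp = 80, n_ca = 80, seed = 31)
  tab <- simulate_responses(sc)
  fit <- fit_2ht(spec, tab, compute_se = FALSE)

  n <- lineup2ht:::flat_counts(tab)
  cc <- spec$design$suspect_constant
  grid <- seq(0, 1, by = 1e-3)
  # brute force: vectorised evaluation of the product-multinomial kernel
  # over the full (dP[one], g) grid
  ll <- matrix(0, length(grid), length(grid))
  for (k in 1:2) {
    dP <- if (k == 1L) matrix(grid, length(grid), length(grid)) else 0.5
    g <- matrix(grid, length(grid), length(grid), byrow = TRUE)
    p <- list(
      dP + (1 - dP) * (0.1 + 0.9 * g * cc),
      (1 - dP) * 0.9 * g * (1 - cc),
      (1 - dP) * 0.9 * (1 - g),
      0.8 * (0.1 + 0.9 * g * cc),
      0.8 * 0.9 * g * (1 - cc),
      0.2 + 0.8 * 0.9 * (1 - g)
    )
    for (j in 1:6) {
      if (n[k, j] > 0) ll <- ll + n[k, j] * log(p[[j]])
    }
  }
  expect_lt(abs(max(ll) - fit$loglik), 1e-4)
  expect_gte(fit$loglik + 1e-6, max(ll[is.finite(ll)]))
})

test_that("standard errors match the binomial closed form", {
  # only dP free in a single condition with b = g = 0: the culprit-present
  # tree is Bernoulli(dP) over identification vs rejection
  spec <- model_spec(lineup_design(6), "only", restriction_map(
    fix_constraint("b", "only", 0), fix_constraint("g", "only", 0),
    fix_constraint("dA", "only", 1)
  ))
  k <- 37; n <- 120
  tab <- response_table(matrix(c(k, 0, n - k, 0, 0, 55), 1), conditions = "only")
  fit <- fit_2ht(spec, tab)
  theta <- k / n
  expect_equal(unname(fit$free_estimates["dP"]), theta, tolerance = 1e-6)
  expect_equal(unname(fit$se["dP"]), sqrt(theta * (1 - theta) / n),
               tolerance = 1e-5)
})

test_that("doubling every count shrinks standard errors by 1/sqrt(2)", {
  tab <- table1()
  spec <- base_model_spec(rownames(tab))
  fit1 <- fit_2ht(spec, tab)
  tab2 <- response_table(2L * lineup2ht:::flat_counts(tab),
                         conditions = rownames(tab))
  fit2 <- fit_2ht(spec, tab2)
  expect_equal(unname(fit2$se / fit1$se), rep(1 / sqrt(2), 6), tolerance = 1e-6)
})

test_that("expected counts conserve tree totals and saturate with 0 df", {
  tab <- table1()
  spec <- base_model_spec(rownames(tab))
  fit <- fit_2ht(spec, tab, compute_se = FALSE)
  ec <- expected_counts(fit)
  expect_equal(apply(ec, c(1, 2), sum), apply(unclass(tab), c(1, 2), sum) + 0,
               tolerance = 1e-9)
  expect_equal(sum(ec["fyc", "culprit_present", ]), 158, tolerance = 1e-9)

  # saturated model on on-manifold data reproduces the data exactly
  sat <- model_spec(lineup_design(6), c("fyc", "control"))
  gen <- expected_table(sat, interior_params(), n_cp = 500, n_ca = 400,
                        round_counts = FALSE)
  sfit <- fit_2ht(sat, gen, compute_se = FALSE)
  expect_identical(sfit$df, 0L)
  expect_lt(max(abs(expected_counts(sfit) - unclass(gen))), 1e-3)
  expect_lt(sfit$g_squared, 1e-8)
})

test_that("boundary estimates are flagged and non-convergence is reported, not thrown", {
  tab <- table1()
  spec <- base_model_spec(rownames(tab))
  fit <- fit_2ht(spec, tab, compute_se = FALSE)
  expect_identical(fit$boundary, "b")

  starved <- fit_2ht(spec, tab, max_iter = 1L, n_restarts = 1L, compute_se = FALSE)
  expect_false(starved$converged)
  expect_identical(starved$n_iter, 1L)
})
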