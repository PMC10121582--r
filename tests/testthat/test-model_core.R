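test_that("lineup_design applies the rounded and exact suspect-constant conventions", {
  d <- lineup_design(6)
  expect_identical(d$suspect_constant, 0.16667)
  expect_identical(lineup_design(6, mode = "exact")$suspect_constant, 1 / 6)
  expect_identical(lineup_design(8, mode = "exact")$suspect_constant, 1 / 8)
  expect_error(lineup_design(1), "integer >= 2")
  expect_error(lineup_design(2.5), "integer >= 2")
})

test_that("category probabilities reproduce the tree's closed-form special cases", {
  d <- lineup_design(6, mode = "exact")
  # certain culprit detection: the culprit is always identified
  p <- category_probabilities(c(dP = 1, dA = 0.3, b = 0.2, g = 0.7), d)
  expect_equal(unname(p["culprit_present", ]), c(1, 0, 0))
  # pure guessing splits identifications by the lineup-size constant
  p <- category_probabilities(c(dP = 0, dA = 0, b = 0, g = 1), d)
  expect_equal(unname(p["culprit_present", ]), c(1 / 6, 5 / 6, 0))
  # no detection and no selection process: every lineup is rejected
  p <- category_probabilities(c(dP = 0, dA = 0, b = 0, g = 0), d)
  expect_equal(p["culprit_present", "rejection"], 1)
  expect_equal(p["culprit_absent", "rejection"], 1)
  # biased selection alone drives culprit-absent outcomes
  p <- category_probabilities(c(dP = 0, dA = 0, b = 0.5, g = 0), lineup_design(6))
  expect_equal(unname(p["culprit_absent", ]), c(0.5, 0, 0.5))
})

test_that("out-of-range parameters are rejected by name", {
  d <- lineup_design(6)
  expect_error(category_probabilities(c(dP = 0.5, dA = 0.1, b = -0.01, g = 0.5), d),
               "`b` is outside")
  expect_error(category_probabilities(c(dP = 1.2, dA = 0.1, b = 0, g = 0.5), d),
               "`dP` is outside")
})

test_that("category probabilities normalise and stay non-negative over the cube", {
  set.seed(101)
  n <- 1e6
  pars <- cbind(dP = runif(n), dA = runif(n), b = runif(n), g = runif(n))
  pr <- lineup2ht:::tree_probs(pars[, "dP"], pars[, "dA"], pars[, "b"], pars[, "g"],
                               0.16667)
  expect_true(all(pr >= 0))
  expect_lt(max(abs(rowSums(pr[, 1:3]) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(pr[, 4:6]) - 1)), 1e-12)
})

test_that("rounded and exact suspect constants give nearly identical probabilities", {
  set.seed(202)
  pars <- cbind(dP = runif(2e4), dA = runif(2e4), b = runif(2e4), g = runif(2e4))
  a <- lineup2ht:::tree_probs(pars[, 1], pars[, 2], pars[, 3], pars[, 4], 0.16667)
  b <- lineup2ht:::tree_probs(pars[, 1], pars[, 2], pars[, 3], pars[, 4], 1 / 6)
  # the constant enters multiplied by factors bounded by 1
  expect_lt(max(abs(a - b)), 4e-5)
})

test_that("the culprit-identification probability is monotone in dP, b and g", {
  d <- lineup_design(6)
  grid <- seq(0, 1, by = 0.05)
  base <- c(dP = 0.3, dA = 0.2, b = 0.2, g = 0.4)
  for (p in c("dP", "b", "g")) {
    vals <- vapply(grid, function(v) {
      par <- base; par[p] <- v
      category_probabilities(par, d)["culprit_present", "suspect"]
    }, numeric(1))
    expect_true(all(diff(vals) >= -1e-12), info = p)
  }
})

test_that("the two-condition base model has 6 free parameters and 2 df", {
  spec <- base_model_spec(c("fyc", "control"))
  expect_identical(spec$n_free, 6L)
  expect_identical(spec$df, 2L)
  expect_identical(spec$free_names,
                   c("dP[fyc]", "dP[control]", "g[fyc]", "g[control]", "b", "dA"))
})

test_that("expand/pack realise restrictions and round-trip", {
  d <- lineup_design(6)
  conds <- c("a", "b")
  # no restrictions: 8 free values map one-to-one
  sat <- model_spec(d, conds)
  expect_identical(sat$n_free, 8L)
  expect_identical(sat$df, 0L)
  free <- seq(0.1, 0.8, by = 0.1)
  par <- expand_parameters(free, sat)
  expect_equal(unname(pack_parameters(par, sat)), free)

  # base restrictions: 6 free values expand to 8 instances
  spec <- base_model_spec(conds)
  free6 <- c(0.4, 0.5, 0.3, 0.6, 0.05, 0.15)
  par <- expand_parameters(free6, spec)
  expect_equal(par["a", "b"], par["b", "b"])
  expect_equal(par["a", "dA"], par["b", "dA"])
  expect_equal(unname(pack_parameters(par, spec)), free6)

  # fixing a parameter pins it regardless of the free vector
  fx <- model_spec(d, conds, restriction_map(fix_constraint("b", "a", 0)))
  expect_identical(fx$n_free, 7L)
  par <- expand_parameters(runif(7), fx)
  expect_identical(par["a", "b"], 0)

  expect_error(expand_parameters(c(0.1, 0.2), spec), "length 2, expected 6")
  bad <- expand_parameters(free6, spec)
  bad["a", "dA"] <- 0.99
  expect_error(pack_parameters(bad, spec), "equality restriction")
})

test_that("a parameter instance cannot be restricted twice", {
  conds <- c("a", "b")
  expect_error(
    restriction_map(eq_constraint("b", conds), fix_constraint("b", "a", 0)),
    "more than one constraint"
  )
})

test_that("model specs round-trip through YAML and JSON configs", {
  spec <- base_model_spec(c("fyc", "control"))
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_model_spec(spec, path)
    back <- read_model_spec(path)
    expect_identical(back$free_names, spec$free_names)
    expect_identical(back$conditions, spec$conditions)
    expect_identical(back$design$suspect_constant, spec$design$suspect_constant)
  }
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(
    model_spec(lineup_design(6), c("x", "y"),
               restriction_map(fix_constraint("b", "x", 0.25))), path)
  expect_identical(read_model_spec(path)$fixed["x", "b"], 0.25)
})
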