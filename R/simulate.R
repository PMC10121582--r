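#' Define a data-generating scenario
#'
#' Bundles a model spec, true parameter values satisfying its restrictions,
#' per-condition sample sizes and a seed into a reproducible generator of
#' synthetic response tables.  Per condition, culprit-present and
#' culprit-absent decisions are independent multinomial draws from the
#' model's category probabilities — the same product-multinomial structure
#' the likelihood assumes (decision-level simulation; participant-level
#' dependence is not modelled).
#'
#' @param spec An `ht_model_spec`.
#' @param true_params `K x 4` parameter matrix (columns `dP`, `dA`, `b`,
#'   `g`) satisfying `spec`'s restrictions, or a free vector of length
#'   `spec$n_free`.
#' @param n_cp,n_ca Culprit-present / culprit-absent decisions per condition
#'   (scalar or per-condition vector, all >= 1).
#' @param seed Integer seed (recorded in outputs).
#' @return An object of class `ht_scenario`.
#' @seealso [replication_scenario()] for the default two-condition scenario.
#' @export
generating_scenario <- function(spec, true_params, n_cp, n_ca, seed = 1L) {
  stopifnot(inherits(spec, "ht_model_spec"))
  K <- length(spec$conditions)
  if (is.null(dim(true_params))) true_params <- expand_parameters(true_params, spec)
  if (is.null(colnames(true_params))) colnames(true_params) <- PARAM_NAMES
  true_params <- true_params[, PARAM_NAMES, drop = FALSE]
  rownames(true_params) <- spec$conditions
  pack_parameters(true_params, spec)   # validates the restrictions hold
  if (any(true_params < 0 | true_params > 1)) {
    stop("true parameters must lie in [0, 1]", call. = FALSE)
  }
  n_cp <- rep_len(as.integer(n_cp), K)
  n_ca <- rep_len(as.integer(n_ca), K)
  if (any(n_cp < 1) || any(n_ca < 1)) stop("sample sizes must be >= 1", call. = FALSE)
  structure(
    list(spec = spec, true_params = true_params, n_cp = n_cp, n_ca = n_ca,
         seed = as.integer(seed)),
    class = "ht_scenario"
  )
}

#' The default replication-style scenario
#'
#' A two-condition scenario mirroring the conceptual-replication design:
#' six-person lineups, the base model (`b`, `dA` equated across conditions),
#' equal culprit-present and culprit-absent decision counts per condition,
#' and a `g` difference between conditions with `dP`, `b`, `dA` shared in
#' truth or not according to the fitted values.  The generating parameters
#' are the full-precision maximum-likelihood estimates obtained by fitting
#' the bundled replication table — computed at call time, not hard-coded.
#'
#' @param seed Integer seed for the scenario.
#' @param equalize Optional parameter name(s) (`"dP"`, `"g"`, ...) to equate
#'   across conditions in the generating truth: the truth is then taken from
#'   the correspondingly restricted fit, which makes the scenario an exact
#'   null for the matching ΔG² test.
#' @return An `ht_scenario`.
#' @export
replication_scenario <- function(seed = 1L, equalize = NULL) {
  tab <- lineup_fixture("replication")
  spec <- base_model_spec(rownames(tab))
  fit_spec <- spec
  if (!is.null(equalize)) {
    cons <- lapply(equalize, eq_constraint, conditions = spec$conditions)
    fit_spec <- model_spec(spec$design, spec$conditions,
                           restriction_map(c(unclass(spec$restrictions), cons)))
  }
  fit <- fit_2ht(fit_spec, tab, compute_se = FALSE)
  n <- flat_counts(tab)
  # the truth satisfies the (possibly extra-restricted) generating model but
  # the scenario carries the base spec, so ΔG² tests of `equalize` are nested
  generating_scenario(spec, fit$estimates,
                      n_cp = rowSums(n[, 1:3]), n_ca = rowSums(n[, 4:6]),
                      seed = seed)
}

#' Simulate a response table from a scenario
#'
#' One multinomial draw per condition and lineup type.  Uses R's Mersenne
#' Twister stream seeded from `seed`; identical seeds give identical tables.
#'
#' @param scenario An [generating_scenario()].
#' @param seed Seed override (defaults to the scenario's seed).
#' @return A [response_table()] with the scenario's condition labels.
#' @examples
#' sc <- generating_scenario(
#'   base_model_spec(), rbind(c(0.3, 0.1, 0, 0.5), c(0.3, 0.1, 0, 0.7)),
#'   n_cp = 300, n_ca = 300, seed = 42
#' )
#' simulate_responses(sc)
#' @export
simulate_responses <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "ht_scenario"))
  set.seed(as.integer(seed))
  p <- tree_probs(scenario$true_params[, "dP"], scenario$true_params[, "dA"],
                  scenario$true_params[, "b"], scenario$true_params[, "g"],
                  scenario$spec$design$suspect_constant)
  K <- length(scenario$spec$conditions)
  counts <- matrix(0L, K, 6L)
  for (k in seq_len(K)) {
    counts[k, 1:3] <- stats::rmultinom(1L, scenario$n_cp[k], p[k, 1:3])
    counts[k, 4:6] <- stats::rmultinom(1L, scenario$n_ca[k], p[k, 4:6])
  }
  response_table(counts, conditions = scenario$spec$conditions,
                 lineup_size = scenario$spec$design$lineup_size,
                 experiment = sprintf("simulated (seed %d)", as.integer(seed)))
}

#' Parameter-recovery and test-calibration experiment
#'
#' Repeatedly simulates from a scenario, refits the scenario's model, and
#' (optionally) runs nested ΔG² tests on each simulated table.  Summarises
#' per-free-parameter bias, RMSE and the fraction of boundary estimates, and
#' per-test rejection rates — the standard validation loop for multinomial
#' processing tree analyses (type-I error calibration when the truth
#' satisfies the tested restriction, power otherwise).
#'
#' Replicate `i` uses seed `scenario$seed + i`, so experiments are
#' reproducible and seed blocks are disjoint across scenarios whose seeds
#' differ by more than `n_replicates`.  Unconverged replicates are excluded
#' from the summaries and counted.
#'
#' @param scenario An [generating_scenario()].
#' @param n_replicates Number of simulated datasets (>= 2).
#' @param tests Optional named list of restrictions (as in [compare_2ht()])
#'   whose rejection rates at `alpha` are tracked.
#' @param alpha Significance level for the tracked tests.
#' @param fit_args List of arguments passed to [fit_2ht()] (e.g.
#'   `list(method = "lbfgsb", n_restarts = 2)` to speed up large runs).
#' @return An object of class `ht_recovery`: a list with `parameters` (data
#'   frame: truth, mean estimate, bias, RMSE, boundary fraction, Monte-Carlo
#'   SE), `rejection_rates`, `n_replicates`, `n_unconverged`, `alpha`,
#'   `seed`.
#' @export
recovery_experiment <- function(scenario, n_replicates, tests = NULL,
                                alpha = 0.05, fit_args = list()) {
  stopifnot(inherits(scenario, "ht_scenario"))
  if (n_replicates < 2L) stop("`n_replicates` must be at least 2", call. = FALSE)
  n_replicates <- as.integer(n_replicates)
  spec <- scenario$spec
  truth <- pack_parameters(scenario$true_params, spec)
  fit_args$compute_se <- FALSE
  est <- matrix(NA_real_, n_replicates, spec$n_free)
  n_boundary <- 0L
  rejected <- matrix(NA, n_replicates, length(tests))
  converged <- logical(n_replicates)
  for (i in seq_len(n_replicates)) {
    tab <- simulate_responses(scenario, seed = scenario$seed + i)
    fit <- do.call(fit_2ht, c(list(spec = spec, data = tab), fit_args))
    converged[i] <- fit$converged
    if (!fit$converged) next
    est[i, ] <- fit$free_estimates
    if (length(fit$boundary) > 0L) n_boundary <- n_boundary + 1L
    for (j in seq_along(tests)) {
      cmp <- do.call(compare_2ht,
                     c(list(spec = spec, data = tab, restriction = tests[[j]],
                            base_fit = fit, alpha = alpha), fit_args))
      rejected[i, j] <- cmp$p_value < alpha
    }
  }
  keep <- converged
  m <- colMeans(est[keep, , drop = FALSE])
  param_summary <- data.frame(
    parameter = spec$free_names,
    truth = as.numeric(truth),
    mean_estimate = m,
    bias = m - as.numeric(truth),
    rmse = sqrt(colMeans((est[keep, , drop = FALSE] -
                            rep(truth, each = sum(keep)))^2)),
    mc_se = apply(est[keep, , drop = FALSE], 2L, stats::sd) / sqrt(sum(keep)),
    row.names = NULL
  )
  rates <- if (length(tests) > 0L) {
    stats::setNames(colMeans(rejected[keep, , drop = FALSE]),
                    names(tests) %||% paste0("test", seq_along(tests)))
  } else NULL
  structure(
    list(parameters = param_summary, rejection_rates = rates,
         boundary_fraction = n_boundary / max(sum(keep), 1L),
         n_replicates = n_replicates, n_used = sum(keep),
         n_unconverged = sum(!keep), alpha = alpha, seed = scenario$seed,
         low_precision = n_replicates < 50L),
    class = "ht_recovery"
  )
}

#' @export
print.ht_recovery <- function(x, ...) {
  cat(sprintf("<ht_recovery> %d replicates (%d used, %d unconverged), seed %d\n",
              x$n_replicates, x$n_used, x$n_unconverged, x$seed))
  if (x$low_precision) {
    cat("note: few replicates; summaries carry wide Monte-Carlo uncertainty\n")
  }
  print(cbind(x$parameters[1L],
              round(x$parameters[-1L], 4)))
  cat(sprintf("boundary-estimate fraction: %.3f\n", x$boundary_fraction))
  if (!is.null(x$rejection_rates)) {
    cat(sprintf("rejection rates at alpha = %g:\n", x$alpha))
    print(round(x$rejection_rates, 4))
  }
  invisible(x)
}
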