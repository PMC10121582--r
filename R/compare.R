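#' Likelihood-ratio test of a nested parameter restriction
#'
#' Fits the base model and the base model augmented with additional
#' constraints, and tests the restriction with the difference of the two
#' goodness-of-fit statistics, `ΔG² = G²(restricted) - G²(base)`, referred
#' to a chi-square distribution with `Δdf` degrees of freedom.  A
#' significant result means the restricted model fits significantly worse,
#' i.e. the restriction does not hold.
#'
#' The restricted model is constructed from the base spec plus
#' `restriction`, so it is nested by construction; a constraint that clashes
#' with an existing one (the parameter instance is already restricted) is an
#' error.  Tiny negative `ΔG²` from numerical noise is clamped to 0 (with a
#' warning below `-1e-6`).
#'
#' @param spec Base `ht_model_spec`.
#' @param data A [response_table()].
#' @param restriction A single constraint, a list of constraints, or a
#'   [restriction_map()] to add to the base model.  As a convenience, a bare
#'   parameter name (`"dP"`, `"g"`, ...) equates that parameter across all of
#'   the spec's conditions.
#' @param base_fit Optional already-computed base fit to reuse (must match
#'   `spec` and `data`).
#' @param alpha Significance level used for the printed decision only.
#' @param ... Passed to [fit_2ht()] for both fits.
#'
#' @return An object of class `ht_comparison`: `delta_g_squared`,
#'   `delta_df`, `p_value`, `base_fit`, `restricted_fit`,
#'   `restriction_description`, `alpha`.
#'
#' @examples
#' tab <- lineup_fixture("horry_reanalysis")
#' compare_2ht(base_model_spec(rownames(tab)), tab, "g")
#' @export
compare_2ht <- function(spec, data, restriction, base_fit = NULL, alpha = 0.05, ...) {
  stopifnot(inherits(spec, "ht_model_spec"))
  if (is.character(restriction) && length(restriction) == 1L) {
    restriction <- eq_constraint(restriction, spec$conditions)
  }
  if (inherits(restriction, "ht_constraint")) restriction <- list(restriction)
  restricted_map <- tryCatch(
    restriction_map(c(unclass(spec$restrictions), unclass(restriction))),
    error = function(e) {
      stop(sprintf("restriction is not nested in the base model: %s",
                   conditionMessage(e)), call. = FALSE)
    }
  )
  rspec <- model_spec(spec$design, spec$conditions, restricted_map)
  if (rspec$n_free >= spec$n_free) {
    stop("restriction does not reduce the number of free parameters", call. = FALSE)
  }
  if (is.null(base_fit)) {
    base_fit <- fit_2ht(spec, data, ...)
  } else {
    stopifnot(inherits(base_fit, "ht_fit"))
    if (!identical(base_fit$spec$free_names, spec$free_names) ||
        !identical(unclass(base_fit$data), unclass(align_data(spec, data)))) {
      stop("`base_fit` does not match `spec` and `data`", call. = FALSE)
    }
  }
  restricted_fit <- fit_2ht(rspec, data, ...)

  dg <- restricted_fit$g_squared - base_fit$g_squared
  if (dg < -1e-6) {
    warning(sprintf("restricted fit better than base fit (dG^2 = %.2e); clamped to 0", dg))
  }
  dg <- max(dg, 0)
  ddf <- restricted_fit$df - base_fit$df
  structure(
    list(delta_g_squared = dg, delta_df = ddf,
         p_value = stats::pchisq(dg, df = ddf, lower.tail = FALSE),
         base_fit = base_fit, restricted_fit = restricted_fit,
         restriction_description = paste(
           vapply(restriction, format_constraint, character(1L)), collapse = "; "),
         converged = base_fit$converged && restricted_fit$converged,
         alpha = alpha),
    class = "ht_comparison"
  )
}

#' @export
print.ht_comparison <- function(x, ...) {
  cat("<ht_comparison> nested likelihood-ratio test\n")
  cat("restriction:", x$restriction_description, "\n")
  cat(sprintf("dG^2(%d) = %.2f, p = %.3f -> %s at alpha = %g%s\n",
              x$delta_df, x$delta_g_squared, x$p_value,
              if (x$p_value < x$alpha) "reject the restriction"
              else "retain the restriction", x$alpha,
              if (x$converged) "" else "  ** a fit did not converge **"))
  invisible(x)
}

# ---- power / sensitivity ---------------------------------------------------

# noncentrality at which the chi-square LR test attains `power`
solve_noncentrality <- function(alpha, power, df) {
  crit <- stats::qchisq(1 - alpha, df = df)
  f <- function(l) stats::pchisq(crit, df = df, ncp = l, lower.tail = FALSE) - power
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}

#' Minimal detectable effect size (Cohen's w) of the likelihood-ratio test
#'
#' Solves the noncentral chi-square power equation for the noncentrality
#' `λ*` at which the test with significance level `alpha` and `df` degrees
#' of freedom reaches the target power, and converts it to Cohen's effect
#' size `w = sqrt(λ* / n_total)`.  `n_total` counts identification
#' decisions (participants times lineups per participant).
#'
#' @param alpha Significance level in (0, 1).
#' @param power Target power in (0, 1); must exceed `alpha`.
#' @param n_total Total number of identification decisions (>= 1).
#' @param df Degrees of freedom of the test (default 1, a single-parameter
#'   restriction).
#' @return The minimal detectable Cohen's `w`.
#'
#' @examples
#' # 355 participants x 4 decisions, alpha = beta = 0.05
#' sensitivity_w(0.05, 0.95, 355 * 4, df = 1)  # ~0.10
#' @export
sensitivity_w <- function(alpha, power, n_total, df = 1L) {
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (!(power > 0 && power < 1)) stop("`power` must be in (0, 1)", call. = FALSE)
  if (power <= alpha) stop("`power` must exceed `alpha`", call. = FALSE)
  if (n_total < 1) stop("`n_total` must be at least 1", call. = FALSE)
  if (df < 1) stop("`df` must be at least 1", call. = FALSE)
  sqrt(solve_noncentrality(alpha, power, df) / n_total)
}

#' Power of the likelihood-ratio test at a given effect size
#'
#' Inverse of [sensitivity_w()]: the upper-`alpha`-tail mass of the
#' noncentral chi-square distribution with noncentrality
#' `λ = n_total * w^2` beyond the central critical value.
#'
#' @inheritParams sensitivity_w
#' @param w Cohen's effect size (>= 0); `w = 0` returns `alpha` exactly.
#' @return Power in `[alpha, 1)`.
#' @export
power_of_test <- function(alpha, n_total, df, w) {
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (w < 0) stop("`w` must be non-negative", call. = FALSE)
  crit <- stats::qchisq(1 - alpha, df = df)
  stats::pchisq(crit, df = df, ncp = n_total * w^2, lower.tail = FALSE)
}

#' Effect size implied by a parameter difference
#'
#' Cohen's `w` of a nested restriction under hypothetical true parameters:
#' expected category probabilities are computed under `true_params`
#' (the alternative), the restricted model is fitted to the corresponding
#' expected counts (the best-fitting null), and
#' `w = sqrt(G²(restricted on expected data) / n_total)` — so
#' `n_total * w²` is the noncentrality of the ΔG² test at these cell sizes.
#'
#' @param spec Base `ht_model_spec` that `true_params` satisfies.
#' @param true_params `K x 4` parameter matrix (alternative hypothesis).
#' @param restriction Constraint(s) to test, as in [compare_2ht()].
#' @param n_cp,n_ca Decisions per condition in culprit-present /
#'   culprit-absent lineups (scalars or per-condition vectors).
#' @param ... Passed to [fit_2ht()] for the null fit.
#' @return Cohen's `w` (non-negative scalar).
#' @export
implied_effect_size <- function(spec, true_params, restriction, n_cp, n_ca, ...) {
  stopifnot(inherits(spec, "ht_model_spec"))
  K <- length(spec$conditions)
  n_cp <- rep_len(n_cp, K); n_ca <- rep_len(n_ca, K)
  if (is.null(colnames(true_params))) colnames(true_params) <- PARAM_NAMES
  true_params <- true_params[, PARAM_NAMES, drop = FALSE]
  pack_parameters(true_params, spec)   # errors if restrictions violated
  p <- tree_probs(true_params[, "dP"], true_params[, "dA"],
                  true_params[, "b"], true_params[, "g"],
                  spec$design$suspect_constant)
  expected <- cbind(n_cp * p[, 1:3, drop = FALSE], n_ca * p[, 4:6, drop = FALSE])
  tab <- response_table(expected, conditions = spec$conditions,
                        lineup_size = spec$design$lineup_size,
                        experiment = "expected", check_integer = FALSE)
  if (is.character(restriction) && length(restriction) == 1L) {
    restriction <- list(eq_constraint(restriction, spec$conditions))
  }
  if (inherits(restriction, "ht_constraint")) restriction <- list(restriction)
  rspec <- model_spec(spec$design, spec$conditions,
                      restriction_map(c(unclass(spec$restrictions), unclass(restriction))))
  null_fit <- fit_2ht(rspec, tab, compute_se = FALSE, ...)
  base_fit <- fit_2ht(spec, tab, compute_se = FALSE, ...)
  dg <- max(null_fit$g_squared - base_fit$g_squared, 0)
  sqrt(dg / sum(n_cp + n_ca))
}
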