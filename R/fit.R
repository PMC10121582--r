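# ---- likelihood ------------------------------------------------------------

# category probabilities as a K x 6 matrix in flat_counts() order,
# unvalidated (used in hot loops and for numerical derivatives)
prob_matrix <- function(free, spec) {
  par <- expand_parameters(free, spec)
  tree_probs(par[, "dP"], par[, "dA"], par[, "b"], par[, "g"],
             spec$design$suspect_constant)
}

#' Product-multinomial log-likelihood of the 2-HT model
#'
#' The multinomial kernel `sum(count * log(probability))` over all
#' conditions, lineup types and outcome categories, with the convention that
#' a category with probability 0 and count 0 contributes 0.  A category with
#' probability 0 but a positive count makes the data impossible under the
#' parameters: the function returns `-Inf` with attribute
#' `support_violation = TRUE`.
#'
#' @param free Free-parameter vector for `spec` (values in `[0, 1]`).
#' @param spec An `ht_model_spec`.
#' @param data A [response_table()] whose conditions match `spec$conditions`.
#' @return The log-likelihood (a scalar; `-Inf` on support violation).
#' @export
model_loglik <- function(free, spec, data) {
  data <- align_data(spec, data)
  n <- flat_counts(data)
  p <- prob_matrix(free, spec)
  pos <- n > 0
  if (any(p[pos] <= 0)) {
    return(structure(-Inf, support_violation = TRUE))
  }
  sum(n[pos] * log(p[pos]))
}

# reorder data conditions to spec order; error on mismatch
align_data <- function(spec, data) {
  stopifnot(inherits(data, "response_table"))
  conds <- dimnames(data)[[1L]]
  if (length(conds) != length(spec$conditions) ||
      !setequal(conds, spec$conditions)) {
    stop("data conditions do not match the model's conditions", call. = FALSE)
  }
  if (identical(conds, spec$conditions)) data
  else {
    out <- unclass(data)[spec$conditions, , , drop = FALSE]
    response_table(out, conditions = spec$conditions,
                   lineup_size = attr(data, "lineup_size"),
                   experiment = attr(data, "experiment"),
                   check_integer = FALSE)
  }
}

# log-likelihood of the saturated product-multinomial model
saturated_loglik <- function(data) {
  n <- flat_counts(data)
  ll <- 0
  for (t in c(1L, 4L)) {
    cnt <- n[, t:(t + 2L), drop = FALSE]
    tot <- rowSums(cnt)
    pos <- cnt > 0
    ll <- ll + sum(cnt[pos] * log((cnt / tot)[pos]))
  }
  ll
}

# ---- EM --------------------------------------------------------------------

# One EM pass for the 2-HT trees.  The E-step distributes each observed
# category count over the latent branches consistent with it in proportion
# to the branch probabilities; the M-step sets each free parameter to the
# ratio of expected traversals of its "success" branches over expected
# visits to its node, pooled across the conditions an equality class spans.
em_step <- function(free, spec, n, cc) {
  par <- expand_parameters(free, spec)
  dP <- par[, "dP"]; dA <- par[, "dA"]; b <- par[, "b"]; g <- par[, "g"]
  # branch probabilities (per condition)
  cp1 <- dP                                  # detect culprit -> culprit ID
  cp2 <- (1 - dP) * b                        # biased selection -> culprit ID
  cp3 <- (1 - dP) * (1 - b) * g * cc         # guess suspect   -> culprit ID
  cp4 <- (1 - dP) * (1 - b) * g * (1 - cc)   # guess filler    -> filler ID
  cp5 <- (1 - dP) * (1 - b) * (1 - g)        # no selection    -> rejection
  ca1 <- (1 - dA) * b
  ca2 <- (1 - dA) * (1 - b) * g * cc
  ca3 <- (1 - dA) * (1 - b) * g * (1 - cc)
  ca4 <- dA
  ca5 <- (1 - dA) * (1 - b) * (1 - g)

  P1 <- cp1 + cp2 + cp3
  P4 <- ca1 + ca2
  P6 <- ca4 + ca5
  frac <- function(num, den) ifelse(den > 0, num / den, 0)
  # expected branch counts
  m1 <- n[, 1L] * frac(cp1, P1)
  m2 <- n[, 1L] * frac(cp2, P1)
  m3 <- n[, 1L] * frac(cp3, P1)
  m4 <- n[, 2L]
  m5 <- n[, 3L]
  m6 <- n[, 4L] * frac(ca1, P4)
  m7 <- n[, 4L] * frac(ca2, P4)
  m8 <- n[, 5L]
  m9 <- n[, 6L] * frac(ca4, P6)
  m10 <- n[, 6L] * frac(ca5, P6)

  num <- cbind(dP = m1,
               dA = m9,
               b  = m2 + m6,
               g  = m3 + m4 + m7 + m8)
  den <- cbind(dP = n[, 1L] + n[, 2L] + n[, 3L],
               dA = n[, 4L] + n[, 5L] + n[, 6L],
               b  = m2 + m3 + m4 + m5 + m6 + m7 + m8 + m10,
               g  = m3 + m4 + m7 + m8 + m5 + m10)
  new_free <- free
  for (j in seq_along(free)) {
    sel <- spec$index == j
    dj <- sum(den[, colnames(spec$index)][sel])
    if (dj > 0) new_free[j] <- sum(num[, colnames(spec$index)][sel]) / dj
  }
  new_free
}

fit_em <- function(start, spec, n, cc, max_iter, tol) {
  free <- start
  ll <- em_loglik(free, spec, n, cc)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    new <- em_step(free, spec, n, cc)
    # step-lengthening: EM crawls linearly toward boundary solutions, so try
    # extrapolating along the EM direction (projected into [0,1]) and keep
    # the doubling only while it still improves the likelihood
    ll_new <- em_loglik(new, spec, n, cc)
    step <- new - free
    repeat {
      cand <- pmin(pmax(new + step, 0), 1)
      ll_cand <- em_loglik(cand, spec, n, cc)
      if (ll_cand > ll_new) {
        new <- cand
        ll_new <- ll_cand
        step <- step * 2
      } else break
    }
    if (is.finite(ll_new) && is.finite(ll) && abs(ll_new - ll) < tol) {
      free <- new
      ll <- ll_new
      converged <- TRUE
      break
    }
    free <- new
    ll <- ll_new
  }
  list(free = free, loglik = ll, converged = converged, iter = iter)
}

em_loglik <- function(free, spec, n, cc) {
  p <- prob_matrix(free, spec)
  pos <- n > 0
  if (any(p[pos] <= 0)) return(-Inf)
  sum(n[pos] * log(p[pos]))
}

fit_lbfgsb <- function(start, spec, n, cc, max_iter, tol) {
  negll <- function(free) {
    p <- pmax(prob_matrix(free, spec), 1e-300)
    -sum(n[n > 0] * log(p[n > 0]))
  }
  o <- stats::optim(start, negll, method = "L-BFGS-B",
                    lower = 1e-9, upper = 1 - 1e-9,
                    control = list(maxit = max_iter, factr = 100,
                                   ndeps = rep(1e-6, length(start))))
  list(free = o$par, loglik = -o$value,
       converged = o$convergence == 0L, iter = o$counts[["function"]])
}

# ---- fitting ---------------------------------------------------------------

#' Fit the 2-HT identification model by maximum likelihood
#'
#' Maximises the product-multinomial likelihood of a [model_spec()] over the
#' free parameters, constrained to `[0, 1]`.  The primary optimiser is the
#' EM algorithm for multinomial processing tree models; a box-constrained
#' quasi-Newton route (`method = "lbfgsb"`, via [stats::optim()]) is
#' available as an independent cross-check and as a faster option for large
#' simulation studies.  Multiple uniform random restarts (deterministic
#' given `seed`) guard against local maxima; the best restart by
#' log-likelihood wins, ties going to the lowest restart index.
#'
#' The goodness of fit is the likelihood-ratio statistic
#' `G² = 2 * sum(obs * log(obs / expected))` over all cells (zero counts
#' contribute 0), referred to a chi-square distribution with
#' `conditions x 4 - n_free` degrees of freedom.
#'
#' @param spec An `ht_model_spec`.
#' @param data A [response_table()] with matching conditions.
#' @param method `"em"` (default) or `"lbfgsb"`.
#' @param n_restarts Number of random restarts (default 10).
#' @param max_iter Iteration cap per restart (default 10000).
#' @param tol Convergence tolerance on the absolute log-likelihood change
#'   (default 1e-10).
#' @param seed Integer seed for the restart draws.
#' @param compute_se Compute standard errors from the expected Fisher
#'   information (default `TRUE`).
#'
#' @return An object of class `ht_fit`: a list with `estimates` (`K x 4`
#'   parameter matrix), `free_estimates` (named free vector), `se` (named,
#'   `NA` where undefined), `loglik`, `g_squared`, `df`, `p_value`,
#'   `converged`, `n_restarts_used`, `boundary` (names of free parameters at
#'   0 or 1), `method`, `seed`, plus the `spec` and `data` for downstream
#'   operations.  Non-convergence in all restarts yields `converged = FALSE`
#'   with diagnostics, not an error.
#'
#' @examples
#' tab <- lineup_fixture("horry_reanalysis")
#' fit <- fit_2ht(base_model_spec(rownames(tab)), tab)
#' fit
#' @export
fit_2ht <- function(spec, data, method = c("em", "lbfgsb"),
                    n_restarts = 10L, max_iter = 10000L, tol = 1e-10,
                    seed = 1L, compute_se = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "ht_model_spec"))
  data <- align_data(spec, data)
  n <- flat_counts(data)
  cc <- spec$design$suspect_constant
  nf <- spec$n_free

  best <- NULL
  if (nf == 0L) {
    best <- list(free = numeric(0), loglik = em_loglik(numeric(0), spec, n, cc),
                 converged = TRUE, iter = 0L)
    n_restarts <- 0L
  } else {
    set.seed(as.integer(seed))
    starts <- matrix(stats::runif(n_restarts * nf, 0.02, 0.98), n_restarts, nf)
    for (r in seq_len(n_restarts)) {
      res <- switch(method,
        em = fit_em(starts[r, ], spec, n, cc, max_iter, tol),
        lbfgsb = fit_lbfgsb(starts[r, ], spec, n, cc, max_iter, tol)
      )
      if (is.null(best) || res$loglik > best$loglik + 1e-12) best <- res
    }
  }

  free <- stats::setNames(best$free, spec$free_names)
  estimates <- expand_parameters(free, spec)
  exp_cnt <- expected_counts_internal(free, spec, n)
  pos <- n > 0
  g2 <- 2 * sum(n[pos] * log(n[pos] / exp_cnt[pos]))
  df <- spec$df
  p_value <- stats::pchisq(g2, df = df, lower.tail = FALSE)
  boundary_tol <- 1e-4
  boundary <- spec$free_names[free < boundary_tol | free > 1 - boundary_tol]

  fit <- structure(
    list(estimates = estimates, free_estimates = free, se = NULL,
         loglik = best$loglik, g_squared = g2, df = df, p_value = p_value,
         converged = best$converged, n_restarts_used = n_restarts,
         n_iter = best$iter, boundary = boundary, method = method,
         seed = as.integer(seed), spec = spec, data = data),
    class = "ht_fit"
  )
  if (compute_se && nf > 0L) fit$se <- standard_errors(fit)
  fit
}

# model-implied expected counts, K x 6 in flat_counts() order
expected_counts_internal <- function(free, spec, n) {
  p <- prob_matrix(free, spec)
  n_cp <- rowSums(n[, 1:3, drop = FALSE])
  n_ca <- rowSums(n[, 4:6, drop = FALSE])
  cbind(n_cp * p[, 1:3, drop = FALSE], n_ca * p[, 4:6, drop = FALSE])
}

#' Model-implied expected counts
#'
#' Expected cell counts under the fitted parameters: per condition and
#' lineup type, the tree total times the fitted category probabilities, so
#' expected counts conserve each tree's observed total.
#'
#' @param fit An `ht_fit`.
#' @return A `K x 2 x 3` array shaped like the fitted [response_table()].
#' @export
expected_counts <- function(fit) {
  stopifnot(inherits(fit, "ht_fit"))
  e <- expected_counts_internal(fit$free_estimates, fit$spec, flat_counts(fit$data))
  arr <- array(e[, c(1L, 4L, 2L, 5L, 3L, 6L)], dim = c(nrow(e), 2L, 3L),
               dimnames = dimnames(fit$data))
  arr
}

# ---- standard errors -------------------------------------------------------

#' Standard errors from the expected Fisher information
#'
#' Computes per-free-parameter standard errors as square roots of the
#' diagonal of the inverse expected Fisher information of the
#' product-multinomial model, evaluated at the maximum-likelihood estimates.
#' Derivatives of the category probabilities are central finite differences
#' of the tree polynomials, which remain valid at the `[0, 1]` boundary.
#' Estimates on the boundary are listed in the fit's `boundary` field: their
#' SEs come from the same (unconstrained) information matrix and standard
#' asymptotics are distorted there, so they should be read with caution.
#' If the information matrix is singular, affected parameters get `NA` and
#' the rest are computed from a pseudo-inverse.
#'
#' @param fit An `ht_fit`.
#' @return Named numeric vector of standard errors (`NA` where undefined).
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "ht_fit"))
  spec <- fit$spec
  free <- fit$free_estimates
  nf <- spec$n_free
  if (nf == 0L) return(stats::setNames(numeric(0), character(0)))
  n <- flat_counts(fit$data)
  K <- nrow(n)
  n_tree <- cbind(matrix(rowSums(n[, 1:3, drop = FALSE]), K, 3L),
                  matrix(rowSums(n[, 4:6, drop = FALSE]), K, 3L))
  p <- prob_matrix(free, spec)
  h <- 1e-6
  J <- array(0, dim = c(dim(p), nf))              # d p / d free
  for (j in seq_len(nf)) {
    up <- free; up[j] <- up[j] + h
    dn <- free; dn[j] <- dn[j] - h
    J[, , j] <- (prob_matrix(up, spec) - prob_matrix(dn, spec)) / (2 * h)
  }
  info <- matrix(0, nf, nf)
  pf <- pmax(p, 1e-10)
  for (i in seq_len(nf)) {
    for (j in i:nf) {
      # skip cells whose probability vanishes and whose derivatives do too
      num <- J[, , i] * J[, , j]
      keep <- p > 1e-10 | abs(num) > 1e-16
      info[i, j] <- info[j, i] <- sum((n_tree * num / pf)[keep])
    }
  }
  se <- rep(NA_real_, nf)
  inv <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(inv)) {
    inv <- MASS::ginv(info)
    d <- diag(inv)
    ok <- d > 0 & is.finite(d)
    se[ok] <- sqrt(d[ok])
  } else {
    d <- diag(inv)
    se[d > 0 & is.finite(d)] <- sqrt(d[d > 0 & is.finite(d)])
  }
  stats::setNames(se, spec$free_names)
}

# ---- printing --------------------------------------------------------------

#' @export
print.ht_fit <- function(x, digits = 2, ...) {
  cat("<ht_fit> 2-HT eyewitness identification model\n")
  cat(sprintf("method: %s (%d restarts, seed %d)%s\n", x$method,
              x$n_restarts_used, x$seed,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  est <- x$free_estimates
  tab <- data.frame(estimate = round(est, digits))
  if (!is.null(x$se)) tab$se <- round(x$se, digits)
  tab$note <- ifelse(names(est) %in% x$boundary, "boundary", "")
  print(tab)
  cat(sprintf("logLik %.4f;  G^2(%d) = %.2f, p = %.3f\n",
              x$loglik, x$df, x$g_squared, x$p_value))
  invisible(x)
}

#' Serialise a fit to JSON
#'
#' Writes full-precision estimates, standard errors, fit statistics and a
#' rounded (2-decimal) presentation view.
#'
#' @param fit An `ht_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "ht_fit"))
  obj <- list(
    conditions = fit$spec$conditions,
    free_names = fit$spec$free_names,
    estimates = as.list(fit$free_estimates),
    se = if (is.null(fit$se)) NULL else as.list(fit$se),
    loglik = fit$loglik, g_squared = fit$g_squared, df = fit$df,
    p_value = fit$p_value, converged = fit$converged,
    boundary = fit$boundary, method = fit$method, seed = fit$seed,
    rounded = list(estimates = as.list(round(fit$free_estimates, 2)),
                   g_squared = round(fit$g_squared, 2),
                   p_value = round(fit$p_value, 3))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
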