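#' Specify a 2-HT identification model
#'
#' Binds a lineup design, an ordered set of experimental conditions and a
#' [restriction_map()] into a fittable model.  Each condition contributes the
#' four process parameters `dP`, `dA`, `b`, `g`; restrictions equate
#' parameters across conditions or fix them to constants.
#'
#' The free parameters are ordered canonically — `dP` per condition, then `g`
#' per condition, then the remaining (possibly shared) `b` and `dA` instances
#' — so that free vectors, seeds and serialised fits are reproducible.  The
#' goodness-of-fit degrees of freedom are `conditions x 2 trees x 2` minus
#' the number of free parameters.
#'
#' @param design A [lineup_design()].
#' @param conditions Character vector of unique, non-empty condition labels.
#' @param restrictions A [restriction_map()] (default: none, the saturated
#'   per-condition parameterisation).
#'
#' @return An object of class `ht_model_spec` with elements `design`,
#'   `conditions`, `restrictions`, `free_names`, `n_free`, `df`, and internal
#'   index tables mapping free values to parameter instances.
#'
#' @examples
#' spec <- base_model_spec(c("fyc", "control"))
#' spec$n_free  # 6
#' spec$df      # 2
#' @export
model_spec <- function(design, conditions,
                       restrictions = restriction_map()) {
  stopifnot(inherits(design, "lineup_design"))
  conditions <- as.character(conditions)
  if (length(conditions) < 1L || anyDuplicated(conditions) || any(!nzchar(conditions))) {
    stop("`conditions` must be unique non-empty labels", call. = FALSE)
  }
  if (!inherits(restrictions, "restriction_map")) {
    restrictions <- restriction_map(restrictions)
  }
  K <- length(conditions)

  # assignment tables: index[k, p] > 0 points into the free vector,
  # index[k, p] == 0 means the instance is fixed at fixed[k, p]
  index <- matrix(NA_integer_, K, 4L, dimnames = list(conditions, PARAM_NAMES))
  fixed <- matrix(NA_real_, K, 4L, dimnames = list(conditions, PARAM_NAMES))
  group <- matrix(NA_integer_, K, 4L, dimnames = list(conditions, PARAM_NAMES))

  for (cn in restrictions) {
    unknown <- setdiff(cn$conditions, conditions)
    if (length(unknown) > 0L) {
      stop(sprintf("restriction on `%s` names unknown condition `%s`",
                   cn$parameter, unknown[1L]), call. = FALSE)
    }
    if (cn$type == "fix") {
      fixed[cn$conditions, cn$parameter] <- cn$value
      index[cn$conditions, cn$parameter] <- 0L
    }
  }
  # equality groups: one group id per eq constraint
  gid <- 0L
  for (cn in restrictions) {
    if (cn$type == "equal") {
      gid <- gid + 1L
      group[cn$conditions, cn$parameter] <- gid
    }
  }

  free_names <- character(0)
  nf <- 0L
  for (p in c("dP", "g", "b", "dA")) {       # canonical free-vector order
    done_groups <- integer(0)
    for (k in seq_len(K)) {
      if (!is.na(index[k, p])) next           # fixed
      g_k <- group[k, p]
      if (!is.na(g_k) && g_k %in% done_groups) {
        index[k, p] <- index[match(g_k, group[, p]), p]
        next
      }
      nf <- nf + 1L
      index[k, p] <- nf
      if (!is.na(g_k)) {
        done_groups <- c(done_groups, g_k)
        members <- conditions[which(group[, p] == g_k)]
        nm <- if (length(members) == K) p else
          sprintf("%s[%s]", p, paste(members, collapse = "="))
      } else {
        nm <- if (K == 1L) p else sprintf("%s[%s]", p, conditions[k])
      }
      free_names <- c(free_names, nm)
    }
  }
  df <- K * 2L * 2L - nf
  structure(
    list(design = design, conditions = conditions, restrictions = restrictions,
         free_names = free_names, n_free = nf, df = df,
         index = index, fixed = fixed),
    class = "ht_model_spec"
  )
}

#' The base two-condition model used for instruction experiments
#'
#' Convenience constructor: a two-condition model in which the
#' biased-suspect-selection parameter `b` and the culprit-absence-detection
#' parameter `dA` are each equated across conditions — the restrictions that
#' follow from using the same fair lineups in both conditions.  This leaves
#' 6 free parameters and a 2-df goodness-of-fit test.
#'
#' @param conditions Two condition labels.
#' @param design A [lineup_design()]; defaults to a six-person lineup with
#'   the rounded suspect constant 0.16667.
#'
#' @return An `ht_model_spec`.
#' @export
base_model_spec <- function(conditions = c("fyc", "control"),
                            design = lineup_design(6L)) {
  if (length(conditions) != 2L) stop("`conditions` must be two labels", call. = FALSE)
  model_spec(design, conditions, restriction_map(
    eq_constraint("b", conditions),
    eq_constraint("dA", conditions)
  ))
}

#' Expand a free-parameter vector to the full parameter set
#'
#' @param free Numeric vector of length `spec$n_free`, in the canonical order
#'   of `spec$free_names`.
#' @param spec An `ht_model_spec`.
#'
#' @return A `K x 4` matrix of parameter values (columns `dP`, `dA`, `b`,
#'   `g`; one row per condition) satisfying the spec's restrictions.
#' @seealso [pack_parameters()] for the inverse.
#' @export
expand_parameters <- function(free, spec) {
  stopifnot(inherits(spec, "ht_model_spec"))
  if (length(free) != spec$n_free) {
    stop(sprintf("`free` has length %d, expected %d", length(free), spec$n_free),
         call. = FALSE)
  }
  out <- spec$fixed
  idx <- spec$index > 0L
  out[idx] <- free[spec$index[idx]]
  out
}

#' Pack a full parameter set into the free vector
#'
#' Inverse of [expand_parameters()].  Errors if `params` violates the spec's
#' restrictions (unequal values inside an equality group, or a fixed instance
#' not at its fixed value).
#'
#' @param params `K x 4` parameter matrix (columns `dP`, `dA`, `b`, `g`).
#' @param spec An `ht_model_spec`.
#' @param tol Tolerance for restriction-consistency checks.
#'
#' @return Numeric vector of length `spec$n_free` named by `spec$free_names`.
#' @export
pack_parameters <- function(params, spec, tol = 1e-8) {
  stopifnot(inherits(spec, "ht_model_spec"))
  params <- params[, PARAM_NAMES, drop = FALSE]
  free <- numeric(spec$n_free)
  for (j in seq_len(spec$n_free)) {
    vals <- params[spec$index == j]
    if (diff(range(vals)) > tol) {
      stop(sprintf("parameter instances of `%s` violate an equality restriction",
                   spec$free_names[j]), call. = FALSE)
    }
    free[j] <- vals[1L]
  }
  fixed_idx <- which(spec$index == 0L)
  if (any(abs(params[fixed_idx] - spec$fixed[fixed_idx]) > tol)) {
    stop("a fixed parameter instance is not at its fixed value", call. = FALSE)
  }
  stats::setNames(free, spec$free_names)
}

#' @export
print.ht_model_spec <- function(x, ...) {
  cat(sprintf("<ht_model_spec> %d condition(s): %s\n",
              length(x$conditions), paste(x$conditions, collapse = ", ")))
  print(x$design)
  print(x$restrictions)
  cat(sprintf("free parameters (%d): %s\n", x$n_free,
              paste(x$free_names, collapse = ", ")))
  cat(sprintf("goodness-of-fit df: %d\n", x$df))
  invisible(x)
}
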