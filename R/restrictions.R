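#' Parameter restrictions
#'
#' Restrictions reduce the free parameters of a model.  `eq_constraint()`
#' collapses one parameter across a group of conditions into a single free
#' value; `fix_constraint()` pins one parameter in one condition to a
#' constant.  `restriction_map()` bundles constraints and checks that no
#' parameter instance (a parameter in a condition) is touched by more than
#' one constraint.
#'
#' @param parameter One of `"dP"`, `"dA"`, `"b"`, `"g"`.
#' @param conditions Character vector of at least two condition labels whose
#'   instances of `parameter` share one free value.
#' @param condition A single condition label.
#' @param value Fixed value in `[0, 1]`.
#' @param ... Constraints built with `eq_constraint()` / `fix_constraint()`,
#'   or a single list of them.
#'
#' @return `eq_constraint()` and `fix_constraint()` return constraint
#'   objects; `restriction_map()` returns a validated list of class
#'   `restriction_map`.
#'
#' @examples
#' restriction_map(
#'   eq_constraint("b", c("fyc", "control")),
#'   eq_constraint("dA", c("fyc", "control"))
#' )
#' @export
eq_constraint <- function(parameter, conditions) {
  parameter <- match.arg(parameter, PARAM_NAMES)
  conditions <- as.character(conditions)
  if (length(conditions) < 2L || anyDuplicated(conditions)) {
    stop("`conditions` must be at least two distinct labels", call. = FALSE)
  }
  structure(list(type = "equal", parameter = parameter, conditions = conditions),
            class = "ht_constraint")
}

#' @rdname eq_constraint
#' @export
fix_constraint <- function(parameter, condition, value) {
  parameter <- match.arg(parameter, PARAM_NAMES)
  if (length(condition) != 1L) stop("`condition` must be a single label", call. = FALSE)
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1) {
    stop("`value` must be a single number in [0, 1]", call. = FALSE)
  }
  structure(list(type = "fix", parameter = parameter,
                 conditions = as.character(condition), value = value),
            class = "ht_constraint")
}

#' @rdname eq_constraint
#' @export
restriction_map <- function(...) {
  cons <- list(...)
  if (length(cons) == 1L && is.list(cons[[1L]]) && !inherits(cons[[1L]], "ht_constraint")) {
    cons <- cons[[1L]]
  }
  ok <- vapply(cons, inherits, logical(1L), what = "ht_constraint")
  if (!all(ok)) stop("all restrictions must be eq_constraint() or fix_constraint()", call. = FALSE)
  seen <- character(0)
  for (cn in cons) {
    inst <- paste(cn$parameter, cn$conditions, sep = "@")
    dup <- intersect(inst, seen)
    if (length(dup) > 0L) {
      stop(sprintf("parameter instance %s appears in more than one constraint", dup[1L]),
           call. = FALSE)
    }
    seen <- c(seen, inst)
  }
  structure(cons, class = "restriction_map")
}

#' @export
print.ht_constraint <- function(x, ...) {
  cat(format_constraint(x), "\n")
  invisible(x)
}

#' @export
print.restriction_map <- function(x, ...) {
  if (length(x) == 0L) cat("<restriction_map> (none)\n")
  else cat("<restriction_map>\n", paste0("  ", vapply(x, format_constraint, character(1L)),
                                         collapse = "\n"), "\n", sep = "")
  invisible(x)
}

format_constraint <- function(cn) {
  if (cn$type == "equal") {
    sprintf("equal: %s across [%s]", cn$parameter, paste(cn$conditions, collapse = ", "))
  } else {
    sprintf("fix: %s@%s = %g", cn$parameter, cn$conditions, cn$value)
  }
}
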