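#' @keywords internal
"_PACKAGE"

# canonical orderings used throughout the package
PARAM_NAMES <- c("dP", "dA", "b", "g")
LINEUP_TYPES <- c("culprit_present", "culprit_absent")
OUTCOMES <- c("suspect", "filler", "rejection")

# Raw tree polynomials, no domain checks.  Vectorised over parameters; also
# valid (as polynomials) slightly outside [0,1], which the numerical
# derivatives behind the Fisher information rely on.
tree_probs <- function(dP, dA, b, g, cc) {
  sel <- b + (1 - b) * g * cc           # suspect selected without detection
  fil <- (1 - b) * g * (1 - cc)         # a filler selected
  rej <- (1 - b) * (1 - g)              # nobody selected
  cbind(
    cp_suspect   = dP + (1 - dP) * sel,
    cp_filler    = (1 - dP) * fil,
    cp_rejection = (1 - dP) * rej,
    ca_suspect   = (1 - dA) * sel,
    ca_filler    = (1 - dA) * fil,
    ca_rejection = dA + (1 - dA) * rej
  )
}

#' Outcome-category probabilities of the 2-HT identification model
#'
#' Maps the four latent process probabilities of one experimental condition to
#' the six outcome-category probabilities: suspect identification, filler
#' identification and lineup rejection, separately for culprit-present and
#' culprit-absent lineups.
#'
#' In a culprit-present lineup the culprit is detected with probability `dP`
#' and identified.  Absent detection, a suspect who stands out is selected
#' with probability `b`; otherwise a lineup member is selected by guessing
#' with probability `g`, the guess landing on the suspect with the design's
#' suspect constant (1/lineup size).  In a culprit-absent lineup, culprit
#' absence is detected with probability `dA`, leading to rejection; otherwise
#' the same non-detection processes operate on the innocent suspect.
#'
#' @param params Named numeric vector with elements `dP`, `dA`, `b`, `g` (one
#'   condition), or a matrix with those columns (one row per condition).
#' @param design A [lineup_design()].
#'
#' @return For a single condition, a 2 x 3 matrix (rows `culprit_present`,
#'   `culprit_absent`; columns `suspect`, `filler`, `rejection`).  For a
#'   parameter matrix with `K` rows, a `K x 2 x 3` array with condition
#'   dimnames.  Each row of probabilities sums to 1.
#'
#' @examples
#' d <- lineup_design(6)
#' category_probabilities(c(dP = 0.4, dA = 0.1, b = 0, g = 0.4), d)
#' @export
category_probabilities <- function(params, design) {
  stopifnot(inherits(design, "lineup_design"))
  single <- is.null(dim(params))
  if (single) params <- matrix(params, nrow = 1L, dimnames = list(NULL, names(params)))
  if (is.null(colnames(params)) || !all(PARAM_NAMES %in% colnames(params))) {
    stop("`params` must be named with dP, dA, b, g", call. = FALSE)
  }
  params <- params[, PARAM_NAMES, drop = FALSE]
  bad <- which(is.na(params) | params < 0 | params > 1, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    p <- PARAM_NAMES[bad[1L, 2L]]
    stop(sprintf(
      "parameter `%s` is outside [0, 1] (value %s)",
      p, format(params[bad[1L, , drop = FALSE]])
    ), call. = FALSE)
  }
  pr <- tree_probs(params[, "dP"], params[, "dA"], params[, "b"], params[, "g"],
                   design$suspect_constant)
  # tree_probs columns are (cp triple, ca triple); the array is filled
  # column-major over (condition, lineup type, outcome)
  out <- array(pr[, c(1L, 4L, 2L, 5L, 3L, 6L)], dim = c(nrow(params), 2L, 3L),
               dimnames = list(rownames(params), LINEUP_TYPES, OUTCOMES))
  if (single) out[1L, , ] else out
}
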