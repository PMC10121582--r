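#' Lineup design constants
#'
#' A lineup consists of one suspect and `lineup_size - 1` fillers.  When a
#' witness selects a lineup member by guessing, the probability that the
#' selection lands on the suspect is a known sampling constant, not an
#' estimated parameter: `1 / lineup_size` under proper randomisation.
#'
#' Two conventions for the constant are supported.  In `"paper"` mode the
#' constant is the 5-decimal rounding of `1 / lineup_size` (for a six-person
#' lineup, 0.16667), the convention used by multiTree-style analyses so that
#' fitted statistics are bit-comparable with published values.  In `"exact"`
#' mode the constant is `1 / lineup_size` exactly.  The two conventions move
#' category probabilities by at most a few parts in 1e5.
#'
#' @param lineup_size Integer number of persons in the lineup, at least 2.
#' @param mode `"paper"` (default) or `"exact"`; see Details.
#'
#' @return An object of class `lineup_design`: a list with elements
#'   `lineup_size`, `suspect_constant` and `mode`.
#'
#' @examples
#' lineup_design(6)                  # suspect_constant 0.16667
#' lineup_design(6, mode = "exact")  # suspect_constant 1/6
#' @export
lineup_design <- function(lineup_size = 6L, mode = c("paper", "exact")) {
  mode <- match.arg(mode)
  if (!is.numeric(lineup_size) || length(lineup_size) != 1L ||
      is.na(lineup_size) || lineup_size != round(lineup_size) || lineup_size < 2) {
    stop("`lineup_size` must be a single integer >= 2", call. = FALSE)
  }
  lineup_size <- as.integer(lineup_size)
  suspect_constant <- switch(mode,
    paper = round(1 / lineup_size, 5),
    exact = 1 / lineup_size
  )
  stopifnot(suspect_constant > 0, suspect_constant < 1)
  structure(
    list(lineup_size = lineup_size, suspect_constant = suspect_constant, mode = mode),
    class = "lineup_design"
  )
}

#' @export
print.lineup_design <- function(x, ...) {
  cat(sprintf(
    "<lineup_design> %d persons, suspect constant %.6g (%s mode)\n",
    x$lineup_size, x$suspect_constant, x$mode
  ))
  invisible(x)
}
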