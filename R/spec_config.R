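#' Read and write model specifications as config files
#'
#' A model spec serialises to a small YAML or JSON config:
#'
#' ```yaml
#' lineup_size: 6
#' mode: paper
#' conditions: [fyc, control]
#' restrictions:
#'   - "equal: b across [fyc, control]"
#'   - "equal: dA across [fyc, control]"
#' ```
#'
#' Restriction strings are `equal: <param> across [c1, c2, ...]` or
#' `fix: <param>@<condition> = <value>`.
#'
#' @param spec An `ht_model_spec`.
#' @param path File path; extension picks the format unless `format` is
#'   given.
#' @param format `"auto"`, `"yaml"` or `"json"`.
#' @return `write_model_spec()` returns `path` invisibly;
#'   `read_model_spec()` returns an `ht_model_spec`.
#' @export
write_model_spec <- function(spec, path, format = c("auto", "yaml", "json")) {
  stopifnot(inherits(spec, "ht_model_spec"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  obj <- list(
    lineup_size = spec$design$lineup_size,
    mode = spec$design$mode,
    conditions = spec$conditions,
    restrictions = vapply(spec$restrictions, format_constraint, character(1L))
  )
  if (format == "yaml") {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  obj <- if (format == "yaml") yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("lineup_size", "conditions")) {
    if (is.null(obj[[f]])) stop(sprintf("config is missing `%s`", f), call. = FALSE)
  }
  design <- lineup_design(obj$lineup_size, mode = obj$mode %||% "paper")
  cons <- lapply(obj$restrictions %||% character(0), parse_constraint)
  model_spec(design, as.character(obj$conditions), restriction_map(cons))
}

parse_constraint <- function(s) {
  s <- trimws(s)
  m <- regmatches(s, regexec("^equal:\\s*(\\w+)\\s+across\\s*\\[([^]]+)\\]$", s))[[1L]]
  if (length(m) == 3L) {
    return(eq_constraint(m[2L], trimws(strsplit(m[3L], ",")[[1L]])))
  }
  m <- regmatches(s, regexec("^fix:\\s*(\\w+)@(\\S+)\\s*=\\s*([0-9.eE+-]+)$", s))[[1L]]
  if (length(m) == 4L) {
    return(fix_constraint(m[2L], m[3L], as.numeric(m[4L])))
  }
  stop(sprintf("cannot parse restriction `%s`", s), call. = FALSE)
}
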