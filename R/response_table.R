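#' Observed lineup identification frequencies
#'
#' The 2 x 3 data structure of eyewitness identification decisions per
#' condition: counts of suspect identifications (the culprit in
#' culprit-present lineups, the innocent suspect in culprit-absent lineups),
#' filler identifications, and lineup rejections, in culprit-present and
#' culprit-absent lineups.
#'
#' @param counts Either a `K x 6` matrix (columns: CP suspect, CP filler,
#'   CP rejection, CA suspect, CA filler, CA rejection) or a `K x 2 x 3`
#'   array with dimensions condition x lineup type x outcome.
#' @param conditions Condition labels; taken from `rownames(counts)` if
#'   omitted.
#' @param lineup_size Number of persons per lineup (metadata).
#' @param experiment Free-text experiment label (metadata).
#' @param check_integer If `TRUE` (default), counts must be non-negative
#'   integers.  Internal callers that fit to model-implied expected counts
#'   disable this.
#'
#' @return An object of class `response_table`: a `K x 2 x 3` integer (or
#'   numeric) array with dimnames `condition`, `lineup_type`
#'   (`culprit_present`, `culprit_absent`), `outcome` (`suspect`, `filler`,
#'   `rejection`) and attributes `experiment`, `lineup_size`.
#'
#' @examples
#' tab <- response_table(
#'   rbind(fyc = c(71, 26, 61, 7, 38, 102), control = c(69, 23, 30, 5, 48, 79))
#' )
#' rowSums(tab, dims = 1)  # decisions per condition
#' @export
response_table <- function(counts, conditions = NULL, lineup_size = 6L,
                           experiment = "", check_integer = TRUE) {
  if (length(dim(counts)) == 2L) {
    if (ncol(counts) != 6L) stop("a counts matrix must have 6 columns", call. = FALSE)
    if (is.null(conditions)) conditions <- rownames(counts)
    counts <- array(counts[, c(1L, 4L, 2L, 5L, 3L, 6L)],
                    dim = c(nrow(counts), 2L, 3L))
  } else if (length(dim(counts)) == 3L) {
    if (!all(dim(counts)[2:3] == c(2L, 3L))) {
      stop("a counts array must be K x 2 x 3", call. = FALSE)
    }
    if (is.null(conditions)) conditions <- dimnames(counts)[[1L]]
  } else {
    stop("`counts` must be a K x 6 matrix or K x 2 x 3 array", call. = FALSE)
  }
  K <- dim(counts)[1L]
  if (is.null(conditions)) conditions <- paste0("condition", seq_len(K))
  conditions <- as.character(conditions)
  if (length(conditions) != K || anyDuplicated(conditions)) {
    stop("condition labels must be unique and match the number of rows", call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("all counts must be non-negative", call. = FALSE)
  }
  if (check_integer) {
    if (any(counts != round(counts))) stop("counts must be integers", call. = FALSE)
    storage.mode(counts) <- "integer"
  }
  tree_totals <- apply(counts, c(1L, 2L), sum)
  if (any(tree_totals == 0)) {
    warning("some condition has no observations in one lineup type", call. = FALSE)
  }
  dimnames(counts) <- list(condition = conditions, lineup_type = LINEUP_TYPES,
                           outcome = OUTCOMES)
  structure(counts, experiment = experiment, lineup_size = as.integer(lineup_size),
            class = c("response_table", class(counts)))
}

# K x 6 view (CP suspect/filler/rejection, CA suspect/filler/rejection)
flat_counts <- function(tab) {
  cbind(tab[, 1L, 1L], tab[, 1L, 2L], tab[, 1L, 3L],
        tab[, 2L, 1L], tab[, 2L, 2L], tab[, 2L, 3L])
}

#' Read a response table from CSV or JSON
#'
#' The CSV dialect is long format with header
#' `condition,lineup_type,outcome,count`, `lineup_type` in
#' `{culprit_present, culprit_absent}` and `outcome` in
#' `{suspect, filler, rejection}`; every condition must have all six cells
#' exactly once.  The JSON mirror holds `experiment`, `lineup_size` and the
#' same long records under `cells`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return A [response_table()].
#' @export
read_response_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
    meta <- list(experiment = sub("\\.[^.]*$", "", basename(path)), lineup_size = 6L)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(obj$cells)
    meta <- list(experiment = obj$experiment %||% "", lineup_size = obj$lineup_size %||% 6L)
  }
  need <- c("condition", "lineup_type", "outcome", "count")
  if (!all(need %in% names(df))) {
    stop(sprintf("missing column(s): %s", paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("no data rows", call. = FALSE)
  for (i in seq_len(nrow(df))) {
    if (!(df$lineup_type[i] %in% LINEUP_TYPES)) {
      stop(sprintf("row %d: unknown lineup_type `%s`", i, df$lineup_type[i]), call. = FALSE)
    }
    if (!(df$outcome[i] %in% OUTCOMES)) {
      stop(sprintf("row %d: unknown outcome `%s`", i, df$outcome[i]), call. = FALSE)
    }
    cnt <- suppressWarnings(as.numeric(df$count[i]))
    if (is.na(cnt) || cnt < 0 || cnt != round(cnt)) {
      stop(sprintf("row %d: count `%s` is not a non-negative integer", i, df$count[i]),
           call. = FALSE)
    }
  }
  key <- paste(df$condition, df$lineup_type, df$outcome)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate cell at row %d", which(duplicated(key))[1L]), call. = FALSE)
  }
  conditions <- unique(df$condition)
  arr <- array(NA_real_, dim = c(length(conditions), 2L, 3L))
  ii <- cbind(match(df$condition, conditions), match(df$lineup_type, LINEUP_TYPES),
              match(df$outcome, OUTCOMES))
  arr[ii] <- as.numeric(df$count)
  if (any(is.na(arr))) {
    miss <- which(is.na(arr), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing cell: %s / %s / %s", conditions[miss[1L]],
                 LINEUP_TYPES[miss[2L]], OUTCOMES[miss[3L]]), call. = FALSE)
  }
  response_table(arr, conditions = conditions,
                 lineup_size = meta$lineup_size, experiment = meta$experiment)
}

#' Write a response table to CSV or JSON
#'
#' @param tab A [response_table()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(tab, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- as.data.frame.table(unclass(tab), responseName = "count",
                            stringsAsFactors = FALSE)
  df <- df[order(match(df$condition, dimnames(tab)[[1L]]),
                 match(df$lineup_type, LINEUP_TYPES),
                 match(df$outcome, OUTCOMES)), ]
  rownames(df) <- NULL
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(experiment = attr(tab, "experiment"),
           lineup_size = attr(tab, "lineup_size"), cells = df),
      path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Bundled experiment frequency tables
#'
#' Returns one of the frequency tables shipped with the package:
#' `"horry_reanalysis"`, identification decisions of 559 participants in two
#' sequential-lineup instruction conditions (one decision each), and
#' `"replication"`, a conceptual replication with 355 participants
#' contributing four decisions each (two culprit-present and two
#' culprit-absent lineups).
#'
#' @param name Fixture name.
#' @return A [response_table()].
#' @examples
#' lineup_fixture("horry_reanalysis")
#' @export
lineup_fixture <- function(name = c("horry_reanalysis", "replication")) {
  name <- match.arg(name)
  read_response_table(
    system.file("extdata", paste0(name, ".csv"), package = "lineup2ht", mustWork = TRUE)
  )
}

#' Descriptive response rates
#'
#' Per condition: the suspect identification rate in culprit-present lineups
#' (correct culprit identifications), the innocent-suspect identification
#' rate in culprit-absent lineups, filler identification rates per lineup
#' type, per-type rejection rates, and the pooled lineup rejection rate
#' (all rejections over all decisions in the condition).
#'
#' @param tab A [response_table()].
#' @return A data frame with one row per condition.  Conditions with a zero
#'   total in some lineup type get `NA` rates there.
#' @examples
#' descriptive_rates(response_table(
#'   rbind(fyc = c(71, 26, 61, 7, 38, 102), control = c(69, 23, 30, 5, 48, 79))
#' ))
#' @export
descriptive_rates <- function(tab) {
  stopifnot(inherits(tab, "response_table"))
  n_cp <- apply(tab[, 1L, , drop = FALSE], 1L, sum)
  n_ca <- apply(tab[, 2L, , drop = FALSE], 1L, sum)
  rate <- function(x, n) ifelse(n > 0, x / n, NA_real_)
  data.frame(
    condition = dimnames(tab)[[1L]],
    n_cp = as.integer(n_cp), n_ca = as.integer(n_ca),
    culprit_id_rate = rate(tab[, 1L, 1L], n_cp),
    innocent_suspect_id_rate = rate(tab[, 2L, 1L], n_ca),
    filler_id_rate_cp = rate(tab[, 1L, 2L], n_cp),
    filler_id_rate_ca = rate(tab[, 2L, 2L], n_ca),
    rejection_rate_cp = rate(tab[, 1L, 3L], n_cp),
    rejection_rate_ca = rate(tab[, 2L, 3L], n_ca),
    rejection_rate = rate(tab[, 1L, 3L] + tab[, 2L, 3L], n_cp + n_ca),
    row.names = NULL
  )
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("<response_table> %s(%d decisions, %d-person lineups)\n",
              if (nzchar(attr(x, "experiment"))) paste0(attr(x, "experiment"), " ") else "",
              sum(x), attr(x, "lineup_size")))
  m <- flat_counts(x)
  dimnames(m) <- list(dimnames(x)[[1L]],
                      c("cp_suspect", "cp_filler", "cp_reject",
                        "ca_suspect", "ca_filler", "ca_reject"))
  print(m)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
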