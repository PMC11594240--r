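#' Read a multi-temperature quality-index table
#'
#' Reads the canonical plain-table format of a storage experiment: one row
#' per (group, index, temperature, time) observation. Temperatures are given
#' in Celsius in the file (the convention of storage studies) and converted
#' to kelvin by +273.15; times are converted to hours (`d` rows multiplied
#' by 24, `h` rows unchanged). Rows are sorted by time within each series.
#'
#' Required columns: `group,index,temperature_C,time,time_unit,value`.
#' With `time_unit_policy = "assume_hours"` the `time_unit` column may be
#' absent and all times are taken as hours.
#'
#' @param path Path to a CSV file (comma separator, `.` decimal, header
#'   required, UTF-8).
#' @param time_unit_policy `"explicit_column"` (default; a `time_unit`
#'   column with tokens `h` or `d` is required) or `"assume_hours"`.
#' @return A [storage_dataset()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("group,index,temperature_C,time,time_unit,value",
#'              "EG,TBARS,4,0,d,0.08", "EG,TBARS,4,3,d,0.18",
#'              "EG,TBARS,4,6,d,0.28", "EG,TBARS,4,9,d,0.38"), f)
#' ds <- read_quality_table(f)
#' dataset_series(ds, "EG", "TBARS", 277.15)$times  # 0 72 144 216
#' @export
read_quality_table <- function(path,
                               time_unit_policy = c("explicit_column",
                                                    "assume_hours")) {
  time_unit_policy <- match.arg(time_unit_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("group", "index", "temperature_C", "time", "value")
  if (time_unit_policy == "explicit_column") required <- c(required, "time_unit")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0) {
    warning("quality table '", basename(path), "' has no data rows")
    return(storage_dataset(list(), provenance = path))
  }
  if (time_unit_policy == "assume_hours" && is.null(tab$time_unit))
    tab$time_unit <- "h"
  bad_unit <- setdiff(unique(tab$time_unit), c("h", "d"))
  if (length(bad_unit))
    stop("unknown time_unit token(s): ", paste(bad_unit, collapse = ", "),
         " (expected 'h' or 'd')", call. = FALSE)
  tab$time_h <- tab$time * ifelse(tab$time_unit == "d", 24, 1)
  tab$temperature_K <- tab$temperature_C + 273.15

  parts <- split(tab, list(tab$group, tab$index, tab$temperature_K),
                 drop = TRUE)
  series <- lapply(parts, function(p) {
    p <- p[order(p$time_h), ]
    if (anyDuplicated(p$time_h))
      stop(sprintf("duplicate time %g h for (%s, %s, %.2f K)",
                   p$time_h[duplicated(p$time_h)][1],
                   p$group[1], p$index[1], p$temperature_K[1]), call. = FALSE)
    quality_series(p$group[1], p$index[1], p$temperature_K[1],
                   times = p$time_h, values = p$value)
  })
  storage_dataset(unname(series), provenance = path)
}

#' Read a fatty-acid composition table
#'
#' One row per (group, temperature, time, fatty-acid code) with the relative
#' percentage of that acid among total fatty acids. Rows whose `fa_code` is
#' one of `PUFA`, `SFA`, `MUFA` are treated as table-supplied class totals
#' and stored separately from the per-acid composition (see
#' [class_totals()] for the consistency check against computed totals).
#'
#' @param path CSV with columns `group,temperature_C,time,time_unit,fa_code,percent`.
#' @return A list of [fa_profile()] objects, ordered by group, temperature,
#'   time.
#' @export
read_fa_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("group", "temperature_C", "time", "time_unit", "fa_code", "percent")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad_unit <- setdiff(unique(tab$time_unit), c("h", "d"))
  if (length(bad_unit))
    stop("unknown time_unit token(s): ", paste(bad_unit, collapse = ", "),
         call. = FALSE)
  tab$time_h <- tab$time * ifelse(tab$time_unit == "d", 24, 1)
  tab$temperature_K <- tab$temperature_C + 273.15
  class_rows <- tab$fa_code %in% c("PUFA", "SFA", "MUFA")

  parts <- split(tab, list(tab$group, tab$temperature_K, tab$time_h),
                 drop = TRUE)
  profiles <- lapply(parts, function(p) {
    acids <- p[!(p$fa_code %in% c("PUFA", "SFA", "MUFA")), ]
    printed <- p[p$fa_code %in% c("PUFA", "SFA", "MUFA"), ]
    comp <- stats::setNames(acids$percent, acids$fa_code)
    pr <- if (nrow(printed)) stats::setNames(printed$percent, printed$fa_code) else NULL
    fa_profile(group = p$group[1], temperature = p$temperature_K[1],
               time = p$time_h[1], composition = comp,
               printed_classes = pr)
  })
  ord <- order(vapply(profiles, function(p) p$group, character(1)),
               vapply(profiles, function(p) p$temperature, numeric(1)),
               vapply(profiles, function(p) p$time, numeric(1)))
  unname(profiles[ord])
}

#' Write (and re-read) structured pipeline results
#'
#' Serializes a pipeline report to disk. JSON keeps arbitrary nested
#' structure (lists of fits, predictions, validation records); CSV is for
#' flat tabular reports (a data frame, or a list coercible to one).
#' Floating-point values are written with full precision so that a
#' write/read round trip reproduces the structure to better than 1e-12
#' relative.
#'
#' @param report A list or data frame of results.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return Invisibly, `path`.
#' @seealso [read_results()]
#' @export
write_results <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("cannot write results: directory does not exist: ", dir, call. = FALSE)
  if (format == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    df <- as.data.frame(report, stringsAsFactors = FALSE)
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read back results written by [write_results()]
#'
#' @param path File path.
#' @param format `"json"` or `"csv"`.
#' @return A list (JSON) or data frame (CSV).
#' @export
read_results <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}
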