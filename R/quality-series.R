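#' Quality-index time series at one storage temperature
#'
#' The elementary record of a storage experiment: one quality index (TBARS,
#' TVB-N, pH, a texture attribute, or a sensory score) measured repeatedly
#' over time for one treatment group held at one constant temperature.
#' Times are always stored in hours and temperatures in kelvin; the readers in
#' [read_quality_table()] perform the unit conversions.
#'
#' @param group Free-text group label, e.g. `"EG"` (treated) or `"CG"`
#'   (control). Labels are conventions of the data, not enforced values.
#' @param index_name Quality-index label, e.g. `"TBARS"`, `"TVB-N"`, `"pH"`.
#' @param temperature Absolute storage temperature in kelvin (> 0).
#' @param times Numeric vector of sampling times in hours, strictly
#'   increasing, all non-negative.
#' @param values Numeric vector of index values, same length as `times`.
#'   Units are index-specific: mg MDA/kg for TBARS, mg/100 g for TVB-N.
#'   Negative values are rejected for TBARS and TVB-N.
#' @param units Optional free-text unit label carried through reports.
#'
#' @return An object of class `quality_series`.
#' @seealso [storage_dataset()], [fit_kinetic()]
#' @examples
#' qs <- quality_series("EG", "TBARS", 277.15,
#'                      times = c(0, 72, 144, 216),
#'                      values = c(0.08, 0.18, 0.28, 0.38),
#'                      units = "mg MDA/kg")
#' qs
#' @export
quality_series <- function(group, index_name, temperature, times, values,
                           units = "") {
  stopifnot(is.character(group), length(group) == 1L,
            is.character(index_name), length(index_name) == 1L)
  temperature <- as.numeric(temperature)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(temperature) != 1L || !is.finite(temperature) || temperature <= 0)
    stop("'temperature' must be a single positive value in kelvin", call. = FALSE)
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length", call. = FALSE)
  if (anyNA(times) || anyNA(values))
    stop("'times' and 'values' must not contain missing values", call. = FALSE)
  if (length(times) > 0) {
    if (any(times < 0))
      stop("'times' must all be >= 0 (hours)", call. = FALSE)
    if (length(times) > 1 && any(diff(times) <= 0))
      stop("'times' must be strictly increasing", call. = FALSE)
  }
  if (index_name %in% c("TBARS", "TVB-N") && any(values < 0))
    stop(sprintf("'%s' values must be >= 0", index_name), call. = FALSE)
  structure(
    list(group = group, index_name = index_name, temperature = temperature,
         times = times, values = values, units = units),
    class = "quality_series")
}

#' @export
print.quality_series <- function(x, ...) {
  cat(sprintf("<quality_series> %s / %s at %.2f K (%g degC), %d points\n",
              x$group, x$index_name, x$temperature, x$temperature - 273.15,
              length(x$times)))
  cat("  t (h):", paste(signif(x$times, 6), collapse = ", "), "\n")
  cat("  value:", paste(signif(x$values, 6), collapse = ", "),
      if (nzchar(x$units)) paste0("[", x$units, "]") else "", "\n")
  invisible(x)
}

series_key <- function(group, index_name, temperature) {
  paste(group, index_name, format(temperature, nsmall = 2), sep = "|")
}

#' Collection of quality-index series from one storage experiment
#'
#' Container keyed by (group, index, temperature); duplicates are rejected.
#' The usual source is [read_quality_table()] or
#' [simulate_kinetic_dataset()].
#'
#' @param series List of [quality_series()] objects.
#' @param provenance Free-text note on where the data came from.
#'
#' @return An object of class `storage_dataset`: a named list of series with
#'   a `provenance` attribute. Keys are `"group|index|temperature"`.
#' @export
storage_dataset <- function(series = list(), provenance = "") {
  stopifnot(is.list(series))
  for (s in series)
    if (!inherits(s, "quality_series"))
      stop("all elements of 'series' must be quality_series objects", call. = FALSE)
  keys <- vapply(series, function(s)
    series_key(s$group, s$index_name, s$temperature), character(1))
  if (anyDuplicated(keys))
    stop("duplicate (group, index, temperature) key: ",
         keys[duplicated(keys)][1], call. = FALSE)
  names(series) <- keys
  structure(series, provenance = provenance, class = "storage_dataset")
}

#' @export
print.storage_dataset <- function(x, ...) {
  cat(sprintf("<storage_dataset> %d series\n", length(x)))
  for (k in names(x))
    cat("  ", k, sprintf(" (%d points)\n", length(x[[k]]$times)), sep = "")
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat("  provenance: ", prov, "\n", sep = "")
  invisible(x)
}

#' Retrieve one series from a storage dataset
#'
#' @param dataset A [storage_dataset()].
#' @param group,index_name,temperature Key of the series to fetch
#'   (temperature in kelvin).
#' @return The matching [quality_series()], or an error if absent.
#' @export
dataset_series <- function(dataset, group, index_name, temperature) {
  stopifnot(inherits(dataset, "storage_dataset"))
  key <- series_key(group, index_name, temperature)
  if (is.null(dataset[[key]]))
    stop("no series for key ", key, call. = FALSE)
  dataset[[key]]
}

#' Enumerate the (group, index, temperature) keys of a dataset
#'
#' @param dataset A [storage_dataset()].
#' @return A data frame with columns `group`, `index_name`, `temperature_K`
#'   and `n_points`, one row per stored series.
#' @export
dataset_keys <- function(dataset) {
  stopifnot(inherits(dataset, "storage_dataset"))
  if (length(dataset) == 0)
    return(data.frame(group = character(), index_name = character(),
                      temperature_K = numeric(), n_points = integer()))
  data.frame(
    group = vapply(dataset, function(s) s$group, character(1)),
    index_name = vapply(dataset, function(s) s$index_name, character(1)),
    temperature_K = vapply(dataset, function(s) s$temperature, numeric(1)),
    n_points = vapply(dataset, function(s) length(s$times), integer(1)),
    row.names = NULL)
}

#' Run configuration for the shelf-life pipeline
#'
#' Bundles the constants and policy switches used by
#' [run_shelf_life_pipeline()]. The defaults are the conventions of
#' accelerated TBARS storage studies: a spoilage limit of 0.5 mg MDA/kg,
#' the gas constant 8.3144 J/(mol K), and the Arrhenius abscissa expressed
#' as 1000/T so that reported slopes are O(1).
#'
#' @param quality_limit Threshold index value defining end of shelf life
#'   (default 0.5, the recommended TBARS limit in mg MDA/kg).
#' @param gas_constant Gas constant in J/(mol K). Default 8.3144.
#' @param kinetic_order `"zero"` or `"first"`; reaction order used for both
#'   fitting and prediction outside paper mode.
#' @param paper_mode Logical. When `TRUE` the pipeline reproduces the hybrid
#'   chain common in the applied literature: per-temperature rate constants
#'   from the zero-order (linear) fit combined with the first-order
#'   threshold formula for shelf life. When `FALSE` (default) the same
#'   `kinetic_order` is used consistently for fitting and prediction.
#' @param arrhenius_x_scale Scale of the Arrhenius abscissa (x = x_scale/T);
#'   default 1000. Changing it rescales slope/intercept reporting only —
#'   Ea and k0 are invariant.
#' @param a0_policy `"per_temperature_intercept"` (default) or
#'   `"shared_value"`: where the time-zero index value used in shelf-life
#'   predictions comes from.
#' @param shared_a0 The shared time-zero value when
#'   `a0_policy = "shared_value"`; ignored otherwise.
#' @param seed Optional integer seed recorded for provenance.
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(quality_limit = 0.5,
                       gas_constant = 8.3144,
                       kinetic_order = c("first", "zero"),
                       paper_mode = FALSE,
                       arrhenius_x_scale = 1000,
                       a0_policy = c("per_temperature_intercept", "shared_value"),
                       shared_a0 = NULL,
                       seed = NULL) {
  kinetic_order <- match.arg(kinetic_order)
  a0_policy <- match.arg(a0_policy)
  if (!is.numeric(quality_limit) || quality_limit <= 0)
    stop("'quality_limit' must be > 0", call. = FALSE)
  if (!is.numeric(gas_constant) || gas_constant <= 0)
    stop("'gas_constant' must be > 0", call. = FALSE)
  if (!is.numeric(arrhenius_x_scale) || arrhenius_x_scale <= 0)
    stop("'arrhenius_x_scale' must be > 0", call. = FALSE)
  if (a0_policy == "shared_value" &&
      (is.null(shared_a0) || !is.numeric(shared_a0) || shared_a0 <= 0))
    stop("'shared_a0' must be a positive number when a0_policy = 'shared_value'",
         call. = FALSE)
  structure(
    list(quality_limit = quality_limit, gas_constant = gas_constant,
         kinetic_order = kinetic_order, paper_mode = paper_mode,
         arrhenius_x_scale = arrhenius_x_scale, a0_policy = a0_policy,
         shared_a0 = shared_a0, seed = seed),
    class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat("  quality_limit:", x$quality_limit, "\n")
  cat("  gas_constant :", x$gas_constant, "J/(mol K)\n")
  cat("  kinetic_order:", x$kinetic_order,
      if (isTRUE(x$paper_mode)) "(paper_mode hybrid: linear k + first-order SL)" else "",
      "\n")
  cat("  a0_policy    :", x$a0_policy,
      if (!is.null(x$shared_a0)) sprintf("(a0 = %g)", x$shared_a0) else "", "\n")
  invisible(x)
}
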