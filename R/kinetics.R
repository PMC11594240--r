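#' Fit zero- or first-order degradation kinetics to one series
#'
#' Ordinary least squares of the quality index against storage time. Under
#' zero-order kinetics the index itself is regressed on time
#' (A = A0 + k t); under first-order kinetics its natural logarithm is
#' (ln A = ln A0 + k t, i.e. A = A0 e^{kt}). In both cases the rate
#' constant k is the fitted slope, in units of the index (or log-index)
#' per hour.
#'
#' @param series A [quality_series()].
#' @param order `"zero"` or `"first"`.
#' @return An object of class `kinetic_fit` with fields `group`,
#'   `temperature` (K), `order`, `k` (per hour), `intercept` (index units
#'   for zero order; log index units for first order), `r_squared` and
#'   `n_points`. When the response has zero variance (all values equal),
#'   `r_squared` is reported as 0 by convention, with a warning.
#' @examples
#' qs <- quality_series("EG", "TBARS", 310.15, times = 0:6,
#'                      values = 0.084 * exp(0.06 * (0:6)))
#' fit_kinetic(qs, "first")  # recovers k = 0.06 exactly
#' @export
fit_kinetic <- function(series, order = c("first", "zero")) {
  order <- match.arg(order)
  stopifnot(inherits(series, "quality_series"))
  t <- series$times
  v <- series$values
  if (length(unique(t)) < 2)
    stop("kinetic fit needs at least 2 distinct times", call. = FALSE)
  if (order == "first" && any(v <= 0)) {
    bad <- t[which(v <= 0)[1]]
    stop(sprintf("first-order fit requires positive values; value <= 0 at t = %g h",
                 bad), call. = FALSE)
  }
  y <- if (order == "first") log(v) else v
  fit <- stats::lm(y ~ t)
  co <- unname(stats::coef(fit))
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warning("response has zero variance; r_squared reported as 0 by convention")
    r2 <- 0
  } else {
    r2 <- 1 - sum(stats::residuals(fit)^2) / sst
  }
  structure(
    list(group = series$group, index_name = series$index_name,
         temperature = series$temperature, order = order,
         k = co[2], intercept = co[1], r_squared = r2,
         n_points = length(t)),
    class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s / %s at %.2f K, %s order\n",
              x$group, x$index_name, x$temperature, x$order))
  cat(sprintf("  k = %.6g /h, intercept = %.6g, R^2 = %.5f (n = %d)\n",
              x$k, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Arrhenius regression of rate constants on inverse temperature
#'
#' Fits ln k = ln k0 - Ea/(R T) by ordinary least squares of ln k on
#' x = x_scale / T. With the conventional `x_scale = 1000` the reported
#' slope is -Ea/(1000 R), matching the "y = a X + b versus 1000/T"
#' presentation of storage studies; Ea and k0 themselves are invariant to
#' `x_scale`.
#'
#' @param rates A data frame with columns `temperature` (kelvin) and `k`
#'   (per hour), one row per storage temperature. At least two distinct
#'   temperatures; all k > 0. Rows are sorted by temperature before
#'   fitting (the fit is order-invariant; sorting stabilizes reports).
#' @param gas_constant Gas constant R in J/(mol K); default 8.3144.
#' @param x_scale Abscissa scale (x = x_scale/T); default 1000.
#' @return An object of class `arrhenius_fit` with fields `Ea` (J/mol),
#'   `k0` (per hour), `slope`, `intercept` (= ln k0), `r_squared`,
#'   `x_scale`, `gas_constant` and `n_temperatures`. Identities
#'   `Ea = -slope * x_scale * gas_constant` and `k0 = exp(intercept)` hold
#'   exactly.
#' @examples
#' rates <- data.frame(temperature = c(277.15, 298.15, 310.15),
#'                     k = c(0.00138, 0.00632, 0.06356))
#' fit_arrhenius(rates)
#' @export
fit_arrhenius <- function(rates, gas_constant = 8.3144, x_scale = 1000) {
  rates <- as.data.frame(rates)
  if (!all(c("temperature", "k") %in% names(rates)))
    stop("'rates' needs columns 'temperature' and 'k'", call. = FALSE)
  if (gas_constant <= 0 || x_scale <= 0)
    stop("'gas_constant' and 'x_scale' must be > 0", call. = FALSE)
  if (any(rates$k <= 0))
    stop("all rate constants must be > 0 for the Arrhenius fit", call. = FALSE)
  if (length(unique(rates$temperature)) < 2)
    stop("Arrhenius fit needs at least 2 distinct temperatures", call. = FALSE)
  rates <- rates[order(rates$temperature), ]
  x <- x_scale / rates$temperature
  y <- log(rates$k)
  fit <- stats::lm(y ~ x)
  co <- unname(stats::coef(fit))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(
    list(Ea = -co[2] * x_scale * gas_constant,
         k0 = exp(co[1]),
         slope = co[2], intercept = co[1], r_squared = r2,
         x_scale = x_scale, gas_constant = gas_constant,
         n_temperatures = length(unique(rates$temperature))),
    class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat("<arrhenius_fit>\n")
  cat(sprintf("  ln k = %.5f * (%g/T) + %.5f   (R^2 = %.5f, %d temperatures)\n",
              x$slope, x$x_scale, x$intercept, x$r_squared, x$n_temperatures))
  cat(sprintf("  Ea = %.6g J/mol, k0 = %.6g /h\n", x$Ea, x$k0))
  invisible(x)
}

#' Arrhenius-interpolated rate constant at a temperature
#'
#' Evaluates k(T) = k0 exp(-Ea/(R T)) from a fitted [fit_arrhenius()]
#' model. Strictly increasing in temperature whenever Ea > 0.
#'
#' @param fit An `arrhenius_fit`.
#' @param temperature Absolute temperature(s) in kelvin (> 0); vectorized.
#' @return Rate constant(s), per hour.
#' @export
rate_at <- function(fit, temperature) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  if (any(temperature <= 0))
    stop("'temperature' must be > 0 K", call. = FALSE)
  fit$k0 * exp(-fit$Ea / (fit$gas_constant * temperature))
}

#' Forward kinetic model: index value after t hours
#'
#' @param a0 Index value at time zero (> 0 for first order).
#' @param k Rate constant per hour.
#' @param t Time(s) in hours, >= 0; vectorized.
#' @param order `"zero"` (a0 + k t) or `"first"` (a0 e^{k t}).
#' @return Predicted index value(s).
#' @export
predict_quality <- function(a0, k, t, order = c("first", "zero")) {
  order <- match.arg(order)
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  if (order == "first") {
    if (a0 <= 0) stop("'a0' must be > 0 for first-order kinetics", call. = FALSE)
    a0 * exp(k * t)
  } else {
    a0 + k * t
  }
}

#' Threshold-crossing shelf life
#'
#' Time for the quality index to grow from its time-zero value `a0` to the
#' spoilage limit `a_limit` under the fitted kinetics:
#' (ln a_limit - ln a0)/k for first order, (a_limit - a0)/k for zero order.
#'
#' @param a0 Time-zero index value (> 0).
#' @param a_limit Threshold index value, >= a0.
#' @param k Rate constant per hour, > 0.
#' @param order `"zero"` or `"first"`.
#' @return Shelf life in hours.
#' @examples
#' predict_shelf_life(0.084, 0.5, 0.06356, "first")  # about 28.06 h
#' @export
predict_shelf_life <- function(a0, a_limit, k, order = c("first", "zero")) {
  order <- match.arg(order)
  if (k <= 0) stop("'k' must be > 0", call. = FALSE)
  if (a0 <= 0) stop("'a0' must be > 0", call. = FALSE)
  if (a_limit < a0)
    stop("'a_limit' is below 'a0': threshold already exceeded at time zero",
         call. = FALSE)
  if (order == "first") (log(a_limit) - log(a0)) / k else (a_limit - a0) / k
}

#' Relative error of a predicted versus actual shelf life
#'
#' 100 |predicted - actual| / predicted, rounded to a whole percent or to
#' one decimal. The predicted value is the denominator, the convention of
#' model-validation tables in storage studies.
#'
#' @param actual,predicted Shelf lives in the same unit; `predicted > 0`.
#' @param precision `"whole_percent"` (default) or `"one_decimal"`.
#' @return Relative error in percent.
#' @examples
#' relative_error(50, 55)                          # 9
#' relative_error(19, 20, "one_decimal")           # 5
#' @export
relative_error <- function(actual, predicted,
                           precision = c("whole_percent", "one_decimal")) {
  precision <- match.arg(precision)
  if (any(predicted <= 0)) stop("'predicted' must be > 0", call. = FALSE)
  err <- 100 * abs(predicted - actual) / predicted
  round(err, digits = if (precision == "whole_percent") 0 else 1)
}

#' Human-readable shelf-life label
#'
#' Shelf lives shorter than 72 h are reported to the nearest hour;
#' longer ones in days with one decimal.
#'
#' @param hours Shelf life in hours.
#' @return Character label, e.g. `"28 h"` or `"53.9 d"`.
#' @export
format_shelf_life <- function(hours) {
  vapply(hours, function(h) {
    if (h < 72) sprintf("%d h", as.integer(round(h)))
    else sprintf("%.1f d", round(h / 24, 1))
  }, character(1))
}

#' Shelf-life modelling chain: kinetics, Arrhenius, prediction, validation
#'
#' Runs the full accelerated-storage analysis for one quality index: per
#' temperature kinetic fits for each group, Arrhenius regression across
#' temperatures, threshold shelf-life predictions at each storage
#' temperature, and (when actual shelf lives are supplied) predicted versus
#' actual validation records.
#'
#' In `paper_mode` (see [run_config()]) the per-temperature rate constants
#' come from the zero-order (linear) fit while the shelf life uses the
#' first-order threshold formula — the hybrid chain used in applied TBARS
#' studies; otherwise the configured order is used for both stages.
#' Predictions use each temperature's own fitted rate constant
#' (`k_source = "fitted_per_temperature"`); [rate_at()] on the returned
#' Arrhenius fit gives the smoothed rate at any other temperature.
#'
#' @param dataset A [storage_dataset()] holding the configured index at
#'   two or more temperatures per group.
#' @param config A [run_config()].
#' @param index_name Quality index to model; default `"TBARS"`.
#' @param actuals Optional data frame of observed shelf lives with columns
#'   `group`, `temperature_C`, `actual`, `unit` (`"h"` or `"d"`).
#' @return An object of class `shelf_life_report`: list with `fits`
#'   (data frame of per-temperature kinetic fits), `arrhenius` (named list
#'   of `arrhenius_fit` per group), `predictions` (data frame), and
#'   `validation` (data frame or NULL).
#' @export
run_shelf_life_pipeline <- function(dataset, config = run_config(),
                                    index_name = "TBARS", actuals = NULL) {
  stopifnot(inherits(dataset, "storage_dataset"), inherits(config, "run_config"))
  keys <- dataset_keys(dataset)
  keys <- keys[keys$index_name == index_name, ]
  if (nrow(keys) == 0)
    stop("dataset contains no '", index_name, "' series", call. = FALSE)

  fit_order <- if (isTRUE(config$paper_mode)) "zero" else config$kinetic_order
  sl_order <- if (isTRUE(config$paper_mode)) "first" else config$kinetic_order

  fit_rows <- list()
  arrhenius <- list()
  pred_rows <- list()
  for (g in unique(keys$group)) {
    temps <- sort(keys$temperature_K[keys$group == g])
    if (length(temps) < 2)
      stop(sprintf("group '%s' has %d temperature(s); Arrhenius fitting needs >= 2",
                   g, length(temps)), call. = FALSE)
    fits <- lapply(temps, function(tc)
      fit_kinetic(dataset_series(dataset, g, index_name, tc), fit_order))
    fit_rows[[g]] <- data.frame(
      group = g, temperature_K = temps, order = fit_order,
      k = vapply(fits, `[[`, numeric(1), "k"),
      intercept = vapply(fits, `[[`, numeric(1), "intercept"),
      r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
      n = vapply(fits, `[[`, integer(1), "n_points"))
    arrhenius[[g]] <- fit_arrhenius(
      data.frame(temperature = temps,
                 k = vapply(fits, `[[`, numeric(1), "k")),
      gas_constant = config$gas_constant, x_scale = config$arrhenius_x_scale)
    a0s <- vapply(seq_along(fits), function(i) {
      if (config$a0_policy == "shared_value") config$shared_a0
      else if (fit_order == "first") exp(fits[[i]]$intercept)
      else fits[[i]]$intercept
    }, numeric(1))
    sl <- vapply(seq_along(fits), function(i)
      predict_shelf_life(a0s[i], config$quality_limit, fits[[i]]$k, sl_order),
      numeric(1))
    pred_rows[[g]] <- data.frame(
      group = g, temperature_K = temps, a0 = a0s,
      a_limit = config$quality_limit,
      k_used = vapply(fits, `[[`, numeric(1), "k"),
      k_source = "fitted_per_temperature", order = sl_order,
      shelf_life_hours = sl, shelf_life_label = format_shelf_life(sl))
  }
  fits_df <- do.call(rbind, c(fit_rows, list(make.row.names = FALSE)))
  preds_df <- do.call(rbind, c(pred_rows, list(make.row.names = FALSE)))

  validation <- NULL
  if (!is.null(actuals)) {
    actuals <- as.data.frame(actuals)
    need <- c("group", "temperature_C", "actual", "unit")
    if (!all(need %in% names(actuals)))
      stop("'actuals' needs columns ", paste(need, collapse = ", "), call. = FALSE)
    actuals$temperature_K <- actuals$temperature_C + 273.15
    actuals$actual_hours <- actuals$actual * ifelse(actuals$unit == "d", 24, 1)
    m <- merge(preds_df[, c("group", "temperature_K", "shelf_life_hours")],
               actuals[, c("group", "temperature_K", "actual_hours")],
               by = c("group", "temperature_K"))
    validation <- data.frame(
      group = m$group, temperature_K = m$temperature_K,
      actual = m$actual_hours, predicted = m$shelf_life_hours,
      relative_error_pct = relative_error(m$actual_hours, m$shelf_life_hours))
  }

  structure(list(index_name = index_name, config = config, fits = fits_df,
                 arrhenius = arrhenius, predictions = preds_df,
                 validation = validation),
            class = "shelf_life_report")
}

#' @export
print.shelf_life_report <- function(x, ...) {
  cat(sprintf("<shelf_life_report> index %s, %d group(s)\n",
              x$index_name, length(x$arrhenius)))
  for (g in names(x$arrhenius))
    cat(sprintf("  %s: Ea = %.6g J/mol, k0 = %.6g /h (R^2 = %.4f)\n",
                g, x$arrhenius[[g]]$Ea, x$arrhenius[[g]]$k0,
                x$arrhenius[[g]]$r_squared))
  cat("Predictions:\n")
  print(x$predictions[, c("group", "temperature_K", "shelf_life_hours",
                          "shelf_life_label")], row.names = FALSE)
  if (!is.null(x$validation)) {
    cat("Validation:\n")
    print(x$validation, row.names = FALSE)
  }
  invisible(x)
}
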