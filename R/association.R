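#' Significance flag for a p-value
#'
#' The star convention of correlation tables: `"**"` for p < 0.01, `"*"`
#' for 0.01 <= p < 0.05, empty otherwise (strict inequalities).
#'
#' @param p P-value(s) in [0, 1]; vectorized.
#' @return Character vector of flags.
#' @export
significance_flag <- function(p) {
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]", call. = FALSE)
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Pearson correlation with exact t-test and star flag
#'
#' Computes r = Sxy / sqrt(Sxx Syy) and the two-sided p-value from the
#' exact t reference distribution, t = r sqrt(n - 2) / sqrt(1 - r^2) on
#' n - 2 degrees of freedom — appropriate at the small n of storage
#' time courses. Perfect correlation (|r| = 1) gets p = 0.
#'
#' @param x,y Numeric vectors of equal length n >= 3, each with nonzero
#'   variance.
#' @return An object of class `correlation_cell`: list with `r`, `p`, `n`,
#'   `flag` (see [significance_flag()]).
#' @examples
#' pearson(c(1, 2, 3), c(1, 2, 4))$r  # 0.982
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx == 0 || syy == 0)
    stop("zero variance in one of the series", call. = FALSE)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sxx * syy)
  r <- max(-1, min(1, r))  # guard rounding just past +/-1
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p = p, n = n, flag = significance_flag(p)),
            class = "correlation_cell")
}

#' @export
print.correlation_cell <- function(x, ...) {
  cat(sprintf("<correlation_cell> r = %.3f%s (p = %.4g, n = %d)\n",
              x$r, if (nzchar(x$flag)) paste0(" ", x$flag) else "", x$p, x$n))
  invisible(x)
}

#' Correlation grid of a target index against other indices
#'
#' For every (group, temperature) present in the dataset, correlates the
#' target index (typically the sensory score) against each other index
#' over the matched time points, producing one row per cell of the
#' conventional sensory-versus-physicochemical correlation table.
#' All series of a cell must share an identical time grid; mismatches are
#' an error listing the missing times.
#'
#' @param dataset A [storage_dataset()].
#' @param target_index Label of the target index, e.g. `"sensory"`.
#' @param other_indices Character vector of index labels to correlate
#'   against.
#' @return Data frame with columns `group`, `temperature_K`, `index`,
#'   `r`, `p`, `n`, `flag`.
#' @export
correlation_table <- function(dataset, target_index, other_indices) {
  stopifnot(inherits(dataset, "storage_dataset"))
  keys <- dataset_keys(dataset)
  tkeys <- keys[keys$index_name == target_index, ]
  if (nrow(tkeys) == 0)
    stop("dataset contains no '", target_index, "' series", call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(tkeys))) {
    g <- tkeys$group[i]; temp <- tkeys$temperature_K[i]
    target <- dataset_series(dataset, g, target_index, temp)
    for (idx in other_indices) {
      other <- dataset_series(dataset, g, idx, temp)
      if (!identical(target$times, other$times)) {
        missing_t <- union(setdiff(target$times, other$times),
                           setdiff(other$times, target$times))
        stop(sprintf(
          "time grids differ for '%s' vs '%s' (%s, %.2f K); unmatched times: %s",
          target_index, idx, g, temp,
          paste(missing_t, collapse = ", ")), call. = FALSE)
      }
      cell <- pearson(target$values, other$values)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, temperature_K = temp, index = idx,
        r = cell$r, p = cell$p, n = cell$n, flag = cell$flag,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
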