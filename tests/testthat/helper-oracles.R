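# Closed-form OLS oracle: slope/intercept/R^2 from raw sums, independent of
# the lm()-based fitting path in the package.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ssres <- sum((y - intercept - slope * x)^2)
  sstot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r_squared = if (sstot == 0) 0 else 1 - ssres / sstot)
}

# Quick series builder for kinetics tests.
qs <- function(times, values, group = "EG", index = "TBARS", temp = 298.15) {
  quality_series(group, index, temp, times = times, values = values)
}

# Write a quality CSV and return its path.
write_quality_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(c("group,index,temperature_C,time,time_unit,value", lines), f)
  f
}
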