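test_that("kinetic fits match the closed-form OLS oracle", {
  # hand-checkable zero-order case
  f <- fit_kinetic(qs(c(0, 10, 20), c(0.10, 0.20, 0.36)), "zero")
  expect_equal(f$k, 0.013, tolerance = 1e-12)
  expect_equal(f$intercept, 0.09, tolerance = 1e-12)
  expect_equal(f$r_squared, 0.9825581, tolerance = 1e-6)

  # random small instances, both orders, against raw-sum formulas
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    t <- sort(sample(0:200, n))
    v <- exp(stats::rnorm(n, 0, 0.5))  # positive for first order
    for (ord in c("zero", "first")) {
      y <- if (ord == "first") log(v) else v
      o <- ols_oracle(t, y)
      f <- fit_kinetic(qs(t, v), ord)
      expect_equal(f$k, o$slope, tolerance = 1e-10)
      expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
      expect_equal(f$r_squared, o$r_squared, tolerance = 1e-10)
    }
  }
})

test_that("first-order fit is exact on data from the exponential model", {
  t <- c(0, 5, 10, 20, 40)
  f <- fit_kinetic(qs(t, 0.1 * exp(0.05 * t)), "first")
  expect_equal(f$k, 0.05, tolerance = 1e-12)
  expect_equal(f$intercept, log(0.1), tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
})

test_that("degenerate series are handled per convention", {
  expect_warning(f <- fit_kinetic(qs(c(0, 10, 20), c(2, 2, 2)), "zero"),
                 "zero variance")
  expect_equal(f$k, 0)
  expect_equal(f$r_squared, 0)
  expect_error(fit_kinetic(qs(0, 0.5), "zero"), "2 distinct times")
  expect_error(fit_kinetic(qs(c(0, 5), c(0.2, 0)), "first"), "t = 5")
})

test_that("Arrhenius fit reproduces the published EG and CG regressions", {
  eg <- fit_arrhenius(data.frame(temperature = c(277.15, 298.15, 310.15),
                                 k = c(0.00138, 0.00632, 0.06356)))
  expect_equal(eg$slope, -9.4251, tolerance = 5e-5 / 9.4251)
  expect_equal(eg$intercept, 27.20091, tolerance = 5e-4 / 27.2)
  expect_equal(eg$Ea, 7.8364e4, tolerance = 1e-5)
  expect_equal(eg$k0, 6.5044e11, tolerance = 5e-3)

  cg <- fit_arrhenius(data.frame(temperature = c(277.15, 298.15, 310.15),
                                 k = c(0.00205, 0.01005, 0.07905)))
  expect_equal(cg$slope, -9.0633, tolerance = 5e-5 / 9.06)
  expect_equal(cg$intercept, 26.33156, tolerance = 5e-4 / 26.3)
  expect_equal(cg$Ea, 7.5356e4, tolerance = 1e-5)
  expect_equal(cg$k0, 2.7268e11, tolerance = 5e-3)
})

test_that("two exact points recover Ea and k0; x_scale only rescales slope", {
  Ea <- 8e4; k0 <- 1e12; R <- 8.3144
  temps <- c(278, 308)
  k <- k0 * exp(-Ea / (R * temps))
  f <- fit_arrhenius(data.frame(temperature = temps, k = k), R)
  expect_equal(f$Ea, Ea, tolerance = 1e-9)
  expect_equal(f$k0, k0, tolerance = 1e-9)

  f1 <- fit_arrhenius(data.frame(temperature = temps, k = k), R, x_scale = 1)
  expect_equal(f1$Ea, f$Ea, tolerance = 1e-10)
  expect_equal(f1$k0, f$k0, tolerance = 1e-10)
  expect_equal(f1$slope, f$slope * 1000, tolerance = 1e-10)
  # identity Ea = -slope * x_scale * R holds exactly
  expect_equal(f$Ea, -f$slope * f$x_scale * f$gas_constant, tolerance = 1e-12)
  expect_equal(f$k0, exp(f$intercept), tolerance = 1e-12)

  expect_error(fit_arrhenius(data.frame(temperature = 298, k = 0.1)),
               "2 distinct temperatures")
  expect_error(fit_arrhenius(data.frame(temperature = temps, k = c(-1, 1))),
               "> 0")
})

test_that("rate_at evaluates the Arrhenius law and increases with T", {
  eg <- fit_arrhenius(data.frame(temperature = c(277.15, 298.15, 310.15),
                                 k = c(0.00138, 0.00632, 0.06356)))
  expect_equal(rate_at(eg, 310.15), 0.04123, tolerance = 1e-4 / 0.041)
  expect_equal(rate_at(eg, 277.15), 1.107e-3, tolerance = 1e-5 / 1.1e-3)
  temps <- seq(270, 320, by = 5)
  expect_true(all(diff(rate_at(eg, temps)) > 0))
  # T -> Inf limit approaches k0
  expect_equal(rate_at(eg, 1e12) / eg$k0, 1, tolerance = 1e-6)
})

test_that("forward model and shelf-life formula are mutually consistent", {
  expect_equal(predict_quality(0.084, 0.06356, 0, "first"), 0.084)
  expect_equal(predict_quality(0.25, log(2), 1, "first"), 0.5)
  expect_equal(predict_quality(0.084, 0.00138, 216, "zero"), 0.38208)

  expect_equal(predict_shelf_life(0.084, 0.5, 0.06356, "first"),
               log(0.5 / 0.084) / 0.06356)
  expect_equal(round(predict_shelf_life(0.084, 0.5, 0.06356, "first")), 28)
  expect_equal(predict_shelf_life(0.25, 0.5, log(2), "first"), 1)
  expect_equal(predict_shelf_life(0.3, 0.3, 0.1, "first"), 0)
  expect_equal(predict_shelf_life(0.3, 0.3, 0.1, "zero"), 0)

  # threshold round trip: quality at the predicted shelf life equals the limit
  set.seed(7)
  for (i in 1:20) {
    a0 <- runif(1, 0.01, 1); lim <- a0 * runif(1, 1, 20)
    k <- runif(1, 1e-4, 0.5)
    for (ord in c("zero", "first")) {
      sl <- predict_shelf_life(a0, lim, k, ord)
      expect_equal(predict_quality(a0, k, sl, ord), lim, tolerance = 1e-9)
    }
  }
  # first-order shelf life at limit = e * a0 is exactly 1/k
  expect_equal(predict_shelf_life(0.1, exp(1) * 0.1, 0.25, "first"), 1 / 0.25,
               tolerance = 1e-12)

  expect_error(predict_shelf_life(0.5, 0.4, 0.1, "first"), "threshold")
  expect_error(predict_shelf_life(0.1, 0.5, 0, "first"), "'k'")
  expect_error(predict_quality(0.1, 0.1, -1, "first"), ">= 0")
})

test_that("shelf life decreases in k and, via the Arrhenius law, in T", {
  ks <- c(0.001, 0.01, 0.1, 1)
  sl <- vapply(ks, function(k) predict_shelf_life(0.084, 0.5, k, "first"),
               numeric(1))
  expect_true(all(diff(sl) < 0))
  eg <- fit_arrhenius(data.frame(temperature = c(277.15, 298.15, 310.15),
                                 k = c(0.00138, 0.00632, 0.06356)))
  temps <- c(275, 285, 295, 305, 315)
  sl_t <- vapply(temps, function(tc)
    predict_shelf_life(0.084, 0.5, rate_at(eg, tc), "first"), numeric(1))
  expect_true(all(diff(sl_t) < 0))
})

test_that("relative error follows the validation-table rounding", {
  expect_equal(relative_error(50, 55), 9)
  expect_equal(relative_error(19, 20, "one_decimal"), 5.0)
  expect_equal(relative_error(2.5, 2.7, "one_decimal"), 7.4)
  expect_equal(relative_error(10, 10), 0)
  expect_error(relative_error(10, 0), "> 0")
})

test_that("shelf-life labels switch from hours to days at 72 h", {
  expect_equal(format_shelf_life(c(28.06, 64.8, 1292.6)),
               c("28 h", "65 h", "53.9 d"))
})

test_that("pipeline reproduces the published 310.15 K prediction in paper mode", {
  reg <- tbars_regressions()
  rows <- do.call(rbind, lapply(seq_len(nrow(reg)), function(i) {
    t <- seq(0, 100, length.out = 4)
    data.frame(group = reg$group[i], index = "TBARS",
               temperature_C = reg$temperature_K[i] - 273.15,
               time = t, time_unit = "h",
               value = reg$intercept[i] + reg$k[i] * t)
  }))
  f <- tempfile(fileext = ".csv")
  write.csv(rows, f, row.names = FALSE, quote = FALSE)
  ds <- read_quality_table(f)
  cfg <- run_config(paper_mode = TRUE, a0_policy = "shared_value",
                    shared_a0 = 0.084)
  rep <- run_shelf_life_pipeline(ds, cfg,
                                 actuals = data.frame(
                                   group = "EG", temperature_C = 37,
                                   actual = 26, unit = "h"))
  p <- rep$predictions
  eg37 <- p[p$group == "EG" & p$temperature_K == 310.15, ]
  expect_equal(eg37$shelf_life_label, "28 h")
  expect_equal(eg37$k_used, 0.06356, tolerance = 1e-9)
  expect_equal(rep$arrhenius$EG$Ea, 7.8364e4, tolerance = 1e-5)
  expect_equal(rep$validation$relative_error_pct, 7)

  # single temperature: Arrhenius precondition breach surfaces
  ds1 <- storage_dataset(list(qs(c(0, 10), c(0.1, 0.2), temp = 298.15)))
  expect_error(run_shelf_life_pipeline(ds1, cfg), ">= 2")
})

test_that("pipeline recovers a known Ea from synthetic data", {
  sim <- simulate_kinetic_dataset(synthetic_spec(additive_sd = 0, seed = 11,
                                                 group = "EG"))
  rep <- run_shelf_life_pipeline(sim$dataset, run_config(kinetic_order = "first"))
  expect_equal(rep$arrhenius$EG$Ea, sim$truth$Ea, tolerance = 1e-8)
  expect_equal(rep$arrhenius$EG$k0, sim$truth$k0, tolerance = 1e-6)
})
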