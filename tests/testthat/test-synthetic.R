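test_that("identical seeds reproduce identical datasets", {
  spec <- synthetic_spec(seed = 17)
  s1 <- simulate_kinetic_dataset(spec)
  s2 <- simulate_kinetic_dataset(spec)
  expect_identical(s1$dataset, s2$dataset)
  s3 <- simulate_kinetic_dataset(synthetic_spec(seed = 18))
  expect_false(identical(s1$dataset, s3$dataset))
})

test_that("noiseless simulate -> fit round trip recovers all parameters", {
  for (ord in c("first", "zero")) {
    spec <- synthetic_spec(additive_sd = 0, multiplicative_sd = 0,
                           order = ord, seed = 5)
    sim <- simulate_kinetic_dataset(spec)
    temps <- vapply(spec$design, `[[`, numeric(1), "temperature")
    fits <- lapply(temps, function(tc)
      fit_kinetic(dataset_series(sim$dataset, "SYN", "TBARS", tc), ord))
    for (i in seq_along(temps)) {
      expect_equal(fits[[i]]$k, unname(sim$truth$k_by_temperature[i]),
                   tolerance = 1e-6)
      a0_hat <- if (ord == "first") exp(fits[[i]]$intercept) else
        fits[[i]]$intercept
      expect_equal(a0_hat, spec$a0, tolerance = 1e-6)
    }
    arr <- fit_arrhenius(data.frame(temperature = temps,
                                    k = vapply(fits, `[[`, numeric(1), "k")))
    expect_equal(arr$Ea, spec$Ea, tolerance = 1e-6)
    expect_equal(arr$k0, spec$k0, tolerance = 1e-6)
  }
})

test_that("noise specification is validated and floors are applied", {
  expect_error(synthetic_spec(additive_sd = -0.1), ">= 0")
  expect_error(synthetic_spec(design = list(
    list(temperature = 280, times = 0:2),
    list(temperature = 280, times = 0:2))), "distinct")
  expect_error(synthetic_spec(design = list(
    list(temperature = 280, times = 0))), "at least 2")
  # huge additive noise forces the positive floor eventually
  spec <- synthetic_spec(additive_sd = 5, seed = 2)
  expect_warning(sim <- simulate_kinetic_dataset(spec), "floored")
  for (k in names(sim$dataset))
    expect_true(all(sim$dataset[[k]]$values > 0))
})

test_that("compositional profiles stay on the simplex and drift monotonically", {
  profs <- simulate_fa_profiles(n_times = 5, n_acids = 8,
                                drift = c(-0.4, rep(0.02, 7)),
                                noise_sd = 0, seed = 3)
  expect_length(profs, 5)
  for (p in profs)
    expect_equal(sum(p$composition), 100, tolerance = 1e-9)
  # the negatively drifting acid strictly decreases
  first_acid <- vapply(profs, function(p) p$composition[[1]], numeric(1))
  expect_true(all(diff(first_acid) < 0))
  # class closure via the aggregation module
  cs <- class_totals(profs[[3]])
  expect_equal(cs$pufa_pct + cs$sfa_pct + cs$mufa_pct, 100, tolerance = 1e-9)

  # zero drift, zero noise: all profiles identical
  flat <- simulate_fa_profiles(4, 5, drift = 0, noise_sd = 0, seed = 3)
  for (i in 2:4)
    expect_equal(flat[[i]]$composition, flat[[1]]$composition)
})

test_that("sensory simulation is an affine transform with clamping", {
  expect_equal(simulate_sensory(c(0, 0.3, 0.6), 100, -100, 0, seed = 1),
               c(100, 70, 40))
  expect_equal(simulate_sensory(c(0.2, 0.2), 80, 0, 0, seed = 1), c(80, 80))
  # strictly increasing quality with negative slope: non-increasing scores
  q <- seq(0, 1, length.out = 10)
  s <- simulate_sensory(q, 120, -90, 0, seed = 1)
  expect_true(all(diff(s) <= 0))
  expect_true(all(s >= 40 & s <= 100))
  # determinism under noise
  s1 <- simulate_sensory(q, 100, -50, 3, seed = 10)
  s2 <- simulate_sensory(q, 100, -50, 3, seed = 10)
  expect_identical(s1, s2)
})

test_that("recovery experiments aggregate seeded replicates reproducibly", {
  spec <- synthetic_spec(additive_sd = 0, seed = 4)
  rec <- recovery_experiment(spec, 3)
  expect_equal(rec$ea_bias_pct, 0, tolerance = 1e-6)
  expect_equal(rec$ea_rmse_pct, 0, tolerance = 1e-6)

  # one replicate reproduces a single simulate+fit run exactly
  spec_n <- synthetic_spec(additive_sd = 0.005, seed = 30)
  rec1 <- recovery_experiment(spec_n, 1)
  sim <- simulate_kinetic_dataset(spec_n)
  temps <- vapply(spec_n$design, `[[`, numeric(1), "temperature")
  fits <- lapply(temps, function(tc)
    fit_kinetic(dataset_series(sim$dataset, "SYN", "TBARS", tc), "first"))
  arr <- fit_arrhenius(data.frame(temperature = temps,
                                  k = vapply(fits, `[[`, numeric(1), "k")))
  expect_equal(rec1$estimates$Ea, arr$Ea)
  expect_equal(rec1$estimates$k0, arr$k0)

  # bit-identical rerun of a seeded multi-rep experiment
  recA <- recovery_experiment(spec_n, 20)
  recB <- recovery_experiment(spec_n, 20)
  expect_identical(recA$estimates, recB$estimates)
  expect_identical(recA$ea_rmse_pct, recB$ea_rmse_pct)
  # RMSE dominates |bias| for every parameter
  expect_gte(recA$ea_rmse_pct, abs(recA$ea_bias_pct) - 1e-12)
})
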