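test_that("autoscaling centers and unit-scales columns", {
  a <- autoscale(cbind(x = c(1, 2, 3)))
  expect_equal(as.numeric(a$scaled), c(-1, 0, 1))
  expect_equal(unname(a$means), 2)
  expect_equal(unname(a$scales), 1)

  # idempotence on an already standardized column
  z <- a$scaled
  expect_equal(autoscale(z)$scaled, z, tolerance = 1e-12)

  expect_warning(a0 <- autoscale(cbind(k = c(5, 5, 5))), "zero-variance")
  expect_equal(as.numeric(a0$scaled), c(0, 0, 0))

  bad <- cbind(c(1, NA, 3))
  expect_error(autoscale(bad), "row 2")
})

test_that("a response equal to one predictor is explained by one component", {
  set.seed(1)
  x1 <- matrix(rnorm(8), 8, 1)
  m <- fit_pls2(x1, x1, n_components = 1)
  expect_equal(m$explained_y_pct[1], 100, tolerance = 1e-8)
  expect_equal(m$explained_x_pct[1], 100, tolerance = 1e-8)
})

test_that("component-1 weights match the dominant singular vector of X'Y", {
  set.seed(42)
  for (rep in 1:5) {
    X <- matrix(rnorm(32), 8, 4)
    Y <- matrix(rnorm(16), 8, 2)
    m <- fit_pls2(X, Y, n_components = 2)
    Xs <- autoscale(X)$scaled; Ys <- autoscale(Y)$scaled
    w_svd <- svd(crossprod(Xs, Ys))$u[, 1]
    w <- m$x_weights[, 1]
    # align sign before comparing
    if (sum(w * w_svd) < 0) w_svd <- -w_svd
    expect_equal(unname(w), w_svd, tolerance = 1e-8)
  }
})

test_that("scores of a rank-1 block align with its dominant singular vector", {
  set.seed(9)
  u <- rnorm(6); v <- rnorm(3)
  X <- u %*% t(v)
  m <- fit_pls2(X, X, n_components = 1)
  sv <- svd(autoscale(X)$scaled)$u[, 1]
  t1 <- m$x_scores[, 1]
  cosang <- abs(sum(t1 * sv)) / sqrt(sum(t1^2) * sum(sv^2))
  expect_equal(cosang, 1, tolerance = 1e-8)
})

test_that("scores are orthogonal and full extraction exhausts the X block", {
  set.seed(11)
  X <- matrix(rnorm(48), 8, 6)
  Y <- matrix(rnorm(24), 8, 3)
  A <- min(ncol(X), nrow(X) - 1)
  m <- fit_pls2(X, Y, n_components = A)
  G <- crossprod(m$x_scores)
  offdiag <- G[upper.tri(G)]
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)

  # residual X after removing all components is numerically zero
  Xs <- autoscale(X)$scaled
  Xres <- Xs - m$x_scores %*% t(m$x_loadings)
  expect_lt(sum(Xres^2) / sum(Xs^2), 1e-8)
  # per-component explained percents are non-negative and sum below 100
  expect_true(all(m$explained_x_pct >= 0))
  expect_lte(sum(m$explained_x_pct), 100 + 1e-6)
  expect_equal(sum(m$explained_x_pct), 100, tolerance = 1e-6)
})

test_that("sign convention is deterministic and sign flips are immaterial", {
  set.seed(2)
  X <- matrix(rnorm(40), 8, 5)
  Y <- matrix(rnorm(16), 8, 2)
  m1 <- fit_pls2(X, Y, 3)
  m2 <- fit_pls2(X, Y, 3)
  expect_identical(m1$x_weights, m2$x_weights)
  # largest |weight| element of each component is positive
  for (a in 1:3) {
    w <- m1$x_weights[, a]
    expect_gt(w[which.max(abs(w))], 0)
  }
  # a joint sign flip leaves reconstruction and explained variance unchanged
  recon1 <- m1$x_scores[, 1] %*% t(m1$x_loadings[, 1])
  recon_flipped <- (-m1$x_scores[, 1]) %*% t(-m1$x_loadings[, 1])
  expect_equal(recon1, recon_flipped)
})

test_that("correlation loadings equal direct variable-score correlations", {
  set.seed(4)
  X <- matrix(rnorm(32), 8, 4, dimnames = list(NULL, paste0("v", 1:4)))
  Y <- matrix(rnorm(16), 8, 2)
  m <- fit_pls2(X, Y, 2)
  r <- correlation_loadings(m, X)
  for (j in 1:4)
    for (a in 1:2)
      expect_equal(r[j, a], cor(X[, j], m$x_scores[, a]), tolerance = 1e-10)
  expect_true(all(abs(r) <= 1 + 1e-12))
  # a variable proportional to a score correlates at +/- 1
  X2 <- cbind(X, exact = m$x_scores[, 1])
  r2 <- correlation_loadings(m, X2)
  expect_equal(abs(r2["exact", 1]), 1, tolerance = 1e-10)
})

test_that("the storage-condition PUFA design fits and reports variance shares", {
  d <- pufa_design()
  expect_equal(dim(d$X), c(14, 19))
  expect_equal(dim(d$Y), c(14, 22))
  expect_true(all(d$X[, 1:17] %in% c(0, 1)))
  m <- fit_pls2(d$X, d$Y, n_components = 2)
  expect_true(all(m$explained_y_pct > 0))
  expect_lte(sum(m$explained_y_pct), 100 + 1e-6)
  r <- correlation_loadings(m, d$Y)
  expect_true(all(abs(r) <= 1 + 1e-12, na.rm = TRUE))
})
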