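#' Column-wise autoscaling (unit-variance standardization)
#'
#' Centers each column to mean zero and scales it to unit sample standard
#' deviation (n - 1 denominator). Zero-variance columns are centered and
#' given scale 1, with a warning — they carry no information but must not
#' produce NaNs downstream.
#'
#' @param x Numeric matrix (samples x variables), at least 2 rows, no
#'   missing cells.
#' @return A list with `scaled` (matrix), `means` and `scales` (per-column
#'   vectors).
#' @examples
#' autoscale(cbind(a = c(1, 2, 3)))$scaled  # -1 0 1
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("autoscaling needs at least 2 samples", call. = FALSE)
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop(sprintf("missing cell at row %d, column %d", idx[1], idx[2]),
         call. = FALSE)
  }
  means <- colMeans(x)
  scales <- apply(x, 2, stats::sd)
  zero <- scales == 0
  if (any(zero)) {
    warning("zero-variance column(s) scaled by 1: ",
            paste(colnames(x)[zero], collapse = ", "))
    scales[zero] <- 1
  }
  scaled <- sweep(sweep(x, 2, means, "-"), 2, scales, "/")
  list(scaled = scaled, means = means, scales = scales)
}

#' Two-block partial least squares regression by NIPALS
#'
#' Fits a PLS2 model relating a predictor block X (samples x p) to a
#' multivariate response block Y (samples x q). Both blocks are
#' autoscaled; components are then extracted one at a time by the NIPALS
#' iteration — alternating regressions that converge on the X-weight
#' vector — followed by deflation of both blocks on the X-scores. The
#' Y block is deflated by regression of Y on the X-scores, so per-block
#' explained variances are the sums of squares each component removes,
#' as a percentage of the scaled block's total.
#'
#' Sign convention: the largest-magnitude element of each X-weight vector
#' is forced positive, making the decomposition deterministic.
#'
#' @param X,Y Numeric matrices with the same number of rows.
#' @param n_components Number of components; at most `min(nrow - 1, ncol(X))`.
#' @param tol Convergence tolerance on the change of the X-weight vector;
#'   default 1e-10.
#' @param max_iter Iteration cap per component (default 500); hitting it
#'   records a warning but keeps the component.
#' @return An object of class `pls_model` with standardization parameters
#'   (`x_means`, `x_scales`, `y_means`, `y_scales`), per-component
#'   `x_weights`, `x_loadings`, `y_loadings` (columns = components),
#'   `x_scores` (n x A), `explained_x_pct`, `explained_y_pct`,
#'   `iterations` and `converged` per component.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(32), 8, 4)
#' m <- fit_pls2(X, X[, 1, drop = FALSE], n_components = 1)
#' round(m$explained_y_pct, 6)  # 100: Y is one X column
#' @export
fit_pls2 <- function(X, Y, n_components, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop("X and Y must have the same number of samples", call. = FALSE)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (n_components < 1 || n_components > min(n - 1, p))
    stop("n_components must be between 1 and min(samples - 1, ncol(X))",
         call. = FALSE)
  sx <- autoscale(X); sy <- autoscale(Y)
  Xc <- sx$scaled; Yc <- sy$scaled
  ss0x <- sum(Xc^2); ss0y <- sum(Yc^2)

  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  C <- matrix(0, q, n_components)
  Tm <- matrix(0, n, n_components)
  evx <- evy <- numeric(n_components)
  iters <- integer(n_components)
  conv <- logical(n_components)

  for (a in seq_len(n_components)) {
    u <- Yc[, which.max(colSums(Yc^2)), drop = TRUE]
    if (sum(u^2) == 0) u <- Xc[, which.max(colSums(Xc^2)), drop = TRUE]
    w_old <- rep(0, p)
    it <- 0L
    repeat {
      it <- it + 1L
      w <- crossprod(Xc, u) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      t_score <- Xc %*% w
      cvec <- crossprod(Yc, t_score) / sum(t_score^2)
      denom <- sum(cvec^2)
      u <- if (denom > 0) Yc %*% cvec / denom else t_score
      if (sqrt(sum((w - w_old)^2)) < tol || it >= max_iter) break
      w_old <- w
    }
    if (it >= max_iter && sqrt(sum((w - w_old)^2)) >= tol)
      warning(sprintf("component %d did not converge in %d iterations", a, max_iter))
    conv[a] <- it < max_iter
    iters[a] <- it
    # deterministic sign: largest |weight| positive
    if (w[which.max(abs(w))] < 0) {
      w <- -w; t_score <- -t_score; cvec <- -cvec
    }
    pvec <- crossprod(Xc, t_score) / sum(t_score^2)
    Xhat <- t_score %*% t(pvec)
    Yhat <- t_score %*% t(cvec)
    Xc <- Xc - Xhat
    Yc <- Yc - Yhat
    W[, a] <- w; P[, a] <- pvec; C[, a] <- cvec; Tm[, a] <- t_score
    evx[a] <- 100 * sum(Xhat^2) / ss0x
    evy[a] <- 100 * sum(Yhat^2) / ss0y
  }
  dimnames(W) <- list(colnames(X), paste0("comp", seq_len(n_components)))
  dimnames(P) <- dimnames(W)
  dimnames(C) <- list(colnames(Y), colnames(W))
  dimnames(Tm) <- list(rownames(X), colnames(W))
  structure(
    list(n_components = n_components,
         x_means = sx$means, x_scales = sx$scales,
         y_means = sy$means, y_scales = sy$scales,
         x_weights = W, x_loadings = P, y_loadings = C, x_scores = Tm,
         explained_x_pct = evx, explained_y_pct = evy,
         iterations = iters, converged = conv, tol = tol),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d X variable(s), %d Y variable(s)\n",
              x$n_components, nrow(x$x_weights), nrow(x$y_loadings)))
  df <- data.frame(component = seq_len(x$n_components),
                   explained_X_pct = round(x$explained_x_pct, 2),
                   explained_Y_pct = round(x$explained_y_pct, 2),
                   iterations = x$iterations)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Correlation loadings of a fitted PLS model
#'
#' Pearson correlation of each original variable with each component
#' score. Plotted against components 1 and 2 these place every variable
#' inside the unit circle, with reference circles at r^2 = 0.5 and
#' r^2 = 1 in the conventional loading plot.
#'
#' @param model A fitted [fit_pls2()] model.
#' @param data The original (unscaled) block the variables come from —
#'   the X block, the Y block, or any matrix with the same samples.
#' @return Matrix (variables x components) of correlations in [-1, 1];
#'   NA for zero-variance variables.
#' @export
correlation_loadings <- function(model, data) {
  if (!inherits(model, "pls_model"))
    stop("'model' must be a fitted pls_model", call. = FALSE)
  data <- as.matrix(data)
  if (nrow(data) != nrow(model$x_scores))
    stop("'data' must have the same samples as the fitted model", call. = FALSE)
  r <- suppressWarnings(stats::cor(data, model$x_scores))
  colnames(r) <- colnames(model$x_scores)
  r
}
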