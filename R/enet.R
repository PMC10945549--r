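# Elastic-net core: standardization, lambda grids, path fitting, LOOCV.
#
# The solver minimizes
#   (1/(2n)) sum_i (y_i - b0 - x_i'b)^2 + lambda ((1-alpha)/2 ||b||_2^2
#                                                + alpha ||b||_1)
# with predictors standardized internally to zero mean and unit (1/n)
# variance; coefficients are reported back on the original predictor scale.

# Standardization summary of a predictor matrix. Constant columns (population
# sd ~ 0) are dropped: their Gram rows/columns are zero and the solver never
# touches them, so their coefficients are exactly 0.
.prep_X <- function(X) {
  n <- nrow(X)
  xm <- colMeans(X)
  xc <- sweep(X, 2L, xm, "-")
  xs <- sqrt(colMeans(xc * xc))
  keep <- xs > 1e-10 * max(xs, 1)
  Xs <- matrix(0, n, ncol(X), dimnames = dimnames(X))
  if (any(keep))
    Xs[, keep] <- sweep(xc[, keep, drop = FALSE], 2L, xs[keep], "/")
  list(n = n, p = ncol(X), xm = xm, xs = xs, keep = keep,
       Xs = Xs, G = crossprod(Xs) / n)
}

.prep_y <- function(prepX, y) {
  ym <- mean(y)
  list(ym = ym, cvec = drop(crossprod(prepX$Xs, y - ym)) / prepX$n)
}

# Default decreasing log-spaced lambda grid. lambda_max is the smallest
# penalty with an all-zero solution; for alpha < 0.05 the 0.05 floor keeps the
# grid finite as the lasso part vanishes.
.default_lambda <- function(cvec, alpha, nlambda, lambda_min_ratio) {
  lmax <- max(max(abs(cvec)), 1e-12) / max(alpha, 0.05)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

# Back-transform one standardized-scale solution column to the original scale.
.orig_scale <- function(prepX, ym, b_std) {
  beta <- numeric(prepX$p)
  names(beta) <- colnames(prepX$Xs)
  beta[prepX$keep] <- b_std[prepX$keep] / prepX$xs[prepX$keep]
  list(intercept = ym - sum(beta * prepX$xm), beta = beta)
}

# Pure ridge (alpha = 0) has a closed form; one eigendecomposition of the
# Gram matrix yields the whole path at once.
.ridge_path_gram <- function(G, cvec, lambda) {
  keep <- which(diag(G) > 0)
  B <- matrix(0, length(cvec), length(lambda))
  if (length(keep)) {
    eg <- eigen(G[keep, keep, drop = FALSE], symmetric = TRUE)
    vc <- drop(crossprod(eg$vectors, cvec[keep]))
    B[keep, ] <- eg$vectors %*% (vc / outer(pmax(eg$values, 0), lambda, "+"))
  }
  B
}

.path_gram <- function(G, cvec, lambda, alpha, tol, maxit) {
  if (alpha == 0) return(.ridge_path_gram(G, cvec, lambda))
  .enet_path_gram(G, cvec, lambda, alpha, tol, as.integer(maxit))
}

.check_xy <- function(X, y) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("X must be a numeric matrix", call. = FALSE)
  if (anyNA(X) || !all(is.finite(X)))
    stop("X contains missing or non-finite values", call. = FALSE)
  if (length(y) != nrow(X))
    stop("length(y) must equal nrow(X)", call. = FALSE)
  if (anyNA(y) || !all(is.finite(y)))
    stop("y contains missing or non-finite values", call. = FALSE)
  if (nrow(X) < 3)
    stop("insufficient data: at least 3 drugs (rows) are required",
         call. = FALSE)
  invisible(TRUE)
}

.check_lambda <- function(lambda) {
  if (anyNA(lambda) || any(lambda < 0))
    stop("lambda values must be non-negative", call. = FALSE)
  if (length(lambda) > 1 && any(diff(lambda) >= 0))
    stop("lambda grid must be strictly decreasing", call. = FALSE)
  invisible(TRUE)
}

#' Fit an elastic-net regularization path
#'
#' Fits penalized linear regressions of a response on a drug-by-kinase
#' residual-activity matrix along a decreasing penalty path, for a fixed
#' mixing parameter `alpha` (`alpha = 1` is the lasso, `alpha = 0` ridge).
#' Predictors are standardized to zero mean and unit variance internally;
#' returned coefficients are on the original predictor scale. Constant
#' predictor columns are dropped with a warning and carry coefficient 0.
#'
#' @param X numeric matrix, drugs in rows, kinases in columns (residual
#'   activity, percent of uninhibited control).
#' @param y numeric response vector, one value per drug.
#' @param alpha elastic-net mixing parameter in `[0, 1]`.
#' @param lambda optional decreasing vector of penalties; by default a
#'   log-spaced grid of `nlambda` values from the smallest all-zero penalty
#'   down by a factor `lambda_min_ratio`.
#' @param nlambda,lambda_min_ratio default grid size and span.
#' @param tol solver tolerance on the largest KKT stationarity violation
#'   (standardized scale); solutions are optimal to well within this.
#' @param maxit maximum coordinate-descent sweeps per penalty.
#' @return An object of class `"enet_path"`: list with `alpha`, `lambda`,
#'   `a0` (intercepts), `beta` (p x nlambda coefficient matrix, original
#'   scale), `df` (nonzero counts) and `dropped` (constant columns).
#' @seealso [loocv_select()] for penalty selection, [fit_kir_model()] for the
#'   full per-cytokine procedure.
#' @examples
#' set.seed(1)
#' X <- matrix(runif(30 * 8, 0, 100), 30, 8,
#'             dimnames = list(NULL, paste0("K", 1:8)))
#' y <- 1 - 0.004 * X[, 1] + rnorm(30, sd = 0.02)
#' fit <- fit_elastic_net(X, y, alpha = 0.5)
#' fit$beta[, 50]
#' @export
fit_elastic_net <- function(X, y, alpha, lambda = NULL, nlambda = 100,
                            lambda_min_ratio = 1e-3, tol = 1e-9,
                            maxit = 500L) {
  .check_xy(X, y)
  if (length(alpha) != 1 || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  prepX <- .prep_X(X)
  if (any(!prepX$keep))
    warning("constant predictor column(s) dropped (coefficient set to 0): ",
            paste(colnames(X)[!prepX$keep], collapse = ", "), call. = FALSE)
  py <- .prep_y(prepX, y)
  if (is.null(lambda))
    lambda <- .default_lambda(py$cvec, alpha, nlambda, lambda_min_ratio)
  .check_lambda(lambda)
  B <- .path_gram(prepX$G, py$cvec, lambda, alpha, tol, maxit)
  beta <- matrix(0, prepX$p, length(lambda),
                 dimnames = list(colnames(X), NULL))
  a0 <- numeric(length(lambda))
  for (l in seq_along(lambda)) {
    sol <- .orig_scale(prepX, py$ym, B[, l])
    beta[, l] <- sol$beta
    a0[l] <- sol$intercept
  }
  structure(list(alpha = alpha, lambda = lambda, a0 = a0, beta = beta,
                 df = colSums(beta != 0), dropped = colnames(X)[!prepX$keep],
                 nobs = nrow(X)),
            class = "enet_path")
}

#' Predict from an elastic-net path
#'
#' @param object an `"enet_path"` from [fit_elastic_net()].
#' @param newx matrix of predictor rows (same kinase columns as the fit).
#' @param s optional penalty value(s); each is matched to the nearest grid
#'   point. Default: the whole path.
#' @param ... unused.
#' @return Matrix of predictions, rows = rows of `newx`, one column per
#'   requested penalty.
#' @export
predict.enet_path <- function(object, newx, s = NULL, ...) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  idx <- if (is.null(s)) seq_along(object$lambda)
         else vapply(s, function(si) which.min(abs(object$lambda - si)), 1L)
  sweep(newx %*% object$beta[, idx, drop = FALSE], 2L, object$a0[idx], "+")
}

#' @export
print.enet_path <- function(x, ...) {
  cat(sprintf("Elastic-net path: alpha = %g, %d penalties, %d predictors\n",
              x$alpha, length(x$lambda), nrow(x$beta)))
  if (length(x$dropped))
    cat("Dropped constant columns:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

# Per-fold standardization summaries shared across responses and alphas.
# Each fold holds the prep of X[-i, ] plus the standardized left-out row.
.fold_preps <- function(X) {
  n <- nrow(X)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    prep <- .prep_X(X[-i, , drop = FALSE])
    xnew <- numeric(prep$p)
    xnew[prep$keep] <- (X[i, prep$keep] - prep$xm[prep$keep]) /
      prep$xs[prep$keep]
    folds[[i]] <- list(prep = prep, xnew = xnew)
  }
  list(full = .prep_X(X), folds = folds)
}

# LOOCV over the drug folds for one alpha on a fixed lambda grid.
# Returns the n x nlambda matrix of single-left-out predictions.
.loocv_pred <- function(preps, y, alpha, lambda, tol, maxit) {
  n <- length(y)
  pred <- matrix(NA_real_, n, length(lambda))
  for (i in seq_len(n)) {
    f <- preps$folds[[i]]
    py <- .prep_y(f$prep, y[-i])
    B <- .path_gram(f$prep$G, py$cvec, lambda, alpha, tol, maxit)
    pred[i, ] <- py$ym + drop(crossprod(B, f$xnew))
  }
  pred
}

# Assemble one selected solution for a given alpha: LOOCV curve, selected
# lambda (ties broken toward the larger, sparser penalty), full-data refit.
.select_solution <- function(preps, y, alpha, lambda, tol, maxit) {
  pred <- .loocv_pred(preps, y, alpha, lambda, tol, maxit)
  cv_mse <- colMeans((y - pred)^2)
  best <- which.min(cv_mse)  # first minimum = largest lambda on ties
  pyf <- .prep_y(preps$full, y)
  B <- .path_gram(preps$full$G, pyf$cvec, lambda, alpha, tol, maxit)
  sol <- .orig_scale(preps$full, pyf$ym, B[, best])
  structure(list(alpha = alpha, lambda = lambda[best],
                 intercept = sol$intercept, coefficients = sol$beta,
                 loocv_mse = cv_mse[best], loocv_pred = pred[, best],
                 lambda_grid = lambda, cv_mse = cv_mse,
                 dropped = colnames(preps$full$Xs)[!preps$full$keep],
                 nobs = length(y)),
            class = "enet_solution")
}

#' Select the elastic-net penalty by leave-one-out cross-validation
#'
#' For a fixed mixing parameter, computes the mean squared error of
#' single-left-out predictions at every penalty on the grid (folds are the n
#' drugs, in order, no shuffling: the procedure is deterministic) and returns
#' the full-data fit at the penalty minimizing LOOCV MSE. Ties are broken
#' toward the larger penalty, i.e. the sparser model. The lambda grid is
#' computed once on the full data so fold errors are comparable.
#'
#' @inheritParams fit_elastic_net
#' @return An object of class `"enet_solution"`: `alpha`, selected `lambda`,
#'   `intercept`, `coefficients` (original scale, named by kinase),
#'   `loocv_mse`, `loocv_pred` (the n held-out predictions at the selected
#'   penalty), plus the full `lambda_grid` and `cv_mse` curve.
#' @examples
#' set.seed(1)
#' X <- matrix(runif(20 * 5, 0, 100), 20, 5,
#'             dimnames = list(NULL, paste0("K", 1:5)))
#' y <- 0.8 - 0.003 * X[, 2]
#' sol <- loocv_select(X, y, alpha = 1)
#' sol$loocv_mse
#' @export
loocv_select <- function(X, y, alpha, lambda = NULL, nlambda = 100,
                         lambda_min_ratio = 1e-3, tol = 1e-9,
                         maxit = 500L) {
  .check_xy(X, y)
  if (length(alpha) != 1 || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  preps <- .fold_preps(X)
  if (is.null(lambda)) {
    py <- .prep_y(preps$full, y)
    lambda <- .default_lambda(py$cvec, alpha, nlambda, lambda_min_ratio)
  }
  .check_lambda(lambda)
  .select_solution(preps, y, alpha, lambda, tol, maxit)
}

#' @export
print.enet_solution <- function(x, ...) {
  cat(sprintf(
    "Elastic-net solution: alpha = %g, lambda = %.4g, LOOCV MSE = %.4g, %d nonzero\n",
    x$alpha, x$lambda, x$loocv_mse, sum(x$coefficients != 0)))
  invisible(x)
}
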