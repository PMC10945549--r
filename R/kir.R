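# Per-cytokine KiR models: alpha sweep, quality gating, informative-kinase
# calling, and out-of-panel prediction.

#' Fit a KiR model for one secreted factor
#'
#' Fits elastic-net regressions of one cytokine's response on the drug-kinase
#' residual-activity matrix for every mixing parameter in `alpha_grid`
#' (default: 11 evenly spaced values from 0 to 1 inclusive), selecting the
#' penalty for each by leave-one-out cross-validation over the drugs. Model
#' quality (normalized root MSE and Pearson correlation of held-out
#' predictions) is assessed on the best solution across the grid, and
#' informative kinases are those with a positive coefficient in at least one
#' selected solution with `alpha > 0` (the ridge end of the grid never
#' produces exact zeros, so it is excluded from hit calling).
#'
#' @inheritParams fit_elastic_net
#' @param alpha_grid vector of mixing parameters swept.
#' @param nrmse_threshold,pearson_threshold acceptance gate: a model is
#'   accepted when nRMSE is below `nrmse_threshold` **and** the correlation
#'   exceeds `pearson_threshold` (both strict).
#' @param coef_tol positive-coefficient tolerance for hit calling; guards
#'   against float noise at the sparsity boundary.
#' @param cytokine_id optional identifier stored in the model.
#' @param .preps internal: precomputed fold standardizations (shared across
#'   cytokines by [fit_kir_models()]).
#' @return An object of class `"kir_model"`: `cytokine_id`, `solutions` (one
#'   [loocv_select()] result per alpha), `best_alpha` (lowest LOOCV MSE across
#'   the whole grid, including alpha = 0), `quality` (see [evaluate_model()]),
#'   `informative_kinases`, `kinase_ids` and the response `y`.
#' @examples
#' sim <- simulate_screen(sim_config(n_screen_drugs = 12, n_kinases = 8,
#'                                   n_cytokines = 1, k_planted = 2, seed = 1))
#' m <- fit_kir_model(sim$x_screen, sim$y_screen[, 1], nlambda = 30)
#' m$informative_kinases
#' @export
fit_kir_model <- function(X, y, alpha_grid = seq(0, 1, by = 0.1),
                          lambda = NULL, nlambda = 100,
                          lambda_min_ratio = 1e-3,
                          nrmse_threshold = 0.1, pearson_threshold = 0.85,
                          coef_tol = 1e-8, cytokine_id = NULL,
                          tol = 1e-9, maxit = 500L, .preps = NULL) {
  .check_xy(X, y)
  if (length(alpha_grid) < 1 || anyNA(alpha_grid) ||
      any(alpha_grid < 0 | alpha_grid > 1))
    stop("alpha_grid values must lie in [0, 1]", call. = FALSE)
  if (max(y) == min(y))
    stop("zero response variance: cytokine cannot be fitted", call. = FALSE)
  if (is.null(.preps)) .preps <- .fold_preps(X)
  pyf <- .prep_y(.preps$full, y)
  solutions <- lapply(alpha_grid, function(a) {
    lam <- if (is.null(lambda))
      .default_lambda(pyf$cvec, a, nlambda, lambda_min_ratio)
    else lambda
    .check_lambda(lam)
    .select_solution(.preps, y, a, lam, tol, maxit)
  })
  names(solutions) <- format(alpha_grid)
  model <- structure(
    list(cytokine_id = cytokine_id, alpha_grid = alpha_grid,
         solutions = solutions,
         best_alpha = alpha_grid[which.min(
           vapply(solutions, `[[`, numeric(1), "loocv_mse"))],
         kinase_ids = colnames(X), y = y,
         coef_tol = coef_tol, quality = NULL, informative_kinases = NULL),
    class = "kir_model")
  model$quality <- evaluate_model(model, y, nrmse_threshold, pearson_threshold)
  model$informative_kinases <- call_informative_kinases(model, coef_tol)
  model
}

# Best (lowest LOOCV MSE) solution of a fitted model.
.best_solution <- function(model) {
  model$solutions[[which(model$alpha_grid == model$best_alpha)[1]]]
}

#' Call informative kinases from a fitted KiR model
#'
#' A kinase is informative for a cytokine when its coefficient exceeds `tol`
#' (i.e. is positive) in the selected solution for at least one mixing
#' parameter with `alpha > 0`. The `alpha = 0` (pure ridge) solution is always
#' excluded: it has nonzero coefficients for every kinase and would call
#' everything.
#'
#' @param model a `"kir_model"`.
#' @param tol positive-coefficient tolerance.
#' @return Character vector of kinase identifiers (possibly empty).
#' @export
call_informative_kinases <- function(model, tol = 1e-8) {
  stopifnot(inherits(model, "kir_model"))
  hits <- character(0)
  for (sol in model$solutions) {
    if (sol$alpha == 0) next
    hits <- union(hits, names(sol$coefficients)[sol$coefficients > tol])
  }
  sort(hits)
}

#' Assess KiR model quality from held-out predictions
#'
#' Uses the best-alpha solution's leave-one-out predictions `yhat`:
#' `nrmse = sqrt(mean((y - yhat)^2)) / (max(y) - min(y))` and
#' `pearson_r = cor(y, yhat)`. A model is accepted when `nrmse <
#' nrmse_threshold` and `pearson_r > pearson_threshold`. Degenerate cases
#' (constant response: nRMSE undefined; constant predictions: correlation
#' undefined) are rejected with an explanatory flag.
#'
#' @param model a `"kir_model"`.
#' @param y the response the model was fitted on.
#' @param nrmse_threshold,pearson_threshold acceptance gate.
#' @return An object of class `"model_quality"`: `nrmse`, `pearson_r`,
#'   `accepted`, `reason` (`NA` when accepted).
#' @export
evaluate_model <- function(model, y, nrmse_threshold = 0.1,
                           pearson_threshold = 0.85) {
  stopifnot(inherits(model, "kir_model"))
  yhat <- .best_solution(model)$loocv_pred
  rng <- max(y) - min(y)
  if (rng == 0) {
    return(structure(list(nrmse = NA_real_, pearson_r = NA_real_,
                          accepted = FALSE,
                          reason = "constant response: nRMSE undefined"),
                     class = "model_quality"))
  }
  nrmse <- sqrt(mean((y - yhat)^2)) / rng
  r <- if (sd(yhat) == 0) NA_real_ else cor(y, yhat)
  accepted <- isTRUE(nrmse < nrmse_threshold && !is.na(r) &&
                     r > pearson_threshold)
  reason <- if (accepted) NA_character_
            else if (is.na(r)) "constant predictions: correlation undefined"
            else sprintf("nrmse = %.3g (gate < %g), r = %.3g (gate > %g)",
                         nrmse, nrmse_threshold, r, pearson_threshold)
  structure(list(nrmse = nrmse, pearson_r = r, accepted = accepted,
                 reason = reason),
            class = "model_quality")
}

#' @export
print.model_quality <- function(x, ...) {
  cat(sprintf("nRMSE = %.4g, Pearson r = %.4g -> %s\n",
              x$nrmse, x$pearson_r,
              if (x$accepted) "accepted" else paste("rejected:", x$reason)))
  invisible(x)
}

#' @export
print.kir_model <- function(x, ...) {
  cat(sprintf("KiR model%s: %d alpha values, best alpha = %g\n",
              if (is.null(x$cytokine_id)) "" else paste0(" [", x$cytokine_id, "]"),
              length(x$solutions), x$best_alpha))
  print(x$quality)
  cat(sprintf("Informative kinases (%d): %s\n",
              length(x$informative_kinases),
              paste(head(x$informative_kinases, 10), collapse = ", ")))
  invisible(x)
}

#' Fit KiR models for every cytokine of a screen
#'
#' Loops [fit_kir_model()] over the columns of the response table. Cytokines
#' with zero response variance are skipped (not fitted) and recorded with a
#' reason. Fold standardizations of `X` are computed once and shared.
#'
#' @inheritParams fit_kir_model
#' @param Y numeric matrix of responses, drugs in rows (aligned with `X`),
#'   cytokines in columns.
#' @param verbose print a progress line per skipped cytokine.
#' @return An object of class `"kir_model_set"`: named list `models` and a
#'   data frame `skipped` (cytokine, reason).
#' @examples
#' sim <- simulate_screen(sim_config(n_screen_drugs = 12, n_kinases = 8,
#'                                   n_cytokines = 2, k_planted = 2, seed = 1))
#' fits <- fit_kir_models(sim$x_screen, sim$y_screen, nlambda = 30)
#' summary(fits)
#' @export
fit_kir_models <- function(X, Y, alpha_grid = seq(0, 1, by = 0.1),
                           lambda = NULL, nlambda = 100,
                           lambda_min_ratio = 1e-3,
                           nrmse_threshold = 0.1, pearson_threshold = 0.85,
                           coef_tol = 1e-8, tol = 1e-9, maxit = 500L,
                           verbose = FALSE) {
  if (!is.matrix(Y) || nrow(Y) != nrow(X))
    stop("Y must be a matrix with one row per drug of X", call. = FALSE)
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop("drug ids of X and Y do not align", call. = FALSE)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("cytokine", seq_len(ncol(Y)))
  preps <- .fold_preps(X)
  models <- list()
  skipped <- data.frame(cytokine = character(0), reason = character(0))
  for (cy in colnames(Y)) {
    y <- Y[, cy]
    if (max(y) == min(y)) {
      skipped <- rbind(skipped,
                       data.frame(cytokine = cy,
                                  reason = "zero response variance"))
      if (verbose) message("skipping ", cy, ": zero response variance")
      next
    }
    models[[cy]] <- fit_kir_model(
      X, y, alpha_grid = alpha_grid, lambda = lambda, nlambda = nlambda,
      lambda_min_ratio = lambda_min_ratio, nrmse_threshold = nrmse_threshold,
      pearson_threshold = pearson_threshold, coef_tol = coef_tol,
      cytokine_id = cy, tol = tol, maxit = maxit, .preps = preps)
  }
  structure(list(models = models, skipped = skipped), class = "kir_model_set")
}

#' @export
summary.kir_model_set <- function(object, ...) {
  rows <- lapply(object$models, function(m) {
    sol <- .best_solution(m)
    data.frame(cytokine = m$cytokine_id, best_alpha = m$best_alpha,
               lambda = sol$lambda, loocv_mse = sol$loocv_mse,
               nrmse = m$quality$nrmse, pearson_r = m$quality$pearson_r,
               accepted = m$quality$accepted,
               n_informative = length(m$informative_kinases))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame()
  out
}

#' @export
print.kir_model_set <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("KiR model set: %d fitted (%d accepted), %d skipped\n",
              length(x$models), if (nrow(s)) sum(s$accepted) else 0L,
              nrow(x$skipped)))
  if (nrow(s)) print(s)
  invisible(x)
}

#' Accepted models of a KiR model set
#'
#' @param models a `"kir_model_set"`.
#' @return The subset of models passing the quality gate (a named list).
#' @export
accepted_models <- function(models) {
  stopifnot(inherits(models, "kir_model_set"))
  Filter(function(m) isTRUE(m$quality$accepted), models$models)
}

.as_model_list <- function(models, accepted_only) {
  lst <- if (inherits(models, "kir_model_set")) {
    if (accepted_only) accepted_models(models) else models$models
  } else if (inherits(models, "kir_model")) {
    setNames(list(models), models$cytokine_id %||% "cytokine1")
  } else if (is.list(models)) {
    if (accepted_only) Filter(function(m) isTRUE(m$quality$accepted), models)
    else models
  } else stop("models must be a kir_model, a list, or a kir_model_set",
              call. = FALSE)
  if (is.null(names(lst)) && length(lst))
    names(lst) <- vapply(seq_along(lst), function(i)
      lst[[i]]$cytokine_id %||% paste0("cytokine", i), "")
  lst
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict secretion responses for an unscreened inhibitor panel
#'
#' Applies each cytokine's best-alpha solution (lowest LOOCV MSE across the
#' whole alpha grid) to the panel's residual-activity rows:
#' `level = b0 + x'b`. A pseudo-drug row of all 100 (no inhibition) predicts
#' the model's fitted control level. By default only models passing the
#' quality gate are used.
#'
#' @param models a `"kir_model_set"`, a list of `"kir_model"`, or one model.
#' @param X_panel numeric matrix, panel drugs x kinases; its columns must
#'   cover every kinase with a nonzero coefficient in the models used.
#' @param accepted_only predict only from accepted models (default `TRUE`).
#' @return Numeric matrix of predicted levels (fraction of the LPS-only
#'   control), panel drugs in rows, cytokines in columns.
#' @export
predict_out_of_panel <- function(models, X_panel, accepted_only = TRUE) {
  lst <- .as_model_list(models, accepted_only)
  if (!length(lst))
    stop("no models to predict from (all rejected by the quality gate?)",
         call. = FALSE)
  if (!is.matrix(X_panel) || is.null(colnames(X_panel)))
    stop("X_panel must be a matrix with kinase column names", call. = FALSE)
  pred <- matrix(NA_real_, nrow(X_panel), length(lst),
                 dimnames = list(rownames(X_panel), names(lst)))
  for (cy in names(lst)) {
    sol <- .best_solution(lst[[cy]])
    nz <- names(sol$coefficients)[sol$coefficients != 0]
    missing <- setdiff(nz, colnames(X_panel))
    if (length(missing))
      stop("kinase column(s) missing from the panel matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    pred[, cy] <- sol$intercept +
      if (length(nz)) drop(X_panel[, nz, drop = FALSE] %*%
                             sol$coefficients[nz]) else 0
  }
  pred
}
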