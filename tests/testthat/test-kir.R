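# Per-cytokine KiR models: alpha sweep structure, hit calling, quality
# gating, and out-of-panel prediction.

test_that("the default alpha grid fits 11 solutions from 0 to 1 inclusive", {
  prob <- rand_problem(15, 8, seed = 401)
  m <- fit_kir_model(prob$X, prob$y, nlambda = 30)
  expect_length(m$solutions, 11)
  expect_equal(m$alpha_grid, seq(0, 1, by = 0.1))
  expect_equal(vapply(m$solutions, `[[`, 1, "alpha"),
               setNames(seq(0, 1, by = 0.1), names(m$solutions)))
})

test_that("the ridge solution keeps every kinase nonzero on generic data", {
  prob <- rand_problem(15, 8, seed = 402)
  m <- fit_kir_model(prob$X, prob$y, nlambda = 30)
  ridge <- m$solutions[["0.0"]]
  expect_equal(ridge$alpha, 0)
  expect_true(all(ridge$coefficients != 0))
})

test_that("hit calling takes positive coefficients and excludes the ridge model", {
  kn <- sprintf("K%02d", 1:4)
  m <- mock_kir_model(list(
    "0"   = setNames(c(1, 1, 1, 1), kn),        # ridge: everything positive
    "0.5" = setNames(c(0.2, -0.3, 0, 1e-12), kn),
    "1"   = setNames(c(0, 0, 0, 0), kn)))
  # only K01: positive above tolerance in an alpha > 0 model; K02 is negative,
  # K04 is below tolerance, and the ridge model's positives never count
  expect_equal(call_informative_kinases(m), "K01")
  # all-null solutions for alpha > 0 give an empty set
  m2 <- mock_kir_model(list("0" = setNames(rep(1, 4), kn),
                            "1" = setNames(rep(0, 4), kn)))
  expect_length(call_informative_kinases(m2), 0)
})

test_that("the quality gate is strict at both thresholds", {
  y <- seq(0, 1, length.out = 10)
  gate <- function(yhat) {
    m <- mock_kir_model(list("0.5" = setNames(1, "K01")), loocv_pred = yhat)
    evaluate_model(m, y)
  }
  perfect <- gate(y)
  expect_equal(perfect$nrmse, 0)
  expect_equal(perfect$pearson_r, 1)
  expect_true(perfect$accepted)
  # nRMSE exactly at 0.1 with perfect correlation: rejected (strict <)
  at_gate <- gate(y + 0.1)
  expect_equal(at_gate$nrmse, 0.1)
  expect_false(at_gate$accepted)
  # r exactly at 0.85 cannot pass; anticorrelated predictions certainly not
  expect_false(gate(rev(y))$accepted)
  # constant predictions: correlation undefined, rejected with a flag
  flat <- gate(rep(mean(y), 10))
  expect_false(flat$accepted)
  expect_match(flat$reason, "constant predictions")
})

test_that("constant responses are rejected and skipped, never fitted", {
  prob <- rand_problem(12, 5, seed = 403)
  expect_error(fit_kir_model(prob$X, rep(1, 12)), "zero response variance")
  Y <- cbind(a = prob$y, b = rep(1, 12))
  fits <- fit_kir_models(prob$X, Y, nlambda = 20)
  expect_equal(names(fits$models), "a")
  expect_equal(fits$skipped$cytokine, "b")
  expect_match(fits$skipped$reason, "zero response variance")
  q <- evaluate_model(fits$models[["a"]], rep(1, 12))
  expect_false(q$accepted)
  expect_match(q$reason, "constant response")
})

test_that("panel prediction reproduces fitted values and the control level", {
  cfg <- sim_config(n_screen_drugs = 16, n_panel_drugs = 6, n_kinases = 10,
                    n_cytokines = 2, k_planted = 2, noise_sd = 0.01, seed = 404)
  sim <- simulate_screen(cfg)
  fits <- fit_kir_models(sim$x_screen, sim$y_screen, nlambda = 40)
  pred <- predict_out_of_panel(fits, sim$x_screen, accepted_only = FALSE)
  for (cy in names(fits$models)) {
    sol <- fits$models[[cy]]$solutions[[
      which(fits$models[[cy]]$alpha_grid == fits$models[[cy]]$best_alpha)]]
    fitted <- sol$intercept + drop(sim$x_screen %*% sol$coefficients)
    expect_equal(unname(pred[, cy]), unname(fitted), tolerance = 1e-12)
  }
  # a pseudo-drug inhibiting nothing predicts the fitted control level
  pseudo <- matrix(100, 1, 10, dimnames = list("none", colnames(sim$x_screen)))
  p0 <- predict_out_of_panel(fits, pseudo, accepted_only = FALSE)
  for (cy in names(fits$models)) {
    sol <- fits$models[[cy]]$solutions[[
      which(fits$models[[cy]]$alpha_grid == fits$models[[cy]]$best_alpha)]]
    expect_equal(unname(p0[, cy]),
                 sol$intercept + 100 * sum(sol$coefficients),
                 tolerance = 1e-12)
  }
})

test_that("a missing panel kinase raises an error naming it", {
  cfg <- sim_config(n_screen_drugs = 14, n_panel_drugs = 4, n_kinases = 8,
                    n_cytokines = 1, k_planted = 2, noise_sd = 0.005,
                    seed = 405)
  sim <- simulate_screen(cfg)
  fits <- fit_kir_models(sim$x_screen, sim$y_screen, nlambda = 40)
  m <- fits$models[[1]]
  needed <- names(which(
    m$solutions[[which(m$alpha_grid == m$best_alpha)]]$coefficients != 0))
  drop_k <- needed[1]
  panel <- sim$x_panel[, setdiff(colnames(sim$x_panel), drop_k)]
  expect_error(predict_out_of_panel(fits, panel, accepted_only = FALSE),
               drop_k)
})

test_that("a clear planted signal is recovered by the informative set", {
  cfg <- sim_config(n_screen_drugs = 30, n_panel_drugs = 4, n_kinases = 15,
                    n_cytokines = 3, k_planted = 2, noise_sd = 0.01,
                    seed = 406)
  sim <- simulate_screen(cfg)
  fits <- fit_kir_models(sim$x_screen, sim$y_screen, nlambda = 50)
  for (cy in names(fits$models)) {
    expect_true(all(sim$ground_truth$support[[cy]] %in%
                      fits$models[[cy]]$informative_kinases))
  }
})
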