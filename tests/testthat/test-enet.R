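# Elastic-net solver: null model, closed forms, independent solvers,
# optimality and path structure.

test_that("lasso at lambda_max and above returns the null model", {
  prob <- rand_problem(20, 8, seed = 101)
  s <- standardize(prob$X)
  lmax <- max(abs(crossprod(s$Xs, prob$y - mean(prob$y)))) / nrow(prob$X)
  fit <- fit_elastic_net(prob$X, prob$y, alpha = 1,
                         lambda = c(2 * lmax, lmax))
  expect_true(all(fit$beta == 0))
  expect_equal(fit$a0, rep(mean(prob$y), 2))
  # one step below lambda_max something must enter
  fit2 <- fit_elastic_net(prob$X, prob$y, alpha = 1, lambda = lmax * 0.95)
  expect_gt(sum(fit2$beta != 0), 0)
})

test_that("ridge solutions match the closed form on the original scale", {
  for (seed in 102:106) {
    n <- sample(10:30, 1)
    p <- sample(3:15, 1)
    prob <- rand_problem(n, p, seed = seed)
    lam <- runif(1, 0.01, 0.5)
    fit <- fit_elastic_net(prob$X, prob$y, alpha = 0, lambda = c(2 * lam, lam))
    oracle <- ridge_oracle(prob$X, prob$y, lam)
    expect_lt(max(abs(fit$beta[, 2] - oracle$beta)), 1e-8)
    expect_lt(abs(fit$a0[2] - oracle$intercept), 1e-8)
  }
})

test_that("solutions agree with an independent coordinate-descent solver", {
  for (alpha in c(0.3, 0.7, 1)) {
    prob <- rand_problem(15, 6, seed = 107)
    fit <- fit_elastic_net(prob$X, prob$y, alpha = alpha, nlambda = 20)
    for (l in c(5, 12, 20)) {
      ref <- enet_ref(prob$X, prob$y, alpha, fit$lambda[l])
      expect_lt(max(abs(fit$beta[, l] - ref$beta)), 1e-7)
      expect_lt(abs(fit$a0[l] - ref$intercept), 1e-7)
    }
  }
})

test_that("solutions never have a higher penalized objective than glmnet", {
  # glmnet parameterizes the same objective; exact correspondence of the
  # solutions holds at the lasso end, while for mid alpha its internal
  # response scaling shifts the L1/L2 balance slightly - so compare by
  # objective value, which any correct solver must (weakly) win on.
  prob <- rand_problem(25, 10, seed = 108)
  for (alpha in c(0.3, 1)) {
    fit <- fit_elastic_net(prob$X, prob$y, alpha = alpha, nlambda = 30)
    g <- glmnet::glmnet(prob$X, prob$y, alpha = alpha, lambda = fit$lambda,
                        thresh = 1e-14, standardize = TRUE)
    cg <- as.matrix(stats::coef(g))
    for (l in c(5, 15, 30)) {
      ours <- enet_objective(prob$X, prob$y, fit$a0[l], fit$beta[, l],
                             alpha, fit$lambda[l])
      theirs <- enet_objective(prob$X, prob$y, cg[1, l], cg[-1, l],
                               alpha, fit$lambda[l])
      expect_lte(ours, theirs + 1e-12)
    }
    if (alpha == 1) {
      cm <- rbind(fit$a0, fit$beta)
      expect_lt(max(abs(cg - cm)), 1e-4)
    }
  }
})

test_that("an exact two-kinase signal carries the largest coefficients", {
  set.seed(109)
  X <- matrix(runif(30 * 10, 0, 100), 30, 10,
              dimnames = list(NULL, sprintf("K%02d", 1:10)))
  y <- 1 + 0.2 * X[, 3] / 100 + 0.15 * X[, 7] / 100
  fit <- fit_elastic_net(X, y, alpha = 0.5)
  last <- abs(fit$beta[, ncol(fit$beta)])
  expect_setequal(names(sort(last, decreasing = TRUE))[1:2], c("K03", "K07"))
})

test_that("constant predictor columns are dropped with zero coefficients", {
  prob <- rand_problem(15, 5, seed = 110)
  prob$X[, 2] <- 42
  expect_warning(fit <- fit_elastic_net(prob$X, prob$y, alpha = 0.5),
                 "K02")
  expect_true(all(fit$beta["K02", ] == 0))
  expect_equal(fit$dropped, "K02")
})

test_that("no coordinate perturbation of 1e-4 improves the objective", {
  prob <- rand_problem(20, 8, seed = 111)
  s <- standardize(prob$X)
  for (alpha in c(0.2, 1)) {
    fit <- fit_elastic_net(prob$X, prob$y, alpha = alpha, nlambda = 20)
    for (l in c(8, 20)) {
      base <- enet_objective(prob$X, prob$y, fit$a0[l], fit$beta[, l],
                             alpha, fit$lambda[l])
      for (j in seq_len(ncol(prob$X))) {
        for (d in c(-1e-4, 1e-4)) {
          pert <- fit$beta[, l]
          # perturb on the standardized scale, as the objective is stated
          pert[j] <- pert[j] + d / s$xs[j]
          expect_gte(enet_objective(prob$X, prob$y, fit$a0[l], pert,
                                    alpha, fit$lambda[l]), base - 1e-12)
        }
      }
    }
  }
})

test_that("sparsity is non-increasing as the penalty grows", {
  # exact support monotonicity is a theorem for orthogonal predictors (the
  # solution is a coordinate-wise soft threshold); on correlated designs
  # variables can re-enter the path, so the guarantee is tested where it holds
  for (seed in 112:114) {
    set.seed(seed)
    n <- 30; p <- 8
    Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * (p + 2)), n))))[, 2:(p + 1)]
    X <- 50 + 20 * Q
    colnames(X) <- sprintf("K%02d", seq_len(p))
    y <- drop(1 + Q %*% runif(p, -0.2, 0.2) + rnorm(n, 0, 0.05))
    for (alpha in c(0.4, 1)) {
      fit <- fit_elastic_net(X, y, alpha = alpha)
      # lambda decreases along the path, so df must be non-decreasing
      expect_true(all(diff(fit$df) >= 0))
      expect_equal(fit$df[[1]], 0)  # the grid starts at lambda_max
    }
  }
  # on generic correlated designs the trend still holds end to end
  prob <- rand_problem(20, 12, seed = 115)
  fit <- fit_elastic_net(prob$X, prob$y, alpha = 0.8)
  expect_equal(fit$df[[1]], 0)
  expect_gt(fit$df[[length(fit$df)]], 0)
})

test_that("argument validation rejects bad inputs", {
  prob <- rand_problem(10, 4, seed = 115)
  expect_error(fit_elastic_net(prob$X, prob$y, alpha = 1.2), "alpha")
  expect_error(fit_elastic_net(prob$X, prob$y, alpha = -0.1), "alpha")
  expect_error(fit_elastic_net(prob$X, prob$y, alpha = 1,
                               lambda = c(0.1, 0.2)), "decreasing")
  expect_error(fit_elastic_net(prob$X[1:2, ], prob$y[1:2], alpha = 1),
               "at least 3")
  Xna <- prob$X; Xna[1, 1] <- NA
  expect_error(fit_elastic_net(Xna, prob$y, alpha = 1), "missing")
})
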