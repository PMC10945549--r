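# Independent oracles used across the suite. These deliberately re-derive
# every quantity from first principles (dense linear algebra, explicit loops,
# exhaustive enumeration) and share no code with the package internals.

# Random regression problem on the residual-activity scale.
rand_problem <- function(n, p, seed, signal = TRUE) {
  set.seed(seed)
  X <- matrix(runif(n * p, 0, 100), n, p,
              dimnames = list(sprintf("d%02d", seq_len(n)),
                              sprintf("K%02d", seq_len(p))))
  y <- if (signal) {
    k <- max(1, min(3, p))
    drop(1 + (X[, seq_len(k), drop = FALSE] / 100) %*% runif(k, 0.1, 0.3) +
           rnorm(n, 0, 0.05))
  } else {
    rnorm(n, 1, 0.1)
  }
  list(X = X, y = y)
}

# Standardization convention shared with the model definition: zero mean,
# unit population (1/n) variance.
standardize <- function(X) {
  xm <- colMeans(X)
  xc <- sweep(X, 2, xm)
  xs <- sqrt(colMeans(xc^2))
  list(Xs = sweep(xc, 2, xs, "/"), xm = xm, xs = xs)
}

# Closed-form ridge estimate on standardized predictors, reported on the
# original scale.
ridge_oracle <- function(X, y, lambda) {
  n <- nrow(X)
  s <- standardize(X)
  bstd <- solve(crossprod(s$Xs) + n * lambda * diag(ncol(X)),
                crossprod(s$Xs, y - mean(y)))
  beta <- drop(bstd) / s$xs
  list(intercept = mean(y) - sum(beta * s$xm), beta = beta)
}

# Plain residual-updating coordinate descent, written independently of the
# package's Gram-based solver.
enet_ref <- function(X, y, alpha, lambda, tol = 1e-13, maxit = 200000) {
  n <- nrow(X)
  s <- standardize(X)
  Xs <- s$Xs
  b <- rep(0, ncol(X))
  r <- y - mean(y)
  for (it in seq_len(maxit)) {
    maxd <- 0
    for (j in seq_len(ncol(X))) {
      z <- sum(Xs[, j] * r) / n + b[j]
      bj <- sign(z) * max(abs(z) - lambda * alpha, 0) /
        (1 + lambda * (1 - alpha))
      if (bj != b[j]) {
        r <- r - Xs[, j] * (bj - b[j])
        maxd <- max(maxd, abs(bj - b[j]))
        b[j] <- bj
      }
    }
    if (maxd < tol) break
  }
  beta <- b / s$xs
  list(intercept = mean(y) - sum(beta * s$xm), beta = beta)
}

# Penalized objective with the internal standardization convention (penalty
# applies to standardized-scale coefficients).
enet_objective <- function(X, y, intercept, beta, alpha, lambda) {
  s <- standardize(X)
  bstd <- beta * s$xs
  mean((y - intercept - drop(X %*% beta))^2) / 2 +
    lambda * ((1 - alpha) / 2 * sum(bstd^2) + alpha * sum(abs(bstd)))
}

# Exhaustive minimum-weight path of at most max_hops edges between two nodes
# of an undirected weighted edge list (depth-first over simple paths; with
# positive weights minimal walks are simple, so this is the true minimum).
min_path_bruteforce <- function(edges, from, to, max_hops) {
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]; w <- edges$weight[i]
    adj[[a]] <- rbind(adj[[a]], data.frame(node = b, w = w))
    adj[[b]] <- rbind(adj[[b]], data.frame(node = a, w = w))
  }
  best <- Inf
  rec <- function(v, visited, w, hops) {
    if (v == to) { best <<- min(best, w); return(invisible()) }
    if (hops == 0) return(invisible())
    nb <- adj[[v]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb)))
      if (!(nb$node[r] %in% visited))
        rec(nb$node[r], c(visited, nb$node[r]), w + nb$w[r], hops - 1)
  }
  rec(from, from, 0, max_hops)
  best
}

# Random connected-ish weighted graph as an edge data frame.
rand_graph <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  ids <- sprintf("G%02d", seq_len(n_nodes))
  pairs <- t(combn(n_nodes, 2))
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  data.frame(from = ids[pairs[pick, 1]], to = ids[pairs[pick, 2]],
             weight = round(runif(length(pick), 0.1, 2), 3))
}

# Write a data frame as a simple TSV edge list (no header).
write_edges_tsv <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

# Mock kir_model with prescribed per-alpha coefficient vectors, for testing
# hit calling and gating logic in isolation.
mock_kir_model <- function(coef_by_alpha, loocv_pred = NULL, y = NULL,
                           best_alpha = NULL, loocv_mse = NULL) {
  alphas <- as.numeric(names(coef_by_alpha))
  if (is.null(loocv_mse)) loocv_mse <- rep(1, length(alphas))
  sols <- lapply(seq_along(alphas), function(i) {
    structure(list(alpha = alphas[i], lambda = 0.1,
                   intercept = 0, coefficients = coef_by_alpha[[i]],
                   loocv_mse = loocv_mse[i], loocv_pred = loocv_pred),
              class = "enet_solution")
  })
  names(sols) <- format(alphas)
  structure(list(cytokine_id = "mock", alpha_grid = alphas, solutions = sols,
                 best_alpha = best_alpha %||% alphas[which.min(loocv_mse)],
                 kinase_ids = names(coef_by_alpha[[1]]), y = y,
                 coef_tol = 1e-8, quality = NULL,
                 informative_kinases = NULL),
            class = "kir_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
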