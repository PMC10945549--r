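#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Elastic-net path solver on the Gram parameterisation.
//
// For each lambda (decreasing, warm-started) minimizes
//   (1/(2n)) sum_i (y_i - x_i'b)^2 + lambda ((1-alpha)/2 ||b||_2^2
//                                           + alpha ||b||_1)
// given G = X'X/n and c = X'y/n for standardized, mean-centered X and
// centered y. Columns with G(j,j) <= 0 encode dropped (constant) predictors.
//
// Strategy (active-set / feature-sign search): a cyclic coordinate-descent
// sweep activates penalty violators, an exact solve of the sign-restricted
// penalized normal equations on the active set polishes the solution (with a
// line search to the first zero crossing when the solve flips a sign, which
// strictly decreases the objective and shrinks the active set), and a full
// KKT check certifies optimality to `tol`. Plain coordinate descent alone
// converges slowly when p > n and the penalty is small; the exact solve
// removes that tail.

// One cyclic coordinate-descent sweep; returns the largest coefficient move.
static double cd_sweep(const mat& G, const vec& c, vec& b, vec& gb,
                       double l1, double l2) {
  const uword p = b.n_elem;
  double maxdelta = 0.0;
  for (uword j = 0; j < p; ++j) {
    const double gjj = G(j, j);
    if (gjj <= 0.0) continue;
    const double z = c[j] - gb[j] + gjj * b[j];
    double bj = 0.0;
    if (z > l1)       bj = (z - l1) / (gjj + l2);
    else if (z < -l1) bj = (z + l1) / (gjj + l2);
    const double d = bj - b[j];
    if (d != 0.0) {
      gb += G.col(j) * d;
      b[j] = bj;
      const double ad = std::fabs(d);
      if (ad > maxdelta) maxdelta = ad;
    }
  }
  return maxdelta;
}

// Largest violation of the KKT stationarity conditions at b.
static double kkt_violation(const mat& G, const vec& c, const vec& b,
                            const vec& gb, double l1, double l2) {
  const uword p = b.n_elem;
  double worst = 0.0;
  for (uword j = 0; j < p; ++j) {
    if (G(j, j) <= 0.0) continue;
    const double g = c[j] - gb[j] - l2 * b[j];
    double v;
    if (b[j] > 0.0)      v = std::fabs(g - l1);
    else if (b[j] < 0.0) v = std::fabs(g + l1);
    else                 v = std::max(std::fabs(g) - l1, 0.0);
    if (v > worst) worst = v;
  }
  return worst;
}

// Penalized objective at b, reusing the maintained gb = G b.
static double objective(const vec& c, const vec& b, const vec& gb,
                        double l1, double l2) {
  return 0.5 * dot(b, gb) - dot(c, b) + 0.5 * l2 * dot(b, b) +
    l1 * norm(b, 1);
}

// [[Rcpp::export(name = ".enet_path_gram")]]
arma::mat enet_path_gram(const arma::mat& G, const arma::vec& c,
                         const arma::vec& lambda, double alpha,
                         double tol, int maxit) {
  const uword p = c.n_elem;
  const uword nl = lambda.n_elem;
  if (G.n_rows != p || G.n_cols != p)
    Rcpp::stop("Gram matrix dimensions do not match the gradient vector");
  mat B(p, nl, fill::zeros);
  vec b(p, fill::zeros), gb(p, fill::zeros);
  const uvec usable = find(G.diag() > 0.0);

  for (uword l = 0; l < nl; ++l) {
    const double lam = lambda[l];
    const double l1 = lam * alpha;
    const double l2 = lam * (1.0 - alpha);
    bool done = false;
    int sweeps = 0;
    double viol_prev = datum::inf;
    int stalls = 0;

    for (int outer = 0; outer < 30 && !done; ++outer) {
      const double viol = kkt_violation(G, c, b, gb, l1, l2);
      if (viol < tol) { done = true; break; }
      // a stalled violation means a flat optimum set (degenerate lasso);
      // further polishing cannot certify and only burns time
      if (viol > 0.5 * viol_prev) { if (++stalls >= 3) break; }
      else stalls = 0;
      viol_prev = viol;
      // activate violators / move toward the optimum
      ++sweeps;
      cd_sweep(G, c, b, gb, l1, l2);
      if (sweeps >= maxit) break;

      // solve of the sign-restricted normal equations on the active set;
      // when the L2 part is (near) zero the system can be singular (lasso
      // with |A| >= n has a flat optimum set), so a tiny Tikhonov term keeps
      // the solve stable and picks a near-minimum-norm point of that set -
      // the KKT certificate below still decides whether it is accepted
      const uvec A = (alpha == 0.0) ? usable : find(b != 0.0);
      if (A.n_elem == 0) continue;
      mat GA = G.submat(A, A);
      const double jitter = (l2 < 1e-9) ? 1e-9 : 0.0;
      GA.diag() += l2 + jitter;
      const vec sA = sign(b.elem(A));
      const vec rhs = c.elem(A) - l1 * sA;
      vec sol;
      const bool ok = solve(sol, GA, rhs,
                            solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) continue;  // fall back to coordinate descent only
      const double obj_old = objective(c, b, gb, l1, l2);
      vec bA;
      if (alpha == 0.0 || !any(sol % sA < 0.0)) {
        bA = sol;
      } else {
        // line search from b_A toward sol up to the first zero crossing:
        // the sign-restricted objective decreases along the whole segment
        bA = b.elem(A);
        double tmin = 1.0;
        for (uword k = 0; k < A.n_elem; ++k) {
          if (sol[k] * sA[k] < 0.0) {
            const double t = bA[k] / (bA[k] - sol[k]);
            if (t < tmin) tmin = t;
          }
        }
        bA += tmin * (sol - bA);
        for (uword k = 0; k < A.n_elem; ++k)
          if (bA[k] * sA[k] <= 0.0) bA[k] = 0.0;
      }
      vec b_new(p, fill::zeros);
      b_new.elem(A) = bA;
      vec gb_new = G.cols(A) * bA;
      // accept the polish only if it does not increase the objective
      if (objective(c, b_new, gb_new, l1, l2) <=
          obj_old + 1e-14 * (1.0 + std::fabs(obj_old))) {
        b = b_new;
        gb = gb_new;
      }
    }
    if (!done && kkt_violation(G, c, b, gb, l1, l2) >= tol) {
      // degenerate flat optima (lasso with more active coordinates than
      // observations): finish with plain coordinate descent; the optimum set
      // is a polytope there and any point of it predicts identically
      while (sweeps < maxit) {
        ++sweeps;
        if (cd_sweep(G, c, b, gb, l1, l2) < 1e-7) break;
      }
      if (kkt_violation(G, c, b, gb, l1, l2) >= 1e-5)
        Rcpp::warning("solver did not fully converge at lambda = %g", lam);
    }
    B.col(l) = b;
  }
  return B;
}
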