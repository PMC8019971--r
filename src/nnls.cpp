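#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Core Lawson-Hanson active-set iteration expressed on the normal equations:
// minimize 0.5 x'Gx - f'x subject to x >= 0, with G = A'A and f = A'b.
// The problem is strictly convex on the passive set as long as G's passive
// principal submatrix is positive definite; singular subproblems fall back
// to a pseudo-inverse solve. Returns the optimal x.
// `tol` must sit above the rounding noise of the Gram-form gradient
// (~n * eps * scale), else near-collinear columns make the exchange cycle.
static vec nnls_gram_core(const mat& G, const vec& f, double tol, int max_iter,
                          const std::vector<bool>* warm = nullptr,
                          int stall_limit = 1000000) {
  const uword n = G.n_cols;
  vec x(n, fill::zeros);
  std::vector<bool> passive(n, false);
  if (warm && warm->size() == n) {
    // warm start: seed the passive set, solve, and repair infeasibility
    // through the usual inner loop before continuing the outer iteration
    bool any = false;
    for (uword j = 0; j < n; ++j) if ((*warm)[j]) { passive[j] = true; any = true; }
    if (any) {
      std::vector<uword> pv0;
      for (uword j = 0; j < n; ++j) if (passive[j]) pv0.push_back(j);
      uvec P0(pv0);
      vec z0;
      bool ok0 = solve(z0, G.submat(P0, P0), f(P0),
                       solve_opts::likely_sympd + solve_opts::no_approx);
      if (ok0 && z0.is_finite() && z0.min() > 0) {
        x(P0) = z0;
      } else {
        for (uword j = 0; j < n; ++j) passive[j] = false;
      }
    }
  }
  vec w = f - G * x;

  int outer = 0;
  int stalled = 0;
  double best_obj = datum::inf;
  std::vector<uword> pv;
  pv.reserve(n);

  while (outer++ < max_iter) {
    // objective monitor: the active-set exchange must strictly decrease
    // 0.5 x'Gx - f'x; tolerate a few flat steps, then stop
    double obj = 0.5 * dot(x, G * x) - dot(f, x);
    if (obj < best_obj - 1e-14 * std::max(1.0, std::abs(best_obj))) {
      best_obj = obj;
      stalled = 0;
    } else if (++stalled > stall_limit) {
      break;
    }
    int t = -1;
    double wmax = tol;
    for (uword j = 0; j < n; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = (int)j; }
    }
    if (t < 0) break;
    passive[t] = true;

    int inner = 0;
    while (inner++ < max_iter) {
      pv.clear();
      for (uword j = 0; j < n; ++j) if (passive[j]) pv.push_back(j);
      uvec P(pv);
      mat Gp = G.submat(P, P);
      // tiny ridge keeps degenerate (near-collinear) subproblems solvable
      // without measurably perturbing well-posed ones
      Gp.diag() += 1e-12 * trace(Gp) / std::max((double)P.n_elem, 1.0);
      vec z;
      bool ok = solve(z, Gp, f(P), solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok || !z.is_finite()) z = pinv(Gp) * f(P);

      if (z.min() > 0) {
        x.zeros();
        x(P) = z;
        break;
      }
      double alpha = 1.0;
      for (uword k = 0; k < P.n_elem; ++k) {
        if (z(k) <= 0) {
          double xk = x(P(k));
          double a = (xk - z(k) > 0) ? xk / (xk - z(k)) : 0.0;
          if (a < alpha) alpha = a;
        }
      }
      for (uword k = 0; k < P.n_elem; ++k) {
        x(P(k)) += alpha * (z(k) - x(P(k)));
      }
      bool removed = false;
      for (uword k = 0; k < P.n_elem; ++k) {
        if (z(k) <= 0 && x(P(k)) <= 1e-12 * std::max(1.0, x.max())) {
          x(P(k)) = 0.0;
          passive[P(k)] = false;
          removed = true;
        }
      }
      if (!removed) {
        // guard against numerical stalling: drop the most negative z
        uword kmin = index_min(z);
        x(P(kmin)) = 0.0;
        passive[P(kmin)] = false;
      }
    }
    // prune exact zeros that linger in the passive set
    for (uword j = 0; j < n; ++j) if (passive[j] && x(j) <= 0) passive[j] = false;
    w = f - G * x;
  }
  return x;
}

// Non-negative least squares min ||A x - b||_2, x >= 0 (Lawson-Hanson).
// The active-set iteration runs on the normal equations for speed; the
// result is then polished with QR-based solves on A itself, continuing the
// active-set exchange if the sharper gradient still finds a violated
// optimality condition (near-collinear columns can cost the Gram form a few
// digits).
// [[Rcpp::export]]
Rcpp::List nnls_solve(const arma::mat& A, const arma::vec& b, int max_iter = 0) {
  const uword m = A.n_rows, n = A.n_cols;
  if (b.n_elem != m) Rcpp::stop("length of b must equal nrow(A)");
  if (max_iter <= 0) max_iter = 10 * (int)n + 100;
  mat G = A.t() * A;
  vec f = A.t() * b;
  const double tol = 1e4 * datum::eps * (f.n_elem ? (double)norm(f, "inf") : 0.0) * std::sqrt((double)n);
  vec x = nnls_gram_core(G, f, tol, max_iter);

  std::vector<bool> passive(n, false);
  for (uword j = 0; j < n; ++j) passive[j] = x(j) > 0;
  const double polish_tol = std::max(tol, 1e3 * datum::eps *
                                     (f.n_elem ? (double)norm(f, "inf") : 0.0));
  int outer = 0;
  while (outer++ < 50) {
    std::vector<uword> pv;
    for (uword j = 0; j < n; ++j) if (passive[j]) pv.push_back(j);
    if (!pv.empty()) {
      uvec P(pv);
      vec z;
      bool ok = solve(z, A.cols(P), b, solve_opts::no_approx);
      if (ok && z.is_finite() && z.min() > 0) {
        x.zeros();
        x(P) = z;
      } else if (ok && z.is_finite()) {
        // a coordinate went non-positive under the sharper solve: step back
        // and drop it, then re-solve
        double alpha = 1.0;
        for (uword k = 0; k < P.n_elem; ++k) {
          if (z(k) <= 0) {
            double xk = x(P(k));
            double a2 = (xk - z(k) > 0) ? xk / (xk - z(k)) : 0.0;
            if (a2 < alpha) alpha = a2;
          }
        }
        for (uword k = 0; k < P.n_elem; ++k) {
          x(P(k)) += alpha * (z(k) - x(P(k)));
          if (z(k) <= 0 && x(P(k)) <= 1e-12) { x(P(k)) = 0.0; passive[P(k)] = false; }
        }
        continue;
      }
    }
    vec w = A.t() * (b - A * x);
    int t = -1;
    double wmax = polish_tol;
    for (uword j = 0; j < n; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = (int)j; }
    }
    if (t < 0) break;
    passive[t] = true;
  }

  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("rnorm") = norm(b - A * x, 2));
}

// Same problem given the normal-equation pieces G = A'A (possibly augmented
// with a penalty term) and f = A'b; returns only x. `warm_support` optionally
// seeds the passive set (1-based indices), e.g. with the support of the
// solution at a nearby regularization weight.
// [[Rcpp::export]]
arma::vec nnls_gram(const arma::mat& G, const arma::vec& f, int max_iter = 0,
                    Rcpp::Nullable<Rcpp::IntegerVector> warm_support = R_NilValue,
                    int stall_limit = 1000000) {
  if (G.n_rows != G.n_cols || f.n_elem != G.n_cols) {
    Rcpp::stop("G must be square with dim matching f");
  }
  if (max_iter <= 0) max_iter = 10 * (int)G.n_cols + 100;
  const double tol = 1e4 * datum::eps * (f.n_elem ? (double)norm(f, "inf") : 0.0) * std::sqrt((double)G.n_cols);
  if (warm_support.isNotNull()) {
    Rcpp::IntegerVector ws(warm_support);
    std::vector<bool> warm(G.n_cols, false);
    for (int i = 0; i < ws.size(); ++i) {
      int j = ws[i] - 1;
      if (j >= 0 && j < (int)G.n_cols) warm[j] = true;
    }
    return nnls_gram_core(G, f, tol, max_iter, &warm, stall_limit);
  }
  return nnls_gram_core(G, f, tol, max_iter, nullptr, stall_limit);
}
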