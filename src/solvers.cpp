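// Convex subproblem solvers for the node-rotation algorithm.
//
// Both block updates minimize a penalized least-squares objective of the
// form  f(b) = ||r - M b||^2 + phi * ||M b||_1  over a small coefficient
// vector b (the latent coordinates of one node, or the scale vector d).
// The L1 penalty acts on the *fitted edge values* z = M b, so with
// z = Q y (Q an orthonormal basis of col(M)) the problem is
//   min_y ||c - y||^2 + phi * ||Q y||_1,      c = Q' r,
// whose Lagrange dual is the box-constrained quadratic program
//   min_{||u||_inf <= 1} (phi^2/4) ||Q' u||^2 - phi * u' Q c .
// The dual is solved by cyclic coordinate descent (O(rank) per
// coordinate) and the primal recovered as y = c - (phi/2) Q' u; the
// duality gap certifies optimality to the requested tolerance.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// 0-based position of edge (u, v), u < v, in the row-major upper-triangle
// half-vectorization of a V x V symmetric matrix.
static inline uword edge_index(uword u, uword v, uword V) {
  return u * (2 * V - u - 1) / 2 + (v - u - 1);
}

static double penalized_objective(const mat& M, const vec& r, double phi,
                                  const vec& b) {
  vec z = M * b;
  return accu(square(r - z)) + phi * accu(abs(z));
}

// Least-squares solve (phi = 0): minimum-norm solution among minimizers
// when M'M is rank deficient.
static vec ls_solve(const mat& M, const vec& r) {
  mat MtM = M.t() * M;
  vec Mtr = M.t() * r;
  vec b;
  if (!solve(b, MtM, Mtr, solve_opts::no_approx)) {
    b = pinv(MtM) * Mtr;
  }
  return b;
}

// Penalized least squares via dual coordinate descent (see header
// comment), warm-startable through the incumbent b0 (used only as a
// fallback: the step is rejected if it would worsen the objective).
static vec pls_dual_cd(const mat& M, const vec& r, double phi,
                       const vec& b0, double tol, int maxit) {
  if (phi <= 0.0) return ls_solve(M, r);
  const uword m = M.n_rows, R = M.n_cols;

  // column-pivoted QR for a well-conditioned basis of col(M)
  mat Q, Rm;
  uvec P;
  if (!qr(Q, Rm, P, M, "vector")) return b0;
  double dmax = (Rm.n_rows > 0) ? std::abs(Rm.max()) : 0.0;
  double rtol = 1e-12 * std::max(1.0, dmax);
  uword k = 0;
  for (uword i = 0; i < std::min(Rm.n_rows, Rm.n_cols); ++i) {
    if (std::abs(Rm(i, i)) > rtol) ++k;
  }
  if (k == 0) { // M numerically zero: fitted values are 0 regardless
    return zeros<vec>(R);
  }
  mat Qk = Q.cols(0, k - 1); // m x k, orthonormal
  vec c = Qk.t() * r;        // k
  vec a = Qk * c;            // m, projection of r onto col(M)

  vec row2(m); // squared row norms of Qk
  for (uword j = 0; j < m; ++j) row2(j) = dot(Qk.row(j), Qk.row(j));

  vec u(m, fill::zeros);
  vec w(k, fill::zeros); // w = Qk' u
  const double h = phi * phi / 2.0;
  double scale = std::max(1.0, dot(r, r));
  vec y = c;
  for (int it = 0; it < maxit; ++it) {
    for (uword j = 0; j < m; ++j) {
      if (row2(j) <= 0) continue;
      double grad = h * dot(Qk.row(j), w) - phi * a(j);
      double unew = u(j) - grad / (h * row2(j));
      unew = std::min(1.0, std::max(-1.0, unew));
      double du = unew - u(j);
      if (du != 0.0) {
        w += du * Qk.row(j).t();
        u(j) = unew;
      }
    }
    // duality gap on the current primal-dual pair
    y = c - (phi / 2.0) * w;
    double l1 = accu(abs(Qk * y));
    double primal = 0.25 * phi * phi * dot(w, w) + phi * l1;
    double dual = phi * dot(u, a) - 0.25 * phi * phi * dot(w, w);
    if (primal - dual <= tol * scale) break;
  }

  // back-substitute y (coefficients on Qk) to b on the original columns
  vec b(R, fill::zeros);
  vec bk = solve(trimatu(Rm.submat(0, 0, k - 1, k - 1)), y);
  for (uword i = 0; i < k; ++i) b(P(i)) = bk(i);

  // never accept a step that worsens the subproblem (guarantees block
  // monotonicity even at solver tolerance)
  if (penalized_objective(M, r, phi, b) >
      penalized_objective(M, r, phi, b0)) {
    return b0;
  }
  return b;
}

// [[Rcpp::export]]
arma::vec cpp_penalized_ls(const arma::mat& M, const arma::vec& r,
                           double phi, const arma::vec& b0,
                           double tol = 1e-8, int maxit = 1000) {
  return pls_dual_cd(M, r, phi, b0, tol, maxit);
}

// Design matrix for the scale update: Phi[(u,v), s] = X(u,s) * X(v,s).
// [[Rcpp::export]]
arma::mat cpp_scale_design(const arma::mat& X) {
  const uword V = X.n_rows, R = X.n_cols;
  mat Phi(V * (V - 1) / 2, R);
  for (uword u = 0; u < V; ++u) {
    for (uword v = u + 1; v < V; ++v) {
      uword e = edge_index(u, v, V);
      for (uword s = 0; s < R; ++s) Phi(e, s) = X(u, s) * X(v, s);
    }
  }
  return Phi;
}

// Low-rank trait signal s = L(X D X') as an edge vector.
// [[Rcpp::export]]
arma::vec cpp_trait_signal(const arma::mat& X, const arma::vec& d) {
  return cpp_scale_design(X) * d;
}

// One full node-rotation pass for a single trait: update the latent
// coordinates of each node v = 1..V in turn (conditioning on the others),
// renormalize the columns of X to unit norm folding the scale into d, and
// update d. `r` is the unconstrained edge-space target for this trait.
// [[Rcpp::export]]
Rcpp::List cpp_update_trait(const arma::vec& r, arma::mat X, arma::vec d,
                            double phi, double tol = 1e-8,
                            int maxit = 1000) {
  const uword V = X.n_rows, R = X.n_cols;

  // node rotation
  vec rv(V - 1);
  mat M(V - 1, R);
  for (uword v = 0; v < V; ++v) {
    uword kk = 0;
    for (uword u = 0; u < V; ++u) {
      if (u == v) continue;
      rv(kk) = r(edge_index(std::min(u, v), std::max(u, v), V));
      M.row(kk) = X.row(u) % d.t();
      ++kk;
    }
    if (norm(M, "fro") == 0.0) { // all m_u zero: coordinates unidentifiable
      X.row(v).zeros();
      continue;
    }
    vec b0 = X.row(v).t();
    X.row(v) = pls_dual_cd(M, rv, phi, b0, tol, maxit).t();
  }

  // renormalize columns, folding scale into d (s = sum d_r x_r x_r' is
  // invariant under (x_r, d_r) -> (x_r / c, c^2 d_r))
  for (uword s = 0; s < R; ++s) {
    double c = norm(X.col(s));
    if (c > 0) {
      X.col(s) /= c;
      d(s) *= c * c;
    }
  }

  // scale update
  mat Phi = cpp_scale_design(X);
  d = pls_dual_cd(Phi, r, phi, d, tol, maxit);

  return Rcpp::List::create(Rcpp::Named("X") = X, Rcpp::Named("d") = d);
}
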