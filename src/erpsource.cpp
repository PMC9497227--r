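// Compiled cores: the Legendre-series dipole kernel of the concentric
// four-shell forward model, and the eLORETA weight iteration.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Dipole gain matrix for a piecewise-homogeneous concentric-shell head.
//
// elec: nE x 3 electrode positions relative to the model centre (mm),
//       assumed on the outer shell radius R.
// src:  nS x 3 source positions relative to the centre (mm), |s| < r1.
// g:    per-degree radial gains from the boundary-value solve in radii
//       normalised by R (g[n-1] for degree n); (2n+1)/n for a homogeneous
//       sphere.
// R:    outer (scalp) radius in mm.  sigma1: innermost conductivity, S/m.
//
// Returns nE x (3 nS) in microvolts per nA*m, not yet average-referenced.
// [[Rcpp::export(name = ".leadfieldKernel")]]
arma::mat leadfield_kernel(const arma::mat& elec, const arma::mat& src,
                           const arma::vec& g, double R, double sigma1) {
  const uword nE = elec.n_rows, nS = src.n_rows, N = g.n_elem;
  mat out(nE, 3 * nS, fill::zeros);
  const double scale = 1000.0 / (4.0 * M_PI * sigma1 * R * R);
  mat ehat = elec / R;  // unit electrode directions

  for (uword s = 0; s < nS; ++s) {
    rowvec sv = src.row(s);
    double t = norm(sv);
    rowvec that = (t > 1e-9) ? rowvec(sv / t) : rowvec(3, fill::zeros);
    double tau = t / R;
    for (uword e = 0; e < nE; ++e) {
      rowvec eh = ehat.row(e);
      rowvec kvec(3, fill::zeros);
      if (t <= 1e-9) {
        kvec = g(0) * eh;  // only degree 1 survives for a central dipole
      } else {
        double c = dot(that, eh);
        if (c > 1.0) c = 1.0;
        if (c < -1.0) c = -1.0;
        // Legendre recurrences for P_n(c) and P'_n(c)
        double Pm1 = 1.0, P = c;        // P_0, P_1
        double dPm1 = 0.0, dP = 1.0;    // P'_0, P'_1
        double tp = 1.0;                // tau^(n-1) at n = 1
        double coefR = 0.0, coefT = 0.0;
        for (uword n = 1; n <= N; ++n) {
          coefR += g(n - 1) * tp * n * P;
          coefT += g(n - 1) * tp * dP;
          // advance to degree n+1
          double Pn1 = ((2.0 * n + 1.0) * c * P - n * Pm1) / (n + 1.0);
          double dPn1 = dPm1 + (2.0 * n + 1.0) * P;
          Pm1 = P; P = Pn1;
          dPm1 = dP; dP = dPn1;
          tp *= tau;
        }
        kvec = coefR * that + coefT * (eh - c * that);
      }
      out(e, 3 * s)     = scale * kvec(0);
      out(e, 3 * s + 1) = scale * kvec(1);
      out(e, 3 * s + 2) = scale * kvec(2);
    }
  }
  return out;
}

// eLORETA weight iteration.
//
// L: nE x 3 nS average-referenced gain matrix.
// alpha: regularisation relative to the mean sensor-space eigenvalue.
// Returns the inverse mapping (3 nS x nE), the converged 3x3 weights, the
// per-iteration max relative weight change, and a convergence flag; the R
// wrapper turns non-convergence into a condition carrying the trace.
// [[Rcpp::export(name = ".eloretaCore")]]
Rcpp::List eloreta_core(const arma::mat& L, double alpha, double tol,
                        int maxIter) {
  const uword nE = L.n_rows;
  const uword nS = L.n_cols / 3;
  cube W(3, 3, nS);
  cube Winv(3, 3, nS);
  for (uword j = 0; j < nS; ++j) {
    W.slice(j).eye();
    Winv.slice(j).eye();
  }
  mat H = eye(nE, nE) - ones(nE, nE) / double(nE);
  std::vector<double> trace;
  bool converged = false;
  mat Cinv(nE, nE);
  auto pinvC = [&](const mat& C) {
    vec eval;
    mat evec;
    eig_sym(eval, evec, C);
    double cut = 1e-12 * eval.max();
    vec inv_eval = eval;
    for (uword k = 0; k < nE; ++k)
      inv_eval(k) = (eval(k) > cut) ? 1.0 / eval(k) : 0.0;
    return mat(evec * diagmat(inv_eval) * evec.t());
  };
  if (maxIter <= 0) {
    // degenerate case: no reweighting; the operator reduces to the
    // weighted-minimum-norm solution with unit weights
    mat M(nE, nE, fill::zeros);
    for (uword j = 0; j < nS; ++j) {
      const mat Lj = L.cols(3 * j, 3 * j + 2);
      M += Lj * Lj.t();
    }
    Cinv = pinvC(M + alpha * (arma::trace(M) / double(nE)) * H);
    mat K(3 * nS, nE);
    for (uword j = 0; j < nS; ++j)
      K.rows(3 * j, 3 * j + 2) = L.cols(3 * j, 3 * j + 2).t() * Cinv;
    return Rcpp::List::create(
        Rcpp::Named("mapping") = K, Rcpp::Named("weights") = W,
        Rcpp::Named("trace") = std::vector<double>(),
        Rcpp::Named("iterations") = 0, Rcpp::Named("converged") = true);
  }
  int it = 0;
  for (it = 0; it < maxIter; ++it) {
    // sensor-space matrix M = sum_j L_j W_j^{-1} L_j^T
    mat M(nE, nE, fill::zeros);
    for (uword j = 0; j < nS; ++j) {
      const mat Lj = L.cols(3 * j, 3 * j + 2);
      M += Lj * Winv.slice(j) * Lj.t();
    }
    double mu = arma::trace(M) / double(nE);
    // pseudo-inverse on the average-reference subspace
    Cinv = pinvC(M + alpha * mu * H);
    // per-source symmetric square roots
    double delta = 0.0;
    for (uword j = 0; j < nS; ++j) {
      const mat Lj = L.cols(3 * j, 3 * j + 2);
      mat A = symmatu(Lj.t() * Cinv * Lj);
      vec av;
      mat avec;
      eig_sym(av, avec, A);
      if (av.max() <= 0 || av.min() < -1e-10 * av.max())
        Rcpp::stop("singular 3x3 weight block at source %d", (int)(j + 1));
      av.for_each([](double& x) { if (x < 0) x = 0; });
      mat Wnew = avec * diagmat(sqrt(av)) * avec.t();
      double d = norm(Wnew - W.slice(j), "fro") /
                 std::max(norm(W.slice(j), "fro"), 1e-300);
      if (d > delta) delta = d;
      W.slice(j) = Wnew;
      // invert via eigenvalues (symmetric positive definite)
      vec sq = sqrt(av);
      double smin = sq.min(), smax = sq.max();
      if (smin <= 1e-12 * smax)
        Rcpp::stop("singular 3x3 weight block at source %d", (int)(j + 1));
      Winv.slice(j) = avec * diagmat(1.0 / sq) * avec.t();
    }
    trace.push_back(delta);
    if (delta < tol) { converged = true; ++it; break; }
  }
  // inverse mapping K = W^{-1} L^T C^+
  mat K(3 * nS, nE);
  for (uword j = 0; j < nS; ++j) {
    const mat Lj = L.cols(3 * j, 3 * j + 2);
    K.rows(3 * j, 3 * j + 2) = Winv.slice(j) * Lj.t() * Cinv;
  }
  return Rcpp::List::create(
      Rcpp::Named("mapping") = K, Rcpp::Named("weights") = W,
      Rcpp::Named("trace") = trace, Rcpp::Named("iterations") = it,
      Rcpp::Named("converged") = converged);
}
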