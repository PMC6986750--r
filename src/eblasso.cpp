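// Greedy type-II likelihood core of the empirical Bayesian lasso under the
// normal-exponential-gamma prior. Mirrors the reference R implementation
// (eblasso_core_r); see R/eblasso.R for the derivation and the meaning of
// the sparsity/quality factors and the per-basis quadratic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double ell(double A, double s, double q, double a, double b) {
  return 0.5 * (q * q * A / (1.0 + A * s) - std::log1p(A * s)) -
         (a + 1.0) * std::log1p(A / b);
}

// [[Rcpp::export(name = ".eb_core_cpp")]]
Rcpp::List eb_core_cpp(const arma::mat& G, const arma::vec& Xty, double yty,
                       int n, double a, double b, int max_iter, double tol,
                       int max_active, int outer_max, double add_gain) {
  const uword p = Xty.n_elem;
  vec cn = G.diag();
  double vy = std::max(yty / n, 1e-12);
  double sigma2 = vy;

  std::vector<uword> active;
  std::vector<double> A;
  mat Sig;        // posterior covariance of active effects
  vec mu;         // posterior mean
  vec S(p), Q(p); // sparsity / quality factors for all bases
  int iter = 0;

  auto refresh = [&]() {
    const uword M = active.size();
    if (M == 0) {
      Sig.set_size(0, 0);
      mu.set_size(0);
      S = cn / sigma2;
      Q = Xty / sigma2;
    } else {
      uvec act(M);
      for (uword k = 0; k < M; ++k) act[k] = active[k];
      mat Gaa = G.submat(act, act) / sigma2;
      for (uword k = 0; k < M; ++k) Gaa(k, k) += 1.0 / A[k];
      Sig = inv_sympd(Gaa);
      mu = Sig * (Xty.elem(act) / sigma2);
      mat Gact = G.cols(act);
      mat W = Gact * Sig;
      S = cn / sigma2 - sum(W % Gact, 1) / (sigma2 * sigma2);
      Q = Xty / sigma2 - (W * Xty.elem(act)) / (sigma2 * sigma2);
    }
  };

  for (int outer = 0; outer < outer_max; ++outer) {
    refresh();
    int since_refresh = 0;
    while (true) {
      if (++iter > max_iter) break;
      const uword M = active.size();
      // leave-one-out factors for active bases
      vec s = S, q = Q;
      for (uword k = 0; k < M; ++k) {
        const uword j = active[k];
        double den = std::max(1.0 - A[k] * S[j], 1e-12);
        s[j] = S[j] / den;
        q[j] = Q[j] / den;
      }
      // candidate prior variances and likelihood gains
      std::vector<int> in_active(p, -1);
      for (uword k = 0; k < M; ++k) in_active[active[k]] = (int)k;
      double best = -datum::inf;
      uword bestj = 0;
      double bestA = 0.0;
      int best_kind = 0; // 1 add, 2 re-estimate, 3 delete
      for (uword j = 0; j < p; ++j) {
        if (s[j] <= 1e-10) continue;
        double qq = q[j] * q[j];
        double c2 = -(a + 1.5) * s[j] * s[j];
        double c1 = 0.5 * (qq - s[j] - b * s[j] * s[j]) - 2.0 * (a + 1.0) * s[j];
        double c0 = 0.5 * b * (qq - s[j]) - (a + 1.0);
        bool incl = c0 > 0.0;
        double Astar = 0.0;
        if (incl) {
          double disc = std::sqrt(std::max(c1 * c1 - 4.0 * c2 * c0, 0.0));
          Astar = (-c1 - disc) / (2.0 * c2);
        }
        int k = in_active[j];
        double d;
        int kind;
        if (k < 0) {
          if (!incl || (int)M >= max_active) continue;
          // admission is charged a minimum evidence gain
          d = ell(Astar, s[j], q[j], a, b) - add_gain;
          kind = 1;
        } else if (incl) {
          d = ell(Astar, s[j], q[j], a, b) - ell(A[k], s[j], q[j], a, b);
          kind = 2;
        } else {
          d = -ell(A[k], s[j], q[j], a, b);
          kind = 3;
        }
        if (d > best) {
          best = d;
          bestj = j;
          bestA = Astar;
          best_kind = kind;
        }
      }
      if (!std::isfinite(best) || best < tol) break;
      const uword j = bestj;
      if (best_kind == 1) { // add
        double Sjj = 1.0 / (1.0 / bestA + S[j]);
        double muj = Sjj * Q[j];
        vec e;
        vec vj;
        if (M > 0) {
          uvec act(M);
          for (uword k = 0; k < M; ++k) act[k] = active[k];
          vec gaj = G.submat(act, uvec{j});
          vj = (Sig * gaj) / sigma2;
          e = G.col(j) / sigma2 - (G.cols(act) * (Sig * gaj)) / (sigma2 * sigma2);
        } else {
          e = G.col(j) / sigma2;
        }
        S -= Sjj * square(e);
        Q -= muj * e;
        mat Sig2(M + 1, M + 1);
        vec mu2(M + 1);
        if (M > 0) {
          Sig2.submat(0, 0, M - 1, M - 1) = Sig + Sjj * (vj * vj.t());
          Sig2.submat(0, M, M - 1, M) = -Sjj * vj;
          Sig2.submat(M, 0, M, M - 1) = (-Sjj * vj).t();
          mu2.subvec(0, M - 1) = mu - muj * vj;
        }
        Sig2(M, M) = Sjj;
        mu2(M) = muj;
        Sig = Sig2;
        mu = mu2;
        active.push_back(j);
        A.push_back(bestA);
      } else {
        const uword k = (uword)in_active[j];
        uvec act(M);
        for (uword kk = 0; kk < M; ++kk) act[kk] = active[kk];
        vec w = (G.cols(act) * Sig.col(k)) / sigma2;
        if (best_kind == 2) { // re-estimate
          double dalpha = 1.0 / bestA - 1.0 / A[k];
          double kap = dalpha / (1.0 + dalpha * Sig(k, k));
          S += kap * square(w);
          Q += kap * mu[k] * w;
          mu -= kap * mu[k] * Sig.col(k);
          Sig -= kap * (Sig.col(k) * Sig.col(k).t());
          A[k] = bestA;
        } else { // delete
          double Skk = Sig(k, k);
          S += square(w) / Skk;
          Q += mu[k] * w / Skk;
          mu -= mu[k] * Sig.col(k) / Skk;
          Sig -= (Sig.col(k) * Sig.col(k).t()) / Skk;
          mu.shed_row(k);
          Sig.shed_row(k);
          Sig.shed_col(k);
          active.erase(active.begin() + k);
          A.erase(A.begin() + k);
        }
      }
      if (++since_refresh >= 100) {
        refresh();
        since_refresh = 0;
      }
    }
    // noise re-estimation from the converged posterior
    const uword M = active.size();
    double new_sigma2;
    if (M > 0) {
      uvec act(M);
      for (uword k = 0; k < M; ++k) act[k] = active[k];
      mat Gaa = G.submat(act, act);
      mat H = Gaa / sigma2;
      for (uword k = 0; k < M; ++k) H(k, k) += 1.0 / A[k];
      mat P = inv_sympd(H);
      vec mu_a = P * (Xty.elem(act) / sigma2);
      double rss = std::max(yty - 2.0 * dot(mu_a, Xty.elem(act)) +
                              dot(mu_a, Gaa * mu_a), 0.0);
      double gam_sum = 0.0;
      for (uword k = 0; k < M; ++k) gam_sum += 1.0 - P(k, k) / A[k];
      new_sigma2 = std::max(rss / std::max(n - 1.0 - gam_sum, 1.0), 1e-8 * vy);
    } else {
      new_sigma2 = vy;
    }
    bool done = std::fabs(std::log(new_sigma2) - std::log(sigma2)) < 1e-4;
    sigma2 = new_sigma2;
    if (done || iter > max_iter) break;
  }

  // final posterior on the retained set
  const uword M = active.size();
  vec beta(M), se(M);
  if (M > 0) {
    uvec act(M);
    for (uword k = 0; k < M; ++k) act[k] = active[k];
    mat H = G.submat(act, act) / sigma2;
    for (uword k = 0; k < M; ++k) H(k, k) += 1.0 / A[k];
    mat P = inv_sympd(H);
    beta = P * (Xty.elem(act) / sigma2);
    se = sqrt(clamp(P.diag(), 0.0, datum::inf));
  }
  Rcpp::IntegerVector act_out(M);
  for (uword k = 0; k < M; ++k) act_out[k] = (int)active[k] + 1; // 1-based
  return Rcpp::List::create(
    Rcpp::Named("active") = act_out,
    Rcpp::Named("A") = Rcpp::NumericVector(A.begin(), A.end()),
    Rcpp::Named("beta") = Rcpp::NumericVector(beta.begin(), beta.end()),
    Rcpp::Named("se") = Rcpp::NumericVector(se.begin(), se.end()),
    Rcpp::Named("sigma2") = sigma2,
    Rcpp::Named("iterations") = iter);
}
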