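// Joint-model marginal log-likelihood and analytic score.
//
// The random effect b_i (intercept + spline coefficients, diagonal prior
// covariance D) is integrated by pseudo-adaptive Gauss-Hermite quadrature:
// nodes are centred and scaled per subject at the empirical-Bayes posterior
// from the longitudinal-only fit and kept fixed across iterations. All
// contractions of the node positions with the design matrices
// (A_obs = X_i B_i, A_q = Xq_i B_i, a_T = xT_i B_i, squared node values)
// are therefore data, precomputed once on the R side. Per node the
// integrand factorizes into the Gaussian longitudinal density, the
// piecewise-constant-hazard survival terms with a current-value
// association, and the random-effect prior; the score reuses the posterior
// node weights p_q = W_q F_q / sum(W_q F_q).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// zero-copy views onto the R-owned slabs (they are large and re-read at
// every likelihood evaluation)
static arma::mat mat_view(Rcpp::NumericMatrix m) {
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}
static arma::vec vec_view(Rcpp::NumericVector v) {
  return arma::vec(v.begin(), v.size(), false, true);
}

// parameter layout in th: beta (p), log d (p), log s2 (1), gamma (c),
// alpha (1), xi (K)
// [[Rcpp::export(name = ".jm_loglik_cpp")]]
Rcpp::List jm_loglik_cpp(const arma::vec& th,
                         const Rcpp::List& prep,
                         bool want_grad) {
  const vec y = vec_view(prep["y"]);
  const mat Xobs = mat_view(prep["Xobs"]);
  const uvec obs_off = Rcpp::as<uvec>(prep["obs_off"]);   // n+1, 0-based rows
  const mat Xq = mat_view(prep["Xq"]);
  const vec uq = vec_view(prep["uq"]);
  const uvec segq = Rcpp::as<uvec>(prep["segq"]);         // 0-based
  const uvec quad_off = Rcpp::as<uvec>(prep["quad_off"]);
  const mat xT = mat_view(prep["xT"]);                    // n x p
  const uvec segT = Rcpp::as<uvec>(prep["segT"]);
  const vec delta = vec_view(prep["delta"]);
  const mat W = mat_view(prep["W"]);                      // n x c
  const vec logwq = vec_view(prep["logwq"]);              // Q
  const vec logdetC = vec_view(prep["logdetC"]);          // n
  const mat Aobs = mat_view(prep["Aobs"]);                // total_obs x Q
  const mat AQ = mat_view(prep["AQ"]);                    // total_quad x Q
  const mat AT = mat_view(prep["AT"]);                    // n x Q
  const mat B2 = mat_view(prep["B2"]);                    // n*p x Q
  const mat SA2 = mat_view(prep["SA2"]);                  // n x Q colsum Aobs^2

  const uword n = AT.n_rows, Q = AT.n_cols;
  const uword p = B2.n_rows / n;
  const uword c = W.n_cols;
  const uword K = th.n_elem - (2 * p + 1 + c + 1);

  const vec beta = th.subvec(0, p - 1);
  const vec d = exp(th.subvec(p, 2 * p - 1));
  const vec inv_d = 1.0 / d;
  const double s2 = std::exp(th(2 * p));
  const vec gamma = (c > 0) ? th.subvec(2 * p + 1, 2 * p + c) : vec();
  const double alpha = th(2 * p + c + 1);
  const vec xi = th.subvec(2 * p + c + 2, 2 * p + c + 1 + K);

  const double log2pi = std::log(2.0 * M_PI);
  const double prior_const =
      -0.5 * double(p) * log2pi - 0.5 * accu(log(d)) +
      0.5 * double(p) * std::log(2.0);

  double ll = 0.0;
  vec g(th.n_elem, fill::zeros);

  vec gw(n, fill::zeros);
  if (c > 0) gw = W * gamma;

  for (uword i = 0; i < n; ++i) {
    // longitudinal part
    const uword o0 = obs_off(i), o1 = obs_off(i + 1);
    const uword ni = o1 - o0;
    vec lq(Q, fill::zeros);
    vec e; double ee = 0.0; rowvec eA;
    if (ni > 0) {
      const mat Xi = Xobs.rows(o0, o1 - 1);
      e = y.subvec(o0, o1 - 1) - Xi * beta;
      ee = dot(e, e);
      eA = e.t() * Aobs.rows(o0, o1 - 1);
      lq = -0.5 * double(ni) * (log2pi + std::log(s2)) -
           0.5 / s2 * (ee - 2.0 * eA.t() + SA2.row(i).t());
    }

    // survival part
    const uword q0 = quad_off(i), q1 = quad_off(i + 1);
    const uword ns = q1 - q0;
    const double Gi = std::exp(gw(i));
    mat Cq; mat Msq; vec Hq(Q, fill::zeros);
    if (ns > 0) {
      const mat Xqi = Xq.rows(q0, q1 - 1);
      vec m0 = Xqi * beta;
      Msq = AQ.rows(q0, q1 - 1);
      Msq.each_col() += m0;                              // ns x Q
      vec base(ns);
      for (uword j = 0; j < ns; ++j)
        base(j) = std::log(uq(q0 + j)) + xi(segq(q0 + j));
      Cq = alpha * Msq;
      Cq.each_col() += base;
      Cq = exp(Cq);
      Hq = sum(Cq, 0).t();
    }
    lq += -Gi * Hq;

    rowvec mT;
    if (delta(i) > 0.5) {
      double mT0 = dot(xT.row(i), beta);
      mT = mT0 + AT.row(i);
      lq += xi(segT(i)) + gw(i) + alpha * mT.t();
    }

    // prior and quadrature weights
    const mat B2i = B2.rows(i * p, (i + 1) * p - 1);     // p x Q
    lq += prior_const - 0.5 * (B2i.t() * inv_d) + logwq + logdetC(i);

    double m = lq.max();
    vec eq = exp(lq - m);
    double sumeq = accu(eq);
    ll += m + std::log(sumeq);

    if (!want_grad) continue;
    vec pq = eq / sumeq;

    vec gbeta(p, fill::zeros);
    if (ni > 0) {
      const mat Xi = Xobs.rows(o0, o1 - 1);
      vec r = e - Aobs.rows(o0, o1 - 1) * pq;
      gbeta += Xi.t() * r / s2;
      double SSbar = ee - 2.0 * dot(eA.t(), pq) + dot(SA2.row(i).t(), pq);
      g(2 * p) += -0.5 * double(ni) + 0.5 * SSbar / s2;
    }
    if (ns > 0) {
      const mat Xqi = Xq.rows(q0, q1 - 1);
      vec cp = Cq * pq;                   // ns
      gbeta -= Gi * alpha * (Xqi.t() * cp);
      double acm = 0.0;                   // alpha score, column-wise
      for (uword q = 0; q < Q; ++q)
        acm += pq(q) * dot(Cq.col(q), Msq.col(q));
      g(2 * p + c + 1) -= Gi * acm;
      for (uword j = 0; j < ns; ++j)
        g(2 * p + c + 2 + segq(q0 + j)) -= Gi * cp(j);        // xi
    }
    if (delta(i) > 0.5) {
      gbeta += alpha * xT.row(i).t();
      g(2 * p + c + 1) += dot(mT.t(), pq);
      g(2 * p + c + 2 + segT(i)) += 1.0;
    }
    g.subvec(0, p - 1) += gbeta;

    vec b2bar = B2i * pq;
    g.subvec(p, 2 * p - 1) += -0.5 + 0.5 * (b2bar % inv_d);

    if (c > 0) {
      double sc = delta(i) - Gi * dot(Hq, pq);
      g.subvec(2 * p + 1, 2 * p + c) += sc * W.row(i).t();
    }
  }

  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("grad") = g);
}
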