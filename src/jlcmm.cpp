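// Compiled kernels for the latent-class mixed model: the per-subject
// per-class marginal Gaussian log-likelihood (random effects integrated
// analytically) and the EM sufficient statistics, both organised around
// visit-pattern groups so each marginal covariance is factorised once.
//
// Flattened pattern-major layout built once on the R side:
//  Xflat  : stacked pattern design matrices, row offsets x_off (0-based)
//  yflat  : subject responses concatenated pattern-major, offsets y_off
//  s_off  : subject-index range per pattern (into the subject sequence)
//  row_of : subject -> output/endpoint row (0-based)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export(name = ".jlcmm_longll_cpp")]]
arma::mat jlcmm_longll_cpp(const arma::mat& beta,      // p x G
                           const arma::vec& d,         // p
                           const double s2,
                           const arma::mat& Xflat,
                           const arma::uvec& x_off,
                           const arma::vec& yflat,
                           const arma::uvec& y_off,
                           const arma::uvec& s_off,
                           const arma::uvec& row_of,
                           const int n_out) {
  const uword G = beta.n_cols;
  const uword n_pat = x_off.n_elem - 1;
  mat out(n_out, G, fill::zeros);
  const double log2pi = std::log(2.0 * datum::pi);
  for (uword pt = 0; pt < n_pat; ++pt) {
    const mat X = Xflat.rows(x_off(pt), x_off(pt + 1) - 1);
    const uword ni = X.n_rows;
    mat V = X * diagmat(d) * X.t();
    V.diag() += s2;
    const mat L = chol(V, "lower");
    const double cst = -0.5 * double(ni) * log2pi - accu(log(L.diag()));
    const mat XB = X * beta;              // ni x G
    for (uword i = s_off(pt); i < s_off(pt + 1); ++i) {
      const vec yi = yflat.subvec(y_off(i), y_off(i + 1) - 1);
      for (uword g = 0; g < G; ++g) {
        vec z = solve(trimatl(L), yi - XB.col(g));
        out(row_of(i), g) = cst - 0.5 * dot(z, z);
      }
    }
  }
  return out;
}

// longitudinal score accumulators given posterior class weights:
// d loglik / d beta_g, d loglik / d d_k, d loglik / d s2 (natural scale)
// [[Rcpp::export(name = ".jlcmm_scoreacc_cpp")]]
Rcpp::List jlcmm_scoreacc_cpp(const arma::mat& beta,
                              const arma::vec& d,
                              const double s2,
                              const arma::mat& w,
                              const arma::mat& Xflat,
                              const arma::uvec& x_off,
                              const arma::vec& yflat,
                              const arma::uvec& y_off,
                              const arma::uvec& s_off,
                              const arma::uvec& row_of) {
  const uword G = beta.n_cols, p = beta.n_rows;
  const uword n_pat = x_off.n_elem - 1;
  mat g_beta(p, G, fill::zeros);
  vec g_d(p, fill::zeros);
  double g_s2 = 0.0;
  for (uword pt = 0; pt < n_pat; ++pt) {
    const mat X = Xflat.rows(x_off(pt), x_off(pt + 1) - 1);
    mat V = X * diagmat(d) * X.t();
    V.diag() += s2;
    const mat Vi = inv_sympd(V);
    const mat XtVi = X.t() * Vi;
    const vec a_diag = diagvec(XtVi * X);
    const double trVi = trace(Vi);
    const mat XB = X * beta;
    for (uword i = s_off(pt); i < s_off(pt + 1); ++i) {
      const vec yi = yflat.subvec(y_off(i), y_off(i + 1) - 1);
      for (uword g = 0; g < G; ++g) {
        const double wg = w(row_of(i), g);
        if (wg < 1e-14) continue;
        vec r = yi - XB.col(g);
        vec Vir = Vi * r;
        vec v = X.t() * Vir;
        g_beta.col(g) += wg * v;
        g_d += -0.5 * wg * (a_diag - square(v));
        g_s2 += -0.5 * wg * (trVi - dot(Vir, Vir));
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("g_beta") = g_beta,
                            Rcpp::Named("g_d") = g_d,
                            Rcpp::Named("g_s2") = g_s2);
}

// EM sufficient statistics given posterior class weights w (n_out x G)
// [[Rcpp::export(name = ".jlcmm_emacc_cpp")]]
Rcpp::List jlcmm_emacc_cpp(const arma::mat& beta,
                           const arma::vec& d,
                           const double s2,
                           const arma::mat& w,
                           const arma::mat& Xflat,
                           const arma::uvec& x_off,
                           const arma::vec& yflat,
                           const arma::uvec& y_off,
                           const arma::uvec& s_off,
                           const arma::uvec& row_of) {
  const uword G = beta.n_cols, p = beta.n_rows;
  const uword n_pat = x_off.n_elem - 1;
  cube A(p, p, G, fill::zeros);
  mat bv(p, G, fill::zeros);
  vec d_acc(p, fill::zeros);
  double s2_acc = 0.0;
  for (uword pt = 0; pt < n_pat; ++pt) {
    const mat X = Xflat.rows(x_off(pt), x_off(pt + 1) - 1);
    mat V = X * diagmat(d) * X.t();
    V.diag() += s2;
    const mat Vi = inv_sympd(V);
    const mat XtVi = X.t() * Vi;
    const mat XtViX = XtVi * X;
    const mat prec = X.t() * X / s2 + diagmat(1.0 / d);
    const mat Sig = inv_sympd(prec);
    const mat XS = X * Sig;
    const double trXSX = accu(X % XS);
    const vec sig_diag = Sig.diag();
    const mat XB = X * beta;
    for (uword i = s_off(pt); i < s_off(pt + 1); ++i) {
      const vec yi = yflat.subvec(y_off(i), y_off(i + 1) - 1);
      const vec XtViy = XtVi * yi;
      for (uword g = 0; g < G; ++g) {
        const double wg = w(row_of(i), g);
        if (wg < 1e-14) continue;
        A.slice(g) += wg * XtViX;
        bv.col(g) += wg * XtViy;
        vec r = yi - XB.col(g);
        vec m = XS.t() * r / s2;
        d_acc += wg * (square(m) + sig_diag);
        vec e = r - X * m;
        s2_acc += wg * (dot(e, e) + trXSX);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("bv") = bv,
                            Rcpp::Named("d_acc") = d_acc,
                            Rcpp::Named("s2_acc") = s2_acc);
}
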