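// Felsenstein pruning likelihoods for binary traits on a phylogeny.
// Two-state transition probabilities are closed form; the four-state joint
// chain uses an eigendecomposition of the rate matrix (one per call), with
// scaling-and-squaring (arma::expmat) as fallback when the eigenbasis is
// ill-conditioned. Per-edge scaling of partial likelihoods guards against
// underflow on large trees.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// partial[node] *= P(t) %*% partial[child], with underflow scaling
static inline double scale_vec(arma::vec &v) {
  double m = v.max();
  if (m > 0.0 && m < 1e-150) {
    v /= m;
    return std::log(m);
  }
  return 0.0;
}

// 2-state transition matrix: states 0 (absent), 1 (present),
// alpha = gain rate 0->1, beta = loss rate 1->0
static inline void pmat2(double alpha, double beta, double t, arma::mat22 &P) {
  double s = alpha + beta;
  if (s <= 0.0 || t <= 0.0) {
    P.eye();
    return;
  }
  double e = std::exp(-s * t);
  P(0, 0) = (beta + alpha * e) / s;
  P(0, 1) = (alpha - alpha * e) / s;
  P(1, 0) = (beta - beta * e) / s;
  P(1, 1) = (alpha + beta * e) / s;
}

// [[Rcpp::export]]
double loglik2_cpp(const IntegerMatrix edge, const NumericVector elen,
                   const int ntip, const int nnode,
                   const IntegerVector states, const double alpha,
                   const double beta, const NumericVector prior,
                   const double floor_len) {
  const int nn = ntip + nnode;
  arma::mat part(2, nn, arma::fill::ones);
  for (int i = 0; i < ntip; ++i) {
    int s = states[i];
    if (s == 0) part(1, i) = 0.0;
    else if (s == 1) part(0, i) = 0.0;
    // s < 0: missing, both states allowed
  }
  double logscale = 0.0;
  arma::mat22 P;
  const int ne = edge.nrow();
  for (int e = 0; e < ne; ++e) {
    int par = edge(e, 0) - 1, chi = edge(e, 1) - 1;
    double t = elen[e];
    if (t < floor_len) t = floor_len;
    pmat2(alpha, beta, t, P);
    arma::vec v = P * part.col(chi);
    logscale += scale_vec(v);
    part.col(par) %= v;
  }
  int root = ntip;  // root index is ntip + 1 in R numbering
  double lik = prior[0] * part(0, root) + prior[1] * part(1, root);
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + logscale;
}

// Joint rate matrix over ordered states S1=(0,0) S2=(0,1) S3=(1,0) S4=(1,1);
// q = (q12,q13,q21,q24,q31,q34,q42,q43); dual transitions fixed at zero.
static arma::mat44 qmat4(const NumericVector q) {
  arma::mat44 Q(arma::fill::zeros);
  Q(0, 1) = q[0]; Q(0, 2) = q[1];
  Q(1, 0) = q[2]; Q(1, 3) = q[3];
  Q(2, 0) = q[4]; Q(2, 3) = q[5];
  Q(3, 1) = q[6]; Q(3, 2) = q[7];
  for (int i = 0; i < 4; ++i) Q(i, i) = -arma::accu(Q.row(i));
  return Q;
}

// [[Rcpp::export]]
double loglik4_cpp(const IntegerMatrix edge, const NumericVector elen,
                   const int ntip, const int nnode, const IntegerVector xs,
                   const IntegerVector ys, const NumericVector q,
                   const NumericVector prior, const double floor_len) {
  const int nn = ntip + nnode;
  arma::mat part(4, nn, arma::fill::ones);
  for (int i = 0; i < ntip; ++i) {
    int x = xs[i], y = ys[i];
    for (int s = 0; s < 4; ++s) {
      int sx = s >> 1, sy = s & 1;  // S1..S4 = (0,0),(0,1),(1,0),(1,1)
      bool ok = (x < 0 || x == sx) && (y < 0 || y == sy);
      if (!ok) part(s, i) = 0.0;
    }
  }
  arma::mat44 Q = qmat4(q);

  // eigen path: P(t) = Re(V diag(exp(lambda t)) V^-1)
  arma::cx_vec eval;
  arma::cx_mat evec;
  bool use_eig = arma::eig_gen(eval, evec, arma::mat(Q));
  arma::cx_mat evinv;
  if (use_eig) use_eig = arma::inv(evinv, evec);
  if (use_eig) {
    // reject ill-conditioned eigenbases (near-defective Q)
    double c = arma::norm(evec, 2) * arma::norm(evinv, 2);
    if (!std::isfinite(c) || c > 1e8) use_eig = false;
  }

  double logscale = 0.0;
  const int ne = edge.nrow();
  arma::mat44 P;
  for (int e = 0; e < ne; ++e) {
    int par = edge(e, 0) - 1, chi = edge(e, 1) - 1;
    double t = elen[e];
    if (t < floor_len) t = floor_len;
    if (use_eig) {
      arma::cx_mat Pc = evec * arma::diagmat(arma::exp(eval * t)) * evinv;
      P = arma::real(Pc);
    } else {
      P = arma::expmat(arma::mat(Q * t));
    }
    P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    arma::vec v = P * part.col(chi);
    logscale += scale_vec(v);
    part.col(par) %= v;
  }
  int root = ntip;
  double lik = 0.0;
  for (int s = 0; s < 4; ++s) lik += prior[s] * part(s, root);
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + logscale;
}
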