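// FIML likelihood core for LST-AR / MR-LST-AR moment structures.
//
// The R side passes a flat layout (one entry per structured parameter
// slot): target matrix code, 0-based indices, free-parameter index (-1 for
// fixed slots), fixed value and transform code (0 identity, 1 exp for
// variances stored on the log scale).  Matrix codes:
//   0 mu, 1 Lambda, 2 Phi trait block, 3 error variance,
//   4 beta_O, 5 var_SR, 6 beta_OPS, 7 var_SRPS.
// The occasion-factor blocks of Phi are rebuilt from the AR recursion at
// every evaluation.  Data enter as per-missingness-pattern sufficient
// statistics (observed column indices, count, mean, within-pattern
// scatter), which makes one evaluation O(#patterns * d^3) independent of n.
//
// The gradient is analytic: the pattern-wise derivative with respect to
// (mu, Sigma) is propagated through Sigma = Lambda Phi Lambda' + diag(thE)
// and through the AR impulse-response representation of the occasion
// blocks, Phi_O = A diag(varSR) A' with A[l,r] = prod(beta_{r+1..l}).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Layout {
  arma::ivec mat, mrow, mcol, fid, trans;
  arma::vec fixed;
  int I, K, L, ref;
};

struct Pattern {
  arma::uvec idx;
  double n;
  arma::vec m;
  arma::mat W;
};

struct Model {
  arma::vec mu, thE, betaO, varSR, betaOPS, varSRPS;
  arma::mat Lam, Phi, Sigma, A, APS;
  int P, Q, M, o0, p0;  // o0: first O column, p0: first OPS column (-1)
  bool two_rater;
};

Layout as_layout(const List& lay) {
  Layout L;
  L.mat = as<arma::ivec>(lay["mat"]);
  L.mrow = as<arma::ivec>(lay["mrow"]);
  L.mcol = as<arma::ivec>(lay["mcol"]);
  L.fid = as<arma::ivec>(lay["free_id"]);   // 0-based, -1 when fixed
  L.trans = as<arma::ivec>(lay["trans"]);
  L.fixed = as<arma::vec>(lay["fixed_value"]);
  L.I = as<int>(lay["I"]);
  L.K = as<int>(lay["K"]);
  L.L = as<int>(lay["L"]);
  L.ref = as<int>(lay["ref"]);
  return L;
}

std::vector<Pattern> as_patterns(const List& pats) {
  std::vector<Pattern> out(pats.size());
  for (int g = 0; g < pats.size(); ++g) {
    List p = pats[g];
    out[g].idx = as<arma::uvec>(p["idx"]);   // 0-based
    out[g].n = as<double>(p["n"]);
    out[g].m = as<arma::vec>(p["m"]);
    out[g].W = as<arma::mat>(p["W"]);
  }
  return out;
}

// Impulse-response matrix of the AR(1) recursion: A[l,r] = prod of the
// weights of transitions r+1..l (A[l,l] = 1, zero above the diagonal).
arma::mat ar_impulse(const arma::vec& beta, int L) {
  arma::mat A(L, L, arma::fill::zeros);
  for (int l = 0; l < L; ++l) {
    A(l, l) = 1.0;
    for (int r = l - 1; r >= 0; --r) A(l, r) = A(l, r + 1) * beta[r];
  }
  return A;
}

Model build_model(const arma::vec& theta, const Layout& lay) {
  Model Mo;
  int I = lay.I, K = lay.K, L = lay.L;
  int KK = (K == 2) ? 2 : 1;
  Mo.two_rater = (K == 2);
  Mo.P = I * K * L;
  Mo.M = I * KK;
  Mo.Q = I * KK + L * KK;
  Mo.o0 = Mo.M;
  Mo.p0 = Mo.two_rater ? Mo.M + L : -1;
  Mo.mu.zeros(Mo.P);
  Mo.Lam.zeros(Mo.P, Mo.Q);
  Mo.Phi.zeros(Mo.Q, Mo.Q);
  Mo.thE.zeros(Mo.P);
  Mo.betaO.zeros(std::max(L - 1, 1));
  Mo.varSR.zeros(L);
  Mo.betaOPS.zeros(std::max(L - 1, 1));
  Mo.varSRPS.zeros(L);

  int ns = lay.mat.n_elem;
  for (int s = 0; s < ns; ++s) {
    double v = (lay.fid[s] >= 0) ? theta[lay.fid[s]] : lay.fixed[s];
    if (lay.trans[s] == 1 && lay.fid[s] >= 0) v = std::exp(v);
    int r = lay.mrow[s], c = lay.mcol[s];
    switch (lay.mat[s]) {
      case 0: Mo.mu[r] = v; break;
      case 1: Mo.Lam(r, c) = v; break;
      case 2: Mo.Phi(r, c) = v; Mo.Phi(c, r) = v; break;
      case 3: Mo.thE[r] = v; break;
      case 4: Mo.betaO[r] = v; break;
      case 5: Mo.varSR[r] = v; break;
      case 6: Mo.betaOPS[r] = v; break;
      case 7: Mo.varSRPS[r] = v; break;
    }
  }
  Mo.A = ar_impulse(Mo.betaO, L);
  Mo.Phi.submat(Mo.o0, Mo.o0, Mo.o0 + L - 1, Mo.o0 + L - 1) =
      Mo.A * arma::diagmat(Mo.varSR) * Mo.A.t();
  if (Mo.two_rater) {
    Mo.APS = ar_impulse(Mo.betaOPS, L);
    Mo.Phi.submat(Mo.p0, Mo.p0, Mo.p0 + L - 1, Mo.p0 + L - 1) =
        Mo.APS * arma::diagmat(Mo.varSRPS) * Mo.APS.t();
  }
  Mo.Sigma = Mo.Lam * Mo.Phi * Mo.Lam.t();
  Mo.Sigma.diag() += Mo.thE;
  Mo.Sigma = 0.5 * (Mo.Sigma + Mo.Sigma.t());
  return Mo;
}

const double PENALTY = 1e12;
const double LOG2PI = 1.8378770664093454836;

double loglik_model(const Model& Mo, const std::vector<Pattern>& pats) {
  double ll = 0.0;
  for (size_t g = 0; g < pats.size(); ++g) {
    const Pattern& p = pats[g];
    arma::mat Sg = Mo.Sigma.submat(p.idx, p.idx);
    arma::mat R;
    if (!arma::chol(R, Sg)) return -PENALTY;
    double logdet = 2.0 * arma::sum(arma::log(R.diag()));
    arma::vec d = p.m - Mo.mu.elem(p.idx);
    arma::vec z = arma::solve(arma::trimatl(R.t()), d);
    arma::mat Si = arma::inv_sympd(Sg);
    int dg = p.idx.n_elem;
    ll += -0.5 * (p.n * (dg * LOG2PI + logdet + arma::dot(z, z)) +
                  arma::accu(Si % p.W));
  }
  if (!std::isfinite(ll)) return -PENALTY;
  return ll;
}

double loglik_impl(const arma::vec& theta, const Layout& lay,
                   const std::vector<Pattern>& pats) {
  Model Mo = build_model(theta, lay);
  return loglik_model(Mo, pats);
}

// Derivative of the AR impulse matrix entry A[l,r] with respect to
// beta_j (transition into occasion j+1, 0-based j): the product over
// transitions r+1..l with transition j+1 left out, when r <= j < l.
double dA_dbeta(const arma::vec& beta, int l, int r, int j) {
  if (!(r <= j && j < l)) return 0.0;
  double prod = 1.0;
  for (int t = r; t < l; ++t) {
    if (t == j) continue;
    prod *= beta[t];
  }
  return prod;
}

// Analytic gradient of the FIML log-likelihood on the flat vector.
bool grad_impl(const arma::vec& theta, const Layout& lay,
               const std::vector<Pattern>& pats, arma::vec& grad) {
  Model Mo = build_model(theta, lay);
  int P = Mo.P, L = lay.L;
  arma::mat G(P, P, arma::fill::zeros);   // dll / dSigma (full entries)
  arma::vec gmu(P, arma::fill::zeros);

  for (size_t g = 0; g < pats.size(); ++g) {
    const Pattern& p = pats[g];
    arma::mat Sg = Mo.Sigma.submat(p.idx, p.idx);
    arma::mat Si;
    if (!arma::inv_sympd(Si, Sg)) return false;
    arma::vec d = p.m - Mo.mu.elem(p.idx);
    arma::vec u = Si * d;
    arma::mat Gg = -0.5 * (p.n * Si - p.n * (u * u.t()) - Si * p.W * Si);
    G.submat(p.idx, p.idx) += Gg;
    arma::vec gm = p.n * u;
    for (arma::uword a = 0; a < p.idx.n_elem; ++a) gmu[p.idx[a]] += gm[a];
  }

  // backpropagate through Sigma = Lam Phi Lam' + diag(thE)
  arma::mat dLam = 2.0 * G * Mo.Lam * Mo.Phi;
  arma::mat H = Mo.Lam.t() * G * Mo.Lam;     // dll / dPhi (full entries)

  // O block: Phi_O = A V A'
  arma::mat HO = H.submat(Mo.o0, Mo.o0, Mo.o0 + L - 1, Mo.o0 + L - 1);
  arma::mat dA = 2.0 * HO * Mo.A * arma::diagmat(Mo.varSR);
  arma::mat AHA = Mo.A.t() * HO * Mo.A;
  arma::vec dvarSR = AHA.diag();
  arma::vec dbetaO(std::max(L - 1, 1), arma::fill::zeros);
  for (int j = 0; j < L - 1; ++j) {
    double s = 0.0;
    for (int l = 0; l < L; ++l)
      for (int r = 0; r <= l; ++r)
        s += dA(l, r) * dA_dbeta(Mo.betaO, l, r, j);
    dbetaO[j] = s;
  }
  arma::vec dvarSRPS, dbetaOPS;
  if (Mo.two_rater) {
    arma::mat HP = H.submat(Mo.p0, Mo.p0, Mo.p0 + L - 1, Mo.p0 + L - 1);
    arma::mat dAPS = 2.0 * HP * Mo.APS * arma::diagmat(Mo.varSRPS);
    dvarSRPS = arma::vec((Mo.APS.t() * HP * Mo.APS).eval().diag());
    dbetaOPS.zeros(std::max(L - 1, 1));
    for (int j = 0; j < L - 1; ++j) {
      double s = 0.0;
      for (int l = 0; l < L; ++l)
        for (int r = 0; r <= l; ++r)
          s += dAPS(l, r) * dA_dbeta(Mo.betaOPS, l, r, j);
      dbetaOPS[j] = s;
    }
  }

  // scatter into the free-parameter vector (chain through exp for
  // log-variance slots)
  grad.zeros(theta.n_elem);
  int ns = lay.mat.n_elem;
  for (int s = 0; s < ns; ++s) {
    int id = lay.fid[s];
    if (id < 0) continue;
    int r = lay.mrow[s], c = lay.mcol[s];
    double d = 0.0;
    switch (lay.mat[s]) {
      case 0: d = gmu[r]; break;
      case 1: d = dLam(r, c); break;
      case 2: d = (r == c) ? H(r, r) : H(r, c) + H(c, r); break;
      case 3: d = G(r, r); break;
      case 4: d = dbetaO[r]; break;
      case 5: d = dvarSR[r]; break;
      case 6: d = dbetaOPS[r]; break;
      case 7: d = dvarSRPS[r]; break;
    }
    if (lay.trans[s] == 1) d *= std::exp(theta[id]);
    grad[id] += d;
  }
  return grad.is_finite();
}

}  // namespace

// [[Rcpp::export]]
List cpp_implied_moments(const arma::vec& theta, const List& layout) {
  Layout lay = as_layout(layout);
  Model Mo = build_model(theta, lay);
  return List::create(_["mu"] = Mo.mu, _["sigma"] = Mo.Sigma);
}

// [[Rcpp::export]]
double cpp_fiml_loglik(const arma::vec& theta, const List& layout,
                       const List& patterns) {
  Layout lay = as_layout(layout);
  std::vector<Pattern> pats = as_patterns(patterns);
  return loglik_impl(theta, lay, pats);
}

// [[Rcpp::export]]
arma::vec cpp_fiml_grad(const arma::vec& theta, const List& layout,
                        const List& patterns) {
  Layout lay = as_layout(layout);
  std::vector<Pattern> pats = as_patterns(patterns);
  arma::vec g;
  if (!grad_impl(theta, lay, pats, g)) g.zeros(theta.n_elem);
  return g;
}

// Central-difference gradient, kept as an independent cross-check of the
// analytic gradient.
// [[Rcpp::export]]
arma::vec cpp_fiml_grad_num(const arma::vec& theta, const List& layout,
                            const List& patterns, double h = 1e-6) {
  Layout lay = as_layout(layout);
  std::vector<Pattern> pats = as_patterns(patterns);
  int p = theta.n_elem;
  arma::vec g(p);
  arma::vec th = theta;
  for (int j = 0; j < p; ++j) {
    double hj = h * std::max(1.0, std::abs(theta[j]));
    th[j] = theta[j] + hj;
    double fp = loglik_impl(th, lay, pats);
    th[j] = theta[j] - hj;
    double fm = loglik_impl(th, lay, pats);
    th[j] = theta[j];
    g[j] = (fp - fm) / (2.0 * hj);
  }
  return g;
}

// Log-likelihood of arbitrary (mu, Sigma) under the same pattern
// sufficient statistics; used for the saturated and baseline models.
// [[Rcpp::export]]
double cpp_mvn_pattern_loglik(const arma::vec& mu, const arma::mat& Sigma,
                              const List& patterns) {
  std::vector<Pattern> pats = as_patterns(patterns);
  double ll = 0.0;
  for (size_t g = 0; g < pats.size(); ++g) {
    const Pattern& p = pats[g];
    arma::mat Sg = Sigma.submat(p.idx, p.idx);
    arma::mat R;
    if (!arma::chol(R, Sg)) return -PENALTY;
    double logdet = 2.0 * arma::sum(arma::log(R.diag()));
    arma::vec d = p.m - mu.elem(p.idx);
    arma::vec z = arma::solve(arma::trimatl(R.t()), d);
    arma::mat Si = arma::inv_sympd(Sg);
    int dg = p.idx.n_elem;
    ll += -0.5 * (p.n * (dg * LOG2PI + logdet + arma::dot(z, z)) +
                  arma::accu(Si % p.W));
  }
  return ll;
}
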