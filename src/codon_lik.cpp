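// Codon substitution branch-model likelihood on a 3-taxon star tree.
//
// The rate matrix is the Goldman-Yang style single-matrix model:
// q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous] for codon pairs
// differing at one position, scaled to one expected substitution per codon
// per unit branch length. The model is reversible, so the symmetrised
// matrix S = D Q D^-1 (D = diag(sqrt(pi))) is diagonalised once per omega
// and branch transition matrices are assembled as
// P(t) = D^-1 V exp(L t) V' D.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat build_Q(double kappa, double omega, const vec& pi,
                   const imat& single, const imat& ts, const imat& syn) {
  const uword n = pi.n_elem;
  mat Q(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    for (uword j = 0; j < n; ++j) {
      if (i == j || !single(i, j)) continue;
      double r = pi(j);
      if (ts(i, j)) r *= kappa;
      if (!syn(i, j)) r *= omega;
      Q(i, j) = r;
    }
  }
  vec rs = sum(Q, 1);
  Q.diag() = -rs;
  double rate = dot(pi, rs);
  if (rate > 0) Q /= rate;
  return Q;
}

struct Decomp { vec lam; mat V; };

// tiny cache: finite-difference gradients re-evaluate with most parameters
// unchanged, so identical (kappa, omega, pi) triples recur many times
struct CacheEntry { double kappa, omega, pisum; Decomp d; bool used = false; };
static CacheEntry cache_slots[8];
static int cache_next = 0;

static Decomp decompose(const mat& Q, const vec& pi) {
  vec sq = sqrt(pi);
  mat S = Q;
  const uword n = pi.n_elem;
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j < n; ++j)
      S(i, j) *= sq(i) / sq(j);
  S = 0.5 * (S + S.t());  // kill round-off asymmetry
  Decomp d;
  eig_sym(d.lam, d.V, S);
  return d;
}

static mat pmat_from(const Decomp& d, const vec& pi, double t) {
  vec sq = sqrt(pi);
  mat E = d.V * diagmat(exp(d.lam * t)) * d.V.t();
  const uword n = pi.n_elem;
  mat P(n, n);
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j < n; ++j) {
      double v = E(i, j) * sq(j) / sq(i);
      P(i, j) = v > 0 ? v : 0.0;
    }
  return P;
}

// [[Rcpp::export(name = ".codon_loglik_cpp")]]
double codon_loglik_cpp(const arma::vec& pi, double kappa,
                        const arma::vec& omegas, const arma::vec& tvec,
                        const arma::imat& patt, const arma::vec& wt,
                        const arma::imat& single, const arma::imat& ts,
                        const arma::imat& syn) {
  const uword nb = omegas.n_elem;            // branches (tips of the star)
  const uword npat = patt.n_cols;            // patt: nb x npat, 0-based codons
  if (patt.n_rows != nb) Rcpp::stop("pattern/branch mismatch");
  // decompose once per distinct omega value, with a cross-call cache
  double pisum = dot(pi, linspace<vec>(1, pi.n_elem, pi.n_elem));
  std::vector<mat> P(nb);
  std::vector<double> seen;
  std::vector<Decomp> dec;
  std::vector<uword> which(nb);
  for (uword b = 0; b < nb; ++b) {
    uword k = seen.size();
    for (uword s = 0; s < seen.size(); ++s)
      if (seen[s] == omegas(b)) { k = s; break; }
    if (k == seen.size()) {
      seen.push_back(omegas(b));
      Decomp* hit = nullptr;
      for (auto& e : cache_slots)
        if (e.used && e.kappa == kappa && e.omega == omegas(b) &&
            e.pisum == pisum) { hit = &e.d; break; }
      if (hit) {
        dec.push_back(*hit);
      } else {
        Decomp d = decompose(build_Q(kappa, omegas(b), pi, single, ts, syn), pi);
        cache_slots[cache_next] = {kappa, omegas(b), pisum, d, true};
        cache_next = (cache_next + 1) % 8;
        dec.push_back(d);
      }
    }
    which[b] = k;
  }
  for (uword b = 0; b < nb; ++b)
    P[b] = pmat_from(dec[which[b]], pi, tvec(b));
  double lnL = 0.0;
  vec acc(pi.n_elem);
  for (uword p = 0; p < npat; ++p) {
    acc = pi;
    for (uword b = 0; b < nb; ++b)
      acc %= P[b].col(patt(b, p));
    double s = accu(acc);
    if (!(s > 0)) return -1e300;
    lnL += wt(p) * std::log(s);
  }
  return lnL;
}

// [[Rcpp::export(name = ".codon_pmat_cpp")]]
arma::mat codon_pmat_cpp(const arma::vec& pi, double kappa, double omega,
                         double t, const arma::imat& single,
                         const arma::imat& ts, const arma::imat& syn) {
  Decomp d = decompose(build_Q(kappa, omega, pi, single, ts, syn), pi);
  mat P = pmat_from(d, pi, t);
  // renormalise rows against clamping round-off
  for (uword i = 0; i < P.n_rows; ++i) {
    double rs = accu(P.row(i));
    if (rs > 0) P.row(i) /= rs;
  }
  return P;
}
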