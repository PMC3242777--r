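// Felsenstein pruning over the 61 sense-codon states, with per-class,
// per-edge omega assignment (site, branch and branch-site mixtures all
// reduce to this), analytic branch-length gradients, and reuse of subtree
// partials between site classes whose omega assignments agree on a whole
// subtree (e.g. background-only subtrees under branch-site models).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct EigenSys {
  mat A;     // D^{-1/2} U
  mat Ainv;  // U' D^{1/2}
  vec lam;
  mat Q;     // scaled generator
};

// Scaled reversible generator for one omega, symmetric-eigendecomposed.
EigenSys build_eigen(const imat& pairType, const vec& pi, double kappa,
                     double omega) {
  const uword n = 61;
  mat S(n, n, fill::zeros);
  const double fac[5] = {0.0, kappa, 1.0, kappa * omega, omega};
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j < n; ++j) {
      int t = pairType(i, j);
      if (t > 0) S(i, j) = fac[t];
    }
  mat Q = S.each_row() % pi.t();
  vec rs = sum(Q, 1);
  Q.diag() = -rs;
  double scale = dot(pi, rs);  // expected substitutions per unit time
  Q /= scale;
  vec sq = sqrt(pi);
  mat B = Q.each_col() % sq;
  B.each_row() /= sq.t();
  B = 0.5 * (B + B.t());
  vec lam;
  mat U;
  eig_sym(lam, U, B);
  EigenSys es;
  es.A = U.each_col() / sq;
  es.Ainv = U.t();
  es.Ainv.each_row() %= sq.t();
  es.lam = lam;
  es.Q = Q;
  return es;
}

inline mat pmat(const EigenSys& es, double t) {
  mat As = es.A;
  As.each_row() %= exp(es.lam * t).t();
  mat P = As * es.Ainv;
  P.clamp(0.0, datum::inf);
  return P;
}

inline void rescale_cols(mat& part, rowvec& sc, bool track) {
  rowvec m = max(part, 0);
  m.transform([](double v) { return v > 0 ? v : 1.0; });
  part.each_row() /= m;
  if (track) sc += log(m);
}

} // namespace

// tipStates: ntaxa x nsites, values 1..61, NA for missing.
// edge: E x 2 (1-based ape node ids), rows in postorder (children first).
// omegaIdx: E x K, 1-based index into omegas, per edge per class.
// rateMult: E x K class rate multipliers; the effective length of edge e
//   for class k is edgeLen[e] * rateMult(e, k) (mixture-average scaling:
//   branch lengths are expected substitutions per codon averaged over
//   classes, classes with more nonsynonymous flow evolve faster).
// classWeights: K mixture proportions.
// Returns lnL, per-site log-likelihood, K x S per-class site log-likelihoods
// and, optionally, the gradient of lnL w.r.t. each edge length.
// [[Rcpp::export]]
Rcpp::List cpp_pruning(const Rcpp::IntegerMatrix tipStates,
                       const Rcpp::IntegerMatrix edge,
                       const Rcpp::NumericVector edgeLen,
                       const Rcpp::IntegerMatrix omegaIdx,
                       const Rcpp::NumericMatrix rateMult,
                       const Rcpp::NumericVector omegas_,
                       double kappa,
                       const Rcpp::NumericVector pi_,
                       const Rcpp::IntegerMatrix pairType_,
                       const Rcpp::NumericVector classWeights,
                       const Rcpp::NumericVector patternWeights,
                       bool gradient) {
  const int ntip = tipStates.nrow();
  const int S = tipStates.ncol();
  const int E = edge.nrow();
  const int K = omegaIdx.ncol();
  const int nnode = E + 1;
  const vec pi(pi_.begin(), 61);
  const vec omegas(omegas_.begin(), omegas_.size());
  imat pairType(61, 61);
  for (int i = 0; i < 61; ++i)
    for (int j = 0; j < 61; ++j) pairType(i, j) = pairType_(i, j);

  std::vector<EigenSys> eigs;
  for (uword w = 0; w < omegas.n_elem; ++w)
    eigs.push_back(build_eigen(pairType, pi, kappa, omegas(w)));

  const int root = edge(E - 1, 0) - 1;

  std::vector<std::vector<int>> child_edges(nnode);
  std::vector<int> edge_of_node(nnode, -1);
  for (int e = 0; e < E; ++e) {
    child_edges[edge(e, 0) - 1].push_back(e);
    edge_of_node[edge(e, 1) - 1] = e;
  }

  // P-matrix cache keyed by (edge, omega index, rate multiplier)
  struct PEntry { int w; double m; mat P; };
  std::vector<std::vector<PEntry>> Pcache(E);
  auto getP = [&](int e, int k) -> const mat& {
    int w = omegaIdx(e, k) - 1;
    double m = rateMult(e, k);
    for (auto& pe : Pcache[e])
      if (pe.w == w && pe.m == m) return pe.P;
    Pcache[e].push_back({w, m, pmat(eigs[w], edgeLen[e] * m)});
    return Pcache[e].back().P;
  };

  // tip partials, shared by all classes
  std::vector<mat> down(nnode);
  std::vector<rowvec> dscale(nnode);
  for (int i = 0; i < ntip; ++i) {
    down[i].set_size(61, S);
    down[i].zeros();
    for (int s = 0; s < S; ++s) {
      int st = tipStates(i, s);
      if (st == NA_INTEGER) down[i].col(s).ones();
      else down[i](st - 1, s) = 1.0;
    }
    dscale[i] = rowvec(S, fill::zeros);
  }

  // subtree signature per internal node: hash of omega indices over all
  // edges below it; a node is recomputed only when its signature changes
  std::vector<long long> stored_hash(nnode, -1);

  mat classSiteLoglik(K, S);
  for (int k = 0; k < K; ++k) {
    std::vector<long long> hash(nnode, 1);
    for (int e = 0; e < E; ++e) {
      int child = edge(e, 1) - 1;
      int parent = edge(e, 0) - 1;
      long long key = (long long)omegaIdx(e, k) * 1000003LL +
                      (long long)std::llround(rateMult(e, k) * 1e9);
      long long h = hash[child] * 131LL + key * 7919LL + e;
      hash[parent] = hash[parent] * 31LL + h;
    }
    for (int e = 0; e < E; ++e) {
      int parent = edge(e, 0) - 1;
      if (stored_hash[parent] == hash[parent]) continue;
      if (e != child_edges[parent].back()) continue;  // compute once, when
                                                      // all children ready
      mat part(61, S, fill::ones);
      rowvec sc(S, fill::zeros);
      for (int ce : child_edges[parent]) {
        int ch = edge(ce, 1) - 1;
        part %= (getP(ce, k) * down[ch]);
        sc += dscale[ch];
      }
      rescale_cols(part, sc, true);
      down[parent] = std::move(part);
      dscale[parent] = sc;
      stored_hash[parent] = hash[parent];
    }
    vec sl = (pi.t() * down[root]).t();
    for (int s = 0; s < S; ++s)
      classSiteLoglik(k, s) = std::log(std::max(sl(s), 1e-300)) +
                              dscale[root](s);
  }

  // mixture combine
  vec w(classWeights.begin(), K);
  vec siteLoglik(S);
  mat postw(K, S);
  for (int s = 0; s < S; ++s) {
    double m = classSiteLoglik.col(s).max();
    double tot = 0;
    for (int k = 0; k < K; ++k) {
      double v = (w(k) > 0 ? w(k) * std::exp(classSiteLoglik(k, s) - m) : 0.0);
      postw(k, s) = v;
      tot += v;
    }
    siteLoglik(s) = m + std::log(tot);
    postw.col(s) /= tot;
  }
  const vec wpat(patternWeights.begin(), S);
  double lnL = dot(wpat, siteLoglik);

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("lnL") = lnL,
      Rcpp::Named("siteLoglik") =
          Rcpp::NumericVector(siteLoglik.begin(), siteLoglik.end()),
      Rcpp::Named("classSiteLoglik") = Rcpp::wrap(classSiteLoglik));

  if (gradient) {
    // d lnL / d t_e = sum_k postw_{k,s} * [U'(Q P)D]_s / [U' P D]_s,
    // scale factors cancelling in the ratio.
    vec grad(E, fill::zeros);
    for (int k = 0; k < K; ++k) {
      if (w(k) <= 0) continue;
      std::vector<mat> D(nnode);
      std::vector<mat> M(E);
      for (int i = 0; i < ntip; ++i) D[i] = down[i];
      for (int e = 0; e < E; ++e) {
        int parent = edge(e, 0) - 1;
        if (e != child_edges[parent].back()) continue;
        mat part(61, S, fill::ones);
        for (int ce : child_edges[parent]) {
          int ch = edge(ce, 1) - 1;
          M[ce] = getP(ce, k) * D[ch];
          part %= M[ce];
        }
        rowvec dummy;
        rescale_cols(part, dummy, false);
        D[parent] = std::move(part);
      }
      std::vector<mat> U(E);
      for (int e = E - 1; e >= 0; --e) {
        int parent = edge(e, 0) - 1;
        mat u;
        if (parent == root) {
          u.set_size(61, S);
          u.each_col() = pi;
        } else {
          int pe = edge_of_node[parent];
          u = getP(pe, k).t() * U[pe];
        }
        for (int ce : child_edges[parent]) {
          if (ce == e) continue;
          u %= M[ce];
        }
        rowvec dummy;
        rescale_cols(u, dummy, false);
        U[e] = std::move(u);
      }
      for (int e = 0; e < E; ++e) {
        int ch = edge(e, 1) - 1;
        int widx = omegaIdx(e, k) - 1;
        const mat& P = getP(e, k);
        mat PD = P * D[ch];
        mat QPD = eigs[widx].Q * PD;
        rowvec numer = sum(U[e] % QPD, 0);
        rowvec denom = sum(U[e] % PD, 0);
        double g = 0;
        for (int s = 0; s < S; ++s)
          if (denom(s) > 0) g += wpat(s) * postw(k, s) * numer(s) / denom(s);
        grad(e) += rateMult(e, k) * g;
      }
    }
    out["grad"] = Rcpp::NumericVector(grad.begin(), grad.end());
  }
  return out;
}
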