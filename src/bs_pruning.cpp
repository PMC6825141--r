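// Felsenstein pruning for the branch-site codon model.
// Transition matrices are built from cached symmetric eigendecompositions
// (P(t) = A diag(exp(lambda t)) B) once per (edge, omega) pair.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Build the unscaled GY94 generator for one omega from the change-type
// matrix `kind` (0 none, 1 syn tv, 2 syn ts, 3 nonsyn tv, 4 nonsyn ts).
static mat gy94_Q(const imat& kind, const double kappa, const double omega,
                  const vec& pi) {
  const int n = pi.n_elem;
  const double mult[5] = {0.0, 1.0, kappa, omega, omega * kappa};
  mat Q(n, n, fill::zeros);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) {
      const int k = kind(i, j);
      if (k > 0) Q(i, j) = mult[k] * pi(j);
    }
  }
  Q.diag() = -sum(Q, 1);
  return Q;
}

// Symmetrized eigendecomposition of a reversible generator: returns A, B
// with P(t) = A diag(exp(lambda t)) B.
struct Eig { mat A, B; vec lambda; };
static Eig rev_eigen(const mat& Q, const vec& pi) {
  const vec d = sqrt(pi);
  mat S = Q;
  S.each_col() %= d;
  S.each_row() /= d.t();
  S = 0.5 * (S + S.t());
  Eig e;
  mat V;
  eig_sym(e.lambda, V, S);
  e.A = V.each_col() / d;
  e.B = V.t();
  e.B.each_row() %= d.t();
  return e;
}

// Full branch-site model A log-likelihood: builds the class rate matrices
// for (omega0, 1, omega2), applies the joint background-rate scaling, and
// runs the pruning for the four site classes.
// [[Rcpp::export]]
double bs_lnL_cpp(const arma::imat& edge, const arma::vec& elen,
                  const int ntip, const int root, const int fg_node,
                  const arma::imat& codidx, const arma::vec& weights,
                  const arma::imat& kind, const double kappa,
                  const double omega0, const double omega2,
                  const arma::vec& props, const arma::vec& pi) {
  const int nedge = edge.n_rows;
  const int npat = codidx.n_cols;
  const int nstate = pi.n_elem;
  int nnode = root;
  for (int e = 0; e < nedge; ++e) {
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));
  }
  // distinct omegas: 0 -> omega0, 1 -> neutral, 2 -> omega2
  mat Q0 = gy94_Q(kind, kappa, omega0, pi);
  mat Q1 = gy94_Q(kind, kappa, 1.0, pi);
  const double r0 = -dot(pi, Q0.diag());
  const double r1 = -dot(pi, Q1.diag());
  const double scale = (props(0) + props(2)) * r0 + (props(1) + props(3)) * r1;
  std::vector<Eig> eigs(3);
  eigs[0] = rev_eigen(Q0 / scale, pi);
  eigs[1] = rev_eigen(Q1 / scale, pi);
  if (omega2 == 1.0) {
    eigs[2] = eigs[1];
  } else if (omega2 == omega0) {
    eigs[2] = eigs[0];
  } else {
    eigs[2] = rev_eigen(gy94_Q(kind, kappa, omega2, pi) / scale, pi);
  }
  // class omega ids (bg, fg): 0:(w0,w0) 1:(1,1) 2a:(w0,w2) 2b:(1,w2)
  const int class_bg[4] = {0, 1, 0, 1};
  const int class_fg[4] = {0, 1, 2, 2};

  std::map<std::pair<int, int>, mat> pcache;
  auto getP = [&](int e, int w) -> const mat& {
    auto key = std::make_pair(e, w);
    auto it = pcache.find(key);
    if (it != pcache.end()) return it->second;
    mat P = eigs[w].A * (exp(eigs[w].lambda * elen(e)) % eigs[w].B.each_col());
    P.clamp(0.0, datum::inf);
    return pcache.emplace(key, std::move(P)).first->second;
  };

  vec sitelik(npat, fill::zeros);
  std::vector<mat> partial(nnode + 1);
  std::vector<bool> seen(nnode + 1);
  for (int cl = 0; cl < 4; ++cl) {
    if (props(cl) <= 0) continue;
    std::fill(seen.begin(), seen.end(), false);
    for (int e = 0; e < nedge; ++e) {
      const int parent = edge(e, 0);
      const int child = edge(e, 1);
      const bool fg = (fg_node > 0 && child == fg_node);
      const mat& P = getP(e, fg ? class_fg[cl] : class_bg[cl]);
      mat msg(nstate, npat);
      if (child <= ntip) {
        for (int s = 0; s < npat; ++s) {
          const int idx = codidx(child - 1, s);
          if (idx > 0) {
            msg.col(s) = P.col(idx - 1);
          } else {
            msg.col(s).ones();
          }
        }
      } else {
        msg = P * partial[child];
      }
      if (!seen[parent]) {
        partial[parent] = std::move(msg);
        seen[parent] = true;
      } else {
        partial[parent] %= msg;
      }
    }
    sitelik += props(cl) * (partial[root].t() * pi);
  }
  double lnL = 0.0;
  for (int s = 0; s < npat; ++s) {
    if (!(sitelik(s) > 0) || !std::isfinite(sitelik(s))) {
      return -datum::inf;
    }
    lnL += weights(s) * std::log(sitelik(s));
  }
  return lnL;
}

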