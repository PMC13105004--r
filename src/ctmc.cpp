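#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& Q, double t) {
  return expmat(Q * t);
}

// Sparse CSR view of the generator's off-diagonals. The chromosome
// model's Q has at most five nonzero off-diagonals per row (gain, loss,
// polyploidy, two demiploidy targets), so exp(Qt) * v is computed by
// uniformization: with lambda = max exit rate and A = I + Q / lambda,
// exp(Qt) v = sum_k Poisson(k; lambda t) A^k v. All terms are
// non-negative, so the scheme is stable at any parameter value,
// including boundary cases where Q is defective and eigendecomposition
// fails.
struct SparseGen {
  int S;
  double lambda;                 // uniformization rate
  std::vector<int> ptr, idx;     // CSR of off-diagonal entries of Q
  std::vector<double> val;
  std::vector<double> diag_a;    // diagonal of A = 1 + Q_ii / lambda

  explicit SparseGen(const mat& Q) : S(Q.n_rows) {
    lambda = 0.0;
    for (int i = 0; i < S; ++i) lambda = std::max(lambda, -Q(i, i));
    ptr.resize(S + 1, 0);
    diag_a.resize(S);
    const double lam = (lambda > 0) ? lambda : 1.0;
    for (int i = 0; i < S; ++i) {
      diag_a[i] = 1.0 + Q(i, i) / lam;
      for (int j = 0; j < S; ++j)
        if (j != i && Q(i, j) != 0.0) {
          idx.push_back(j);
          val.push_back(Q(i, j) / lam);
        }
      ptr[i + 1] = static_cast<int>(idx.size());
    }
  }

  // w = A * v
  void amul(const std::vector<double>& v, std::vector<double>& w) const {
    for (int i = 0; i < S; ++i) {
      double s = diag_a[i] * v[i];
      for (int k = ptr[i]; k < ptr[i + 1]; ++k) s += val[k] * v[idx[k]];
      w[i] = s;
    }
  }

  // v <- exp(Q t) * v
  void propagate(std::vector<double>& v, double t) const {
    const double a = lambda * t;
    if (!(a > 1e-14)) return;
    const int K = static_cast<int>(std::ceil(a + 10.0 * std::sqrt(a + 1.0) + 10.0));
    std::vector<double> acc(S), w = v, tmp(S);
    // Poisson(k; a) weights, accumulated relative to their running max
    // and renormalized at the end (guards against underflow at large a)
    double lw = -a, lwmax = lw;
    std::vector<double> lws(K + 1);
    lws[0] = lw;
    const double la = std::log(a);
    for (int k = 1; k <= K; ++k) {
      lw += la - std::log(static_cast<double>(k));
      lws[k] = lw;
      if (lw > lwmax) lwmax = lw;
    }
    double wsum = 0.0;
    double wk = std::exp(lws[0] - lwmax);
    wsum += wk;
    for (int i = 0; i < S; ++i) acc[i] = wk * w[i];
    for (int k = 1; k <= K; ++k) {
      amul(w, tmp);
      w.swap(tmp);
      wk = std::exp(lws[k] - lwmax);
      if (wk > 0.0) {
        wsum += wk;
        for (int i = 0; i < S; ++i) acc[i] += wk * w[i];
      }
    }
    for (int i = 0; i < S; ++i) v[i] = acc[i] / wsum;
  }
};

// Felsenstein pruning over a postorder edge list (ape 1-based indices).
// partials: S x n_tips, tip columns in node-index order 1..n_tips.
// root_mode: 0 = fitzjohn, 1 = uniform, 2 = fixed (root_state 1-based).
// Per-node partials are rescaled to max 1 with the log scalers
// accumulated, so 100+-tip trees do not underflow.
// [[Rcpp::export]]
Rcpp::List cpp_prune_loglik(const Rcpp::IntegerMatrix& edge,
                            const Rcpp::NumericVector& lengths,
                            const arma::mat& partials,
                            const arma::mat& Q,
                            int n_tips, int n_nodes,
                            int root_mode, int root_state) {
  const int S = Q.n_rows;
  const int nE = edge.nrow();
  SparseGen gen(Q);

  std::vector<std::vector<double>> part(n_nodes, std::vector<double>(S, 1.0));
  for (int j = 0; j < n_tips; ++j)
    for (int i = 0; i < S; ++i) part[j][i] = partials(i, j);

  double logscale = 0.0;
  bool impossible = false;
  for (int e = 0; e < nE && !impossible; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    std::vector<double> v = part[c];
    gen.propagate(v, lengths[e]);
    double m = 0.0;
    for (int i = 0; i < S; ++i) {
      if (v[i] < 0.0) v[i] = 0.0;
      if (v[i] > m) m = v[i];
    }
    if (!(m > 0.0) || !std::isfinite(m)) { impossible = true; break; }
    logscale += std::log(m);
    for (int i = 0; i < S; ++i) part[p][i] *= v[i] / m;
  }

  vec rootp(S, fill::zeros);
  double ll = R_NegInf;
  if (!impossible) {
    for (int i = 0; i < S; ++i) rootp(i) = part[n_tips][i]; // root = n_tips + 1
    const double s = accu(rootp);
    double L = 0.0;
    if (root_mode == 0) {          // FitzJohn: weights w_i = L_i / sum(L)
      if (s > 0.0) L = accu(rootp % rootp) / s;
    } else if (root_mode == 1) {   // uniform root prior
      L = s / S;
    } else {                       // fixed state
      L = rootp(root_state - 1);
    }
    if (L > 0.0) ll = std::log(L) + logscale;
    else impossible = true;
    if (s > 0.0) rootp /= s;
  }

  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("root_dist") = rootp,
                            Rcpp::Named("impossible") = impossible);
}
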