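#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
#include <vector>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning over a rooted binary time-tree.
//
// Nodes are indexed 1..(2n-1); tips are 1..n_tips and sit at height 0.
// parent[i] == 0 marks the root; child1/child2[i] == 0 marks a tip.
// tipdata holds one column per site pattern, entries 0..19 in model state
// order, or -1 for gap/unknown (treated as missing data).
//
// Partial likelihoods are kept as 20 x n_patterns blocks per node so the
// per-branch propagation is a single dgemm; per-node per-pattern scaling
// with log accumulation prevents underflow. Category likelihoods (equal
// weights) are combined by log-sum-exp.
// [[Rcpp::export]]
double prune_loglik_cpp(IntegerVector parent, IntegerVector child1,
                        IntegerVector child2, NumericVector height,
                        int root, int n_tips, IntegerMatrix tipdata,
                        NumericVector weights, NumericMatrix eigvec,
                        NumericVector eigval, NumericVector freqs,
                        NumericVector rates) {
  const int n_nodes = parent.size();
  const int n_pat = tipdata.ncol();
  const int k = rates.size();
  const int S = 20;

  std::vector<double> sq(S), isq(S);
  for (int a = 0; a < S; ++a) {
    sq[a] = std::sqrt(freqs[a]);
    isq[a] = 1.0 / sq[a];
  }

  // postorder list of internal nodes (children before parents)
  std::vector<int> post;
  post.reserve(n_nodes);
  {
    std::vector<int> stack;
    stack.push_back(root);
    while (!stack.empty()) {
      int nd = stack.back();
      stack.pop_back();
      if (child1[nd - 1] > 0) {
        post.push_back(nd);
        stack.push_back(child1[nd - 1]);
        stack.push_back(child2[nd - 1]);
      }
    }
    std::reverse(post.begin(), post.end());
  }

  std::vector<double> collog(static_cast<size_t>(n_pat) * k);
  std::vector<double> P(static_cast<size_t>(n_nodes) * S * S);  // column-major
  std::vector<double> L(static_cast<size_t>(n_nodes) * S * n_pat);
  std::vector<double> Xu(static_cast<size_t>(S) * n_pat);
  std::vector<double> Xv(static_cast<size_t>(S) * n_pat);
  std::vector<double> scale(n_pat);
  const double one = 1.0, zero = 0.0;
  const int Si = S;

  for (int c = 0; c < k; ++c) {
    for (int nd = 1; nd <= n_nodes; ++nd) {
      if (parent[nd - 1] == 0) continue;
      double t = (height[parent[nd - 1] - 1] - height[nd - 1]) * rates[c];
      if (t < 0) stop("negative branch length in pruning");
      double expl[20];
      for (int m = 0; m < S; ++m) expl[m] = std::exp(eigval[m] * t);
      double* Pn = &P[static_cast<size_t>(nd - 1) * S * S];
      for (int b = 0; b < S; ++b) {
        for (int a = 0; a < S; ++a) {
          double e = 0.0;
          for (int m = 0; m < S; ++m)
            e += eigvec(a, m) * expl[m] * eigvec(b, m);
          double p = e * isq[a] * sq[b];
          Pn[a + S * b] = p > 0.0 ? p : 0.0;   // P[a,b], column-major
        }
      }
    }

    std::fill(scale.begin(), scale.end(), 0.0);
    for (size_t idx = 0; idx < post.size(); ++idx) {
      int nd = post[idx];
      int ch[2] = {child1[nd - 1], child2[nd - 1]};
      double* Xs[2] = {Xu.data(), Xv.data()};
      for (int s2 = 0; s2 < 2; ++s2) {
        int u = ch[s2];
        const double* Pu = &P[static_cast<size_t>(u - 1) * S * S];
        double* X = Xs[s2];
        if (child1[u - 1] == 0) {             // tip child: gather P columns
          for (int j = 0; j < n_pat; ++j) {
            int st = tipdata(u - 1, j);
            if (st < 0) {
              for (int a = 0; a < S; ++a) X[a + S * j] = 1.0;
            } else {
              const double* col = &Pu[S * st];
              for (int a = 0; a < S; ++a) X[a + S * j] = col[a];
            }
          }
        } else {
          const double* Lu = &L[static_cast<size_t>(u - 1) * S * n_pat];
          F77_CALL(dgemm)("N", "N", &Si, &n_pat, &Si, &one, Pu, &Si,
                          Lu, &Si, &zero, X, &Si FCONE FCONE);
        }
      }
      double* Ln = &L[static_cast<size_t>(nd - 1) * S * n_pat];
      for (int j = 0; j < n_pat; ++j) {
        double mx = 0.0;
        for (int a = 0; a < S; ++a) {
          double val = Xu[a + S * j] * Xv[a + S * j];
          Ln[a + S * j] = val;
          if (val > mx) mx = val;
        }
        if (mx <= 0.0) return R_NegInf;
        double inv = 1.0 / mx;
        for (int a = 0; a < S; ++a) Ln[a + S * j] *= inv;
        scale[j] += std::log(mx);
      }
    }

    if (post.empty()) {                        // single-tip tree
      for (int j = 0; j < n_pat; ++j) {
        int st = tipdata(root - 1, j);
        collog[static_cast<size_t>(j) * k + c] =
          st < 0 ? 0.0 : std::log(freqs[st]);
      }
    } else {
      const double* Lr = &L[static_cast<size_t>(root - 1) * S * n_pat];
      for (int j = 0; j < n_pat; ++j) {
        double lik = 0.0;
        for (int a = 0; a < S; ++a) lik += freqs[a] * Lr[a + S * j];
        collog[static_cast<size_t>(j) * k + c] = std::log(lik) + scale[j];
      }
    }
  }

  double total = 0.0;
  const double logk = std::log(static_cast<double>(k));
  for (int j = 0; j < n_pat; ++j) {
    const double* cl = &collog[static_cast<size_t>(j) * k];
    double mx = cl[0];
    for (int c = 1; c < k; ++c)
      if (cl[c] > mx) mx = cl[c];
    double s = 0.0;
    for (int c = 0; c < k; ++c) s += std::exp(cl[c] - mx);
    total += weights[j] * (mx + std::log(s) - logk);
  }
  return total;
}
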