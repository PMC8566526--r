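// Exact local Shapley values for tree ensembles via the path-dependent
// polynomial-time recursion (EXTEND/UNWIND over decision paths, conditional
// expectations defined by per-node training coverage). Feature indices are
// compact 0-based indices over the features actually used by the ensemble;
// unused features have Shapley value zero by the dummy axiom and are handled
// on the R side.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathElement {
  int d;        // feature of the split that led here (-1 for the root)
  double z;     // fraction of "zero" (cold) paths flowing through
  double o;     // fraction of "one" (hot) paths flowing through
  double w;     // permutation weight
};

struct Tree {
  std::vector<int> feature, left, right;
  std::vector<double> value, cover;
};

static void extend_path(std::vector<PathElement>& m, double pz, double po,
                        int pi) {
  int l = (int)m.size();
  m.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / double(l + 1);
    m[i].w = pz * m[i].w * (l - i) / double(l + 1);
  }
}

static std::vector<PathElement> unwind_path(const std::vector<PathElement>& m,
                                            int i) {
  int l = (int)m.size() - 1;
  std::vector<PathElement> out(m);
  double n = out[l].w;
  const double o = m[i].o, z = m[i].z;
  for (int j = l - 1; j >= 0; --j) {
    if (o != 0) {
      double t = out[j].w;
      out[j].w = n * (l + 1) / double((j + 1) * o);
      n = t - out[j].w * z * (l - j) / double(l + 1);
    } else {
      out[j].w = out[j].w * (l + 1) / (z * (l - j));
    }
  }
  for (int j = i; j < l; ++j) {
    out[j].d = out[j + 1].d;
    out[j].z = out[j + 1].z;
    out[j].o = out[j + 1].o;
  }
  out.pop_back();
  return out;
}

static void recurse(const Tree& T, int j, std::vector<PathElement> m,
                    double pz, double po, int pi, const int* x,
                    double* phi) {
  extend_path(m, pz, po, pi);
  if (T.feature[j] < 0) {                       // leaf
    for (size_t i = 1; i < m.size(); ++i) {
      std::vector<PathElement> um = unwind_path(m, (int)i);
      double w = 0.0;
      for (size_t k = 0; k < um.size(); ++k) w += um[k].w;
      phi[m[i].d] += w * (m[i].o - m[i].z) * T.value[j];
    }
    return;
  }
  const int d = T.feature[j];
  int hot, cold;
  if (x[d]) { hot = T.right[j]; cold = T.left[j]; }
  else      { hot = T.left[j];  cold = T.right[j]; }
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (size_t i = 1; i < m.size(); ++i)
    if (m[i].d == d) { k = (int)i; break; }
  if (k >= 0) {
    iz = m[k].z; io = m[k].o;
    m = unwind_path(m, k);
  }
  const double rj = T.cover[j];
  recurse(T, hot, m, iz * T.cover[hot] / rj, io, d, x, phi);
  recurse(T, cold, m, iz * T.cover[cold] / rj, 0.0, d, x, phi);
}

// trees: list of lists with integer vectors `feature`, `left`, `right`
// (0-based, -1 where absent) and numeric `value`, `cover`.
// X: instances x compact-features binary matrix.
// Returns instances x compact-features matrix of ensemble Shapley values
// (mean over trees).
// [[Rcpp::export]]
NumericMatrix shap_path_dependent_cpp(List trees, IntegerMatrix X) {
  const int n = X.nrow(), p = X.ncol(), T_n = trees.size();
  std::vector<Tree> forest(T_n);
  for (int t = 0; t < T_n; ++t) {
    List tr = trees[t];
    IntegerVector f = tr["feature"], le = tr["left"], ri = tr["right"];
    NumericVector v = tr["value"], c = tr["cover"];
    Tree& T = forest[t];
    T.feature.assign(f.begin(), f.end());
    T.left.assign(le.begin(), le.end());
    T.right.assign(ri.begin(), ri.end());
    T.value.assign(v.begin(), v.end());
    T.cover.assign(c.begin(), c.end());
    for (size_t j = 0; j < T.cover.size(); ++j)
      if (T.feature[j] >= 0 && T.cover[j] <= 0)
        stop("tree %d: non-positive coverage at internal node %d", t + 1,
             (int)j + 1);
  }
  NumericMatrix phi(n, p);
  std::vector<int> x(p);
  std::vector<double> acc(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) x[j] = X(i, j);
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int t = 0; t < T_n; ++t) {
      std::vector<PathElement> m;
      m.reserve(64);
      recurse(forest[t], 0, m, 1.0, 1.0, -1, x.data(), acc.data());
    }
    for (int j = 0; j < p; ++j) phi(i, j) = acc[j] / T_n;
  }
  return phi;
}
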