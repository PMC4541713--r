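// Vietoris-Rips persistent homology over GF(2) by boundary-matrix
// reduction. Simplices up to dimension max_dim + 1 are enumerated with
// filtration value = longest pairwise distance; columns are reduced in
// filtration order with the standard pivot-pairing algorithm. Sizes here
// (tens of points, low dimension) do not call for the clearing/cohomology
// optimizations of dedicated TDA libraries.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Simplex {
  std::vector<int> verts;  // ascending
  double filt;
  int dim;
};

void enum_combos(int n, int k, std::vector<std::vector<int>>& out) {
  std::vector<int> idx(k);
  for (int i = 0; i < k; ++i) idx[i] = i;
  while (true) {
    out.push_back(idx);
    int i = k - 1;
    while (i >= 0 && idx[i] == n - k + i) --i;
    if (i < 0) break;
    ++idx[i];
    for (int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
  }
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_rips_persistence(NumericMatrix d, int max_dim,
                               double threshold) {
  const int n = d.nrow();
  const int top = max_dim + 1;  // need (max_dim+1)-simplices to kill H_max_dim
  std::vector<Simplex> simplices;
  for (int v = 0; v < n; ++v)
    simplices.push_back({{v}, 0.0, 0});
  for (int k = 2; k <= top + 1; ++k) {
    std::vector<std::vector<int>> combos;
    if (k <= n) enum_combos(n, k, combos);
    for (auto& c : combos) {
      double f = 0.0;
      bool ok = true;
      for (int a = 0; a < k && ok; ++a)
        for (int b = a + 1; b < k; ++b) {
          double dd = d(c[a], c[b]);
          if (dd > threshold) { ok = false; break; }
          if (dd > f) f = dd;
        }
      if (ok) simplices.push_back({c, f, k - 1});
    }
  }
  const int m = (int)simplices.size();
  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (simplices[a].filt != simplices[b].filt)
      return simplices[a].filt < simplices[b].filt;
    if (simplices[a].dim != simplices[b].dim)
      return simplices[a].dim < simplices[b].dim;
    return simplices[a].verts < simplices[b].verts;  // lexicographic
  });
  std::vector<int> pos(m);
  for (int i = 0; i < m; ++i) pos[order[i]] = i;

  // map from vertex set to sorted position, for facet lookup
  std::map<std::vector<int>, int> index_of;
  for (int i = 0; i < m; ++i) index_of[simplices[order[i]].verts] = i;

  // reduction
  std::vector<std::vector<int>> R(m);        // reduced columns (facet pos)
  std::vector<int> pivot_owner(m, -1);       // pivot row -> column
  std::vector<char> is_positive(m, 0);       // column reduced to zero
  for (int j = 0; j < m; ++j) {
    const Simplex& s = simplices[order[j]];
    if (s.dim == 0) { is_positive[j] = 1; continue; }
    std::vector<int> col;
    for (size_t drop = 0; drop <= s.verts.size() - 1; ++drop) {
      // face = verts without position `drop`
      std::vector<int> f;
      f.reserve(s.verts.size() - 1);
      for (size_t t = 0; t < s.verts.size(); ++t)
        if (t != drop) f.push_back(s.verts[t]);
      col.push_back(index_of[f]);
    }
    std::sort(col.begin(), col.end());
    while (!col.empty()) {
      int low = col.back();
      int owner = pivot_owner[low];
      if (owner < 0) break;
      // col ^= R[owner] (symmetric difference of sorted vectors)
      std::vector<int> merged;
      std::set_symmetric_difference(col.begin(), col.end(),
                                    R[owner].begin(), R[owner].end(),
                                    std::back_inserter(merged));
      col.swap(merged);
    }
    if (col.empty()) {
      is_positive[j] = 1;
    } else {
      int low = col.back();
      pivot_owner[low] = j;
      R[j] = col;
    }
  }

  std::vector<int> out_dim;
  std::vector<double> out_birth, out_death;
  for (int j = 0; j < m; ++j) {
    if (!is_positive[j]) continue;
    const Simplex& s = simplices[order[j]];
    if (s.dim > max_dim) continue;  // creators above max_dim not reported
    int killer = pivot_owner[j];
    if (killer < 0) {
      out_dim.push_back(s.dim);
      out_birth.push_back(s.filt);
      out_death.push_back(R_PosInf);
    } else {
      double death = simplices[order[killer]].filt;
      if (death > s.filt) {  // drop zero-persistence pairs
        out_dim.push_back(s.dim);
        out_birth.push_back(s.filt);
        out_death.push_back(death);
      }
    }
  }
  return DataFrame::create(_["dim"] = out_dim, _["birth"] = out_birth,
                           _["death"] = out_death);
}
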