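#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <vector>
using namespace Rcpp;

namespace {

struct Simp {
  std::vector<int> v;  // sorted vertex indices, 0-based
  double val;          // appearance threshold
  int dim;
};

bool simp_less(const Simp& a, const Simp& b) {
  if (a.val != b.val) return a.val < b.val;
  if (a.dim != b.dim) return a.dim < b.dim;
  return a.v < b.v;
}

}  // namespace

// Build the Vietoris-Rips filtration of a finite metric space by incremental
// expansion: every simplex is generated exactly once by extending its sorted
// vertex prefix with a larger vertex adjacent (within eps_max) to all current
// vertices. Appearance value = max pairwise distance among the vertices.
// [[Rcpp::export]]
List rips_complex_cpp(NumericMatrix d, int max_dim, double eps_max) {
  const int n = d.nrow();
  std::vector<Simp> simps;
  simps.reserve(static_cast<size_t>(n) * 4);
  for (int i = 0; i < n; ++i) simps.push_back(Simp{{i}, 0.0, 0});

  // upper neighbour lists under the threshold
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (d(i, j) <= eps_max) nb[i].push_back(j);

  std::vector<Simp> frontier;
  if (max_dim >= 1) {
    for (int i = 0; i < n; ++i)
      for (int j : nb[i]) frontier.push_back(Simp{{i, j}, d(i, j), 1});
    simps.insert(simps.end(), frontier.begin(), frontier.end());
  }
  for (int dim = 2; dim <= max_dim; ++dim) {
    std::vector<Simp> next;
    for (const Simp& s : frontier) {
      const int last = s.v.back();
      for (int u : nb[last]) {
        double val = s.val;
        bool ok = true;
        for (int w : s.v) {
          const double dw = d(w, u);
          if (dw > eps_max) { ok = false; break; }
          if (dw > val) val = dw;
        }
        if (!ok) continue;
        Simp t;
        t.v = s.v;
        t.v.push_back(u);
        t.val = val;
        t.dim = dim;
        next.push_back(std::move(t));
      }
    }
    simps.insert(simps.end(), next.begin(), next.end());
    frontier.swap(next);
  }

  std::sort(simps.begin(), simps.end(), simp_less);

  const int m = static_cast<int>(simps.size());
  IntegerVector dims(m);
  NumericVector vals(m);
  List verts(m);
  for (int i = 0; i < m; ++i) {
    dims[i] = simps[i].dim;
    vals[i] = simps[i].val;
    IntegerVector vv(simps[i].v.size());
    for (size_t k = 0; k < simps[i].v.size(); ++k) vv[k] = simps[i].v[k] + 1;
    verts[i] = vv;
  }
  return List::create(_["dim"] = dims, _["value"] = vals,
                      _["vertices"] = verts);
}

// Persistence pairing by standard column reduction of the GF(2) boundary
// matrix in filtration order. Input simplices must be sorted so that every
// face precedes its cofaces; vertices are 1-based sorted integer vectors.
// Returns one row per interval; death is NA for essential classes.
// [[Rcpp::export]]
DataFrame reduce_filtration_cpp(List vertices, IntegerVector dim,
                                NumericVector value) {
  const int m = vertices.size();
  std::map<std::vector<int>, int> index;
  std::vector<std::vector<int>> cols(m);

  for (int j = 0; j < m; ++j) {
    IntegerVector vv = vertices[j];
    std::vector<int> v(vv.begin(), vv.end());
    if (v.size() > 1) {
      std::vector<int> bd;
      bd.reserve(v.size());
      std::vector<int> face(v.size() - 1);
      for (size_t k = 0; k < v.size(); ++k) {
        size_t t = 0;
        for (size_t l = 0; l < v.size(); ++l)
          if (l != k) face[t++] = v[l];
        std::map<std::vector<int>, int>::const_iterator it = index.find(face);
        if (it == index.end())
          stop("filtration violates closure: simplex at position %d has a "
               "missing or later face", j + 1);
        bd.push_back(it->second);
      }
      std::sort(bd.begin(), bd.end());
      cols[j] = bd;
    }
    index[v] = j;
  }

  std::vector<int> pivot_of(m, -1);       // row -> column with that pivot
  std::vector<int> creator_of(m, -1);     // destroyer column -> creator row
  for (int j = 0; j < m; ++j) {
    std::vector<int>& col = cols[j];
    while (!col.empty()) {
      const int low = col.back();
      const int k = pivot_of[low];
      if (k < 0) break;
      std::vector<int> merged;
      std::set_symmetric_difference(col.begin(), col.end(), cols[k].begin(),
                                    cols[k].end(),
                                    std::back_inserter(merged));
      col.swap(merged);
    }
    if (!col.empty()) {
      pivot_of[col.back()] = j;
      creator_of[j] = col.back();
    }
  }

  std::vector<bool> killed(m, false);
  for (int j = 0; j < m; ++j)
    if (creator_of[j] >= 0) killed[creator_of[j]] = true;

  std::vector<int> idim;
  std::vector<double> ibirth, ideath;
  for (int j = 0; j < m; ++j) {
    if (creator_of[j] >= 0) {
      const int i = creator_of[j];
      if (value[j] > value[i]) {  // zero-length intervals are invisible
        idim.push_back(dim[i]);
        ibirth.push_back(value[i]);
        ideath.push_back(value[j]);
      }
    } else if (cols[j].empty() && !killed[j]) {
      idim.push_back(dim[j]);
      ibirth.push_back(value[j]);
      ideath.push_back(NA_REAL);
    }
  }
  return DataFrame::create(_["dimension"] = idim, _["birth"] = ibirth,
                           _["death"] = ideath);
}
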