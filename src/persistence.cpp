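// Vietoris-Rips persistent cohomology over Z_p with representative cocycles.
//
// Matrix reduction runs on the coboundary matrix in reverse filtration order
// (the standard persistent-cohomology formulation), with the two classic
// optimizations that make Rips computations tractable:
//   * clearing: death simplices of dimension d+1 found while reducing
//     dimension-d columns are skipped as columns in dimension d+1;
//   * emergent-pair shortcut: a column whose first coface (in decreasing
//     combinatorial index order) has the same diameter as the column simplex,
//     and whose coface is not yet claimed as a pivot, forms a zero-persistence
//     pair and is never reduced explicitly.
// Reduced columns are stored implicitly as combinations of column simplices
// (the "V" matrix); a V column doubles as the representative cocycle of the
// bar born at its column simplex.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
#include <queue>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

typedef int64_t index_t;
typedef float value_t;

struct entry_t {
  value_t diam;
  index_t index;
  int coeff;
};

// "a before b" in reverse filtration order (decreasing diameter, increasing
// index); as a heap comparator this puts the pivot (smallest diameter,
// largest index) on top.
struct rev_order {
  bool operator()(const entry_t& a, const entry_t& b) const {
    return a.diam > b.diam || (a.diam == b.diam && a.index < b.index);
  }
};

struct diameter_index_t {
  value_t diam;
  index_t index;
};

struct rev_order_di {
  bool operator()(const diameter_index_t& a, const diameter_index_t& b) const {
    return a.diam > b.diam || (a.diam == b.diam && a.index < b.index);
  }
};

class UnionFind {
  std::vector<index_t> parent;
  std::vector<int> rank_;

public:
  explicit UnionFind(index_t n) : parent(n), rank_(n, 0) {
    for (index_t i = 0; i < n; ++i) parent[i] = i;
  }
  index_t find(index_t x) {
    index_t y = x, z;
    while ((z = parent[y]) != y) y = z;
    while (parent[x] != y) {
      z = parent[x];
      parent[x] = y;
      x = z;
    }
    return y;
  }
  void link(index_t x, index_t y) {
    x = find(x);
    y = find(y);
    if (x == y) return;
    if (rank_[x] > rank_[y]) std::swap(x, y);
    parent[x] = y;
    if (rank_[x] == rank_[y]) ++rank_[y];
  }
};

class RipsComplex {
public:
  index_t n;
  int maxdim;
  value_t threshold;
  int modulus;
  std::vector<value_t> dist;                 // n*n row-major
  std::vector<std::vector<index_t>> binom;   // binom[k][v] = C(v, k)
  std::vector<int> inverse;                  // multiplicative inverses mod p

  RipsComplex(const NumericMatrix& d, int maxdim_, double threshold_, int p)
      : n(d.nrow()), maxdim(maxdim_), threshold((value_t)threshold_), modulus(p) {
    dist.resize(n * n);
    for (index_t i = 0; i < n; ++i)
      for (index_t j = 0; j < n; ++j) dist[i * n + j] = (value_t)d(i, j);
    int K = maxdim + 3;
    binom.assign(K, std::vector<index_t>(n + 1, 0));
    for (index_t v = 0; v <= n; ++v) binom[0][v] = 1;
    for (int k = 1; k < K; ++k)
      for (index_t v = 1; v <= n; ++v)
        binom[k][v] = binom[k - 1][v - 1] + binom[k][v - 1];
    inverse.assign(p, 0);
    if (p > 1) {
      inverse[1] = 1;
      for (int a = 2; a < p; ++a)
        inverse[a] = (int)(p - (int64_t)(p / a) * inverse[p % a] % p);
    }
  }

  value_t d(index_t i, index_t j) const { return dist[i * n + j]; }

  // largest v <= hi with C(v, k) <= idx
  index_t max_vertex(index_t idx, int k, index_t hi) const {
    index_t lo = (index_t)k - 1;
    if (binom[k][hi] <= idx) return hi;
    while (hi - lo > 1) {
      index_t mid = (lo + hi) / 2;
      if (binom[k][mid] <= idx)
        lo = mid;
      else
        hi = mid;
    }
    return lo;
  }

  // vertices of the dim-simplex with combinatorial index idx, descending
  void vertices_of(index_t idx, int dim, index_t* vs) const {
    index_t v = n - 1;
    for (int k = dim + 1; k > 0; --k) {
      v = max_vertex(idx, k, v);
      vs[dim + 1 - k] = v;
      idx -= binom[k][v];
      --v;
    }
  }

  value_t diameter_of(const index_t* vs, int dim) const {
    value_t m = 0;
    for (int a = 0; a <= dim; ++a)
      for (int b = a + 1; b <= dim; ++b) m = std::max(m, d(vs[a], vs[b]));
    return m;
  }
};

// Enumerates cofaces of a d-simplex in decreasing combinatorial index order.
struct CofaceEnumerator {
  const RipsComplex& R;
  const index_t* vs;  // descending vertices of the simplex
  int dim;            // simplex dimension d
  index_t w;          // candidate new vertex, scans n-1 .. 0
  int pos;            // #vertices of vs greater than w
  std::vector<index_t> above;  // prefix sums with raised binomial slots
  std::vector<index_t> below;  // suffix sums with original slots

  CofaceEnumerator(const RipsComplex& R_, const index_t* vs_, int dim_)
      : R(R_), vs(vs_), dim(dim_), w(R_.n - 1), pos(0) {
    int k = dim + 1;  // number of vertices
    above.assign(k + 1, 0);
    below.assign(k + 1, 0);
    for (int q = 0; q < k; ++q)
      above[q + 1] = above[q] + R.binom[dim + 2 - q][vs[q]];
    for (int q = k - 1; q >= 0; --q)
      below[q] = below[q + 1] + R.binom[dim + 1 - q][vs[q]];
  }

  // returns false when exhausted; fills coface index, diameter, sign position
  bool next(index_t& idx, value_t& diam, int& asc_pos) {
    while (w >= 0) {
      if (pos <= dim && vs[pos] == w) {
        ++pos;
        --w;
        continue;
      }
      idx = above[pos] + R.binom[dim + 2 - pos][w] + below[pos];
      diam = 0;
      for (int q = 0; q <= dim; ++q) diam = std::max(diam, R.d(w, vs[q]));
      asc_pos = dim + 1 - pos;  // position of w in ascending vertex order
      --w;
      return true;
    }
    return false;
  }
};

typedef std::priority_queue<entry_t, std::vector<entry_t>, rev_order> Column;
typedef std::vector<std::pair<index_t, int>> VColumn;

static bool pop_pivot(Column& col, int modulus, entry_t& out) {
  while (!col.empty()) {
    entry_t e = col.top();
    col.pop();
    int c = e.coeff % modulus;
    while (!col.empty() && col.top().index == e.index) {
      c = (c + col.top().coeff) % modulus;
      col.pop();
    }
    if (c != 0) {
      e.coeff = c;
      col.push(e);  // keep the column intact
      out = e;
      return true;
    }
  }
  return false;
}

struct PivotInfo {
  int32_t column;
  int coeff;  // coefficient of the pivot entry in that reduced column
};

// [[Rcpp::export(name = ".rips_cohomology")]]
List rips_cohomology(NumericMatrix dmat, int maxdim = 1, double threshold = -1.0,
                     int modulus = 47, bool do_cocycles = true) {
  index_t n = dmat.nrow();
  if (n != (index_t)dmat.ncol()) stop("distance matrix must be square");
  if (maxdim < 0) stop("maxdim must be >= 0");
  for (index_t i = 0; i < n; ++i)
    for (index_t j = 0; j < n; ++j)
      if (!R_finite(dmat(i, j))) stop("non-finite distances are not allowed");

  if (threshold < 0) {
    // enclosing radius: min over points of its eccentricity; the complex is a
    // cone (hence contractible) at this scale, so all finite bars are captured
    double enc = std::numeric_limits<double>::infinity();
    for (index_t i = 0; i < n; ++i) {
      double ecc = 0;
      for (index_t j = 0; j < n; ++j) ecc = std::max(ecc, (double)dmat(i, j));
      enc = std::min(enc, ecc);
    }
    threshold = (n > 1) ? enc : 0.0;
  }

  RipsComplex R(dmat, maxdim, threshold, modulus);

  std::vector<double> out_dim, out_birth, out_death;
  std::vector<VColumn> stored_cocycles;  // one per dim-1 bar emitted
  std::vector<int> cocycle_slot;         // row of the bar each cocycle represents

  // ---- dimension 0 via union-find -------------------------------------
  std::vector<diameter_index_t> edges;
  edges.reserve((size_t)(n * (n - 1) / 2));
  for (index_t i = 1; i < n; ++i)
    for (index_t j = 0; j < i; ++j) {
      value_t dij = R.d(i, j);
      if (dij <= R.threshold)
        edges.push_back({dij, R.binom[2][i] + R.binom[1][j]});
    }
  // ascending filtration order for union-find = reverse of rev_order
  std::sort(edges.begin(), edges.end(), rev_order_di());
  std::vector<char> is_cycle_edge(edges.size(), 0);
  {
    UnionFind uf(n);
    for (size_t e = edges.size(); e-- > 0;) {
      index_t vs[2];
      R.vertices_of(edges[e].index, 1, vs);
      index_t ri = uf.find(vs[0]), rj = uf.find(vs[1]);
      if (ri != rj) {
        uf.link(ri, rj);
        if (edges[e].diam > 0) {
          out_dim.push_back(0);
          out_birth.push_back(0);
          out_death.push_back(edges[e].diam);
        }
      } else {
        is_cycle_edge[e] = 1;
      }
    }
    std::vector<char> seen(n, 0);
    for (index_t v = 0; v < n; ++v) {
      index_t r = uf.find(v);
      if (!seen[r]) {
        seen[r] = 1;
        out_dim.push_back(0);
        out_birth.push_back(0);
        out_death.push_back(R_PosInf);
      }
    }
  }

  // ---- dimensions 1..maxdim -------------------------------------------
  std::vector<diameter_index_t> columns;
  columns.reserve(edges.size());
  for (size_t e = 0; e < edges.size(); ++e)
    if (is_cycle_edge[e]) columns.push_back(edges[e]);
  // already in rev_order

  std::unordered_map<index_t, PivotInfo> pivots;

  for (int dim = 1; dim <= maxdim && n > 0; ++dim) {
    pivots.clear();
    pivots.reserve(columns.size());
    std::unordered_map<int32_t, VColumn> v_store;

    std::vector<index_t> vs(dim + 1);
    std::vector<index_t> vs_other(dim + 1);

    for (int32_t ci = 0; ci < (int32_t)columns.size(); ++ci) {
      const diameter_index_t col = columns[ci];
      R.vertices_of(col.index, dim, vs.data());

      Column working;
      VColumn cur_v;
      cur_v.push_back({col.index, 1});

      // initialize coboundary with emergent-pair shortcut
      entry_t pivot;
      bool have_pivot = false;
      bool emergent = false;
      {
        CofaceEnumerator cofaces(R, vs.data(), dim);
        std::vector<entry_t> buffer;
        bool check_emergent = true;
        index_t cidx;
        value_t cdiam;
        int apos;
        while (cofaces.next(cidx, cdiam, apos)) {
          value_t full = std::max(col.diam, cdiam);
          if (full > R.threshold) continue;
          int sgn = (apos % 2 == 0) ? 1 : modulus - 1;
          buffer.push_back({full, cidx, sgn});
          if (check_emergent && full == col.diam) {
            if (pivots.find(cidx) == pivots.end()) {
              pivot = buffer.back();
              have_pivot = true;
              emergent = true;
              break;
            }
            check_emergent = false;
          }
        }
        if (!emergent) {
          for (const entry_t& e : buffer) working.push(e);
          have_pivot = pop_pivot(working, modulus, pivot);
        }
      }

      // reduce
      while (true) {
        if (!have_pivot) {
          // essential class in this dimension
          out_dim.push_back(dim);
          out_birth.push_back(col.diam);
          out_death.push_back(R_PosInf);
          if (dim == 1 && do_cocycles) {
            cocycle_slot.push_back((int)out_dim.size() - 1);
            stored_cocycles.push_back(cur_v);
          }
          break;
        }
        auto it = pivots.find(pivot.index);
        if (it == pivots.end()) {
          pivots[pivot.index] = {ci, pivot.coeff};
          if (pivot.diam > col.diam) {
            out_dim.push_back(dim);
            out_birth.push_back(col.diam);
            out_death.push_back(pivot.diam);
            if (dim == 1 && do_cocycles) {
              cocycle_slot.push_back((int)out_dim.size() - 1);
              stored_cocycles.push_back(cur_v);
            }
          }
          if (!emergent) v_store[ci] = cur_v;
          break;
        }
        // add factor * column j to cancel the pivot
        const PivotInfo pj = it->second;
        int factor =
            (int)((int64_t)(modulus - pivot.coeff) * R.inverse[pj.coeff] % modulus);
        const VColumn* vj_ptr = nullptr;
        VColumn trivial;
        auto vit = v_store.find(pj.column);
        if (vit != v_store.end())
          vj_ptr = &vit->second;
        else {
          trivial.push_back({columns[pj.column].index, 1});
          vj_ptr = &trivial;
        }
        for (const auto& term : *vj_ptr) {
          int c = (int)((int64_t)term.second * factor % modulus);
          if (c == 0) continue;
          cur_v.push_back({term.first, c});
          R.vertices_of(term.first, dim, vs_other.data());
          value_t sdiam = R.diameter_of(vs_other.data(), dim);
          CofaceEnumerator cof(R, vs_other.data(), dim);
          index_t cidx;
          value_t cdiam;
          int apos;
          while (cof.next(cidx, cdiam, apos)) {
            value_t full = std::max(sdiam, cdiam);
            if (full > R.threshold) continue;
            int sgn = (apos % 2 == 0) ? 1 : modulus - 1;
            working.push({full, cidx, (int)((int64_t)sgn * c % modulus)});
          }
        }
        have_pivot = pop_pivot(working, modulus, pivot);
      }
      if (ci % 4096 == 0) Rcpp::checkUserInterrupt();
    }

    // assemble columns for the next dimension, applying clearing
    if (dim < maxdim) {
      std::vector<diameter_index_t> next_cols;
      if (dim + 1 == 2) {
        for (index_t i = 2; i < n; ++i) {
          for (index_t j = 1; j < i; ++j) {
            value_t dij = R.d(i, j);
            if (dij > R.threshold) continue;
            index_t base = R.binom[3][i] + R.binom[2][j];
            for (index_t k = 0; k < j; ++k) {
              value_t diam = std::max(dij, std::max(R.d(i, k), R.d(j, k)));
              if (diam > R.threshold) continue;
              index_t idx = base + k;
              if (pivots.find(idx) != pivots.end()) continue;
              next_cols.push_back({diam, idx});
            }
          }
          Rcpp::checkUserInterrupt();
        }
      } else {
        // generic enumeration for higher dimensions (not used by default)
        index_t total = R.binom[dim + 2][n];
        std::vector<index_t> vtx(dim + 2);
        for (index_t idx = 0; idx < total; ++idx) {
          R.vertices_of(idx, dim + 1, vtx.data());
          value_t diam = R.diameter_of(vtx.data(), dim + 1);
          if (diam > R.threshold) continue;
          if (pivots.find(idx) != pivots.end()) continue;
          next_cols.push_back({diam, idx});
        }
      }
      std::sort(next_cols.begin(), next_cols.end(), rev_order_di());
      columns.swap(next_cols);
    }
  }

  // decode dim-1 cocycles: edges as 0-based vertex pairs plus coefficient
  List cocycles_out(stored_cocycles.size());
  for (size_t q = 0; q < stored_cocycles.size(); ++q) {
    VColumn vcol = stored_cocycles[q];
    // combine repeated simplices modulo p and drop zero terms
    std::sort(vcol.begin(), vcol.end());
    VColumn merged;
    for (size_t r = 0; r < vcol.size();) {
      index_t ix = vcol[r].first;
      int c = 0;
      while (r < vcol.size() && vcol[r].first == ix) {
        c = (c + vcol[r].second) % modulus;
        ++r;
      }
      if (c != 0) merged.push_back({ix, c});
    }
    vcol = merged;
    IntegerMatrix m((int)vcol.size(), 3);
    for (size_t r = 0; r < vcol.size(); ++r) {
      index_t vs2[2];
      R.vertices_of(vcol[r].first, 1, vs2);
      m((int)r, 0) = (int)vs2[0];
      m((int)r, 1) = (int)vs2[1];
      m((int)r, 2) = vcol[r].second;
    }
    cocycles_out[q] = m;
  }

  return List::create(
      _["dim"] = wrap(out_dim), _["birth"] = wrap(out_birth),
      _["death"] = wrap(out_death), _["cocycle_bar"] = wrap(cocycle_slot),
      _["cocycles"] = cocycles_out, _["threshold"] = (double)R.threshold,
      _["modulus"] = modulus);
}
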