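// Spatial rebalancing scan of the tumour lattice (hot path).
//
// Works on the same states matrix as cyto_core.cpp (one column per GC),
// plus the voxel bookkeeping: `index` is the flattened 3-D voxel array
// holding 0 (non-tumour) or the 1-based column id, `coords` the 1-based
// voxel coordinate of each column, `active` the live flag.  All inputs
// are modified in place; the R wrapper owns the copy discipline.
//
// Tie-breaks are decided by a deterministic hash of (id, hour, seed), so
// a run is reproducible bit-for-bit from its seed and independent of the
// storage order of the columns.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double tie_hash(double id, int seed, int hour) {
  double x = id * 2654435761.0 + hour * 7919.0 + seed * 104729.0;
  const double m = 2147483647.0;
  return x - std::floor(x / m) * m;
}

struct Scan {
  double* S;
  int nr;
  int* index;
  int* coords;   // column-major ncol x 3
  int* active;
  int ncolS;
  int nx, ny, nz;
  double cap;
  int seed, hour;

  double colsum(int j) const {  // j 0-based
    const double* v = S + (R_xlen_t)nr * j;
    double s = 0;
    for (int k = 0; k < nr; ++k) s += v[k];
    return s;
  }
  // move fraction of column a into column b (0-based)
  void move(int a, int b, double frac) {
    double* va = S + (R_xlen_t)nr * a;
    double* vb = S + (R_xlen_t)nr * b;
    if (frac >= 1.0) {
      for (int k = 0; k < nr; ++k) { vb[k] += va[k]; va[k] = 0.0; }
    } else {
      for (int k = 0; k < nr; ++k) {
        double amt = va[k] * frac;
        va[k] -= amt; vb[k] += amt;
      }
    }
  }
  inline int vox(int i, int j, int k) const {  // 1-based voxel coords
    return (i - 1) + nx * ((j - 1) + ny * (k - 1));
  }
  inline int voxid(int col) const {  // 0-based column -> voxel linear id
    return vox(coords[col], coords[col + ncolS], coords[col + 2 * ncolS]);
  }
  // 6-neighbourhood of column j: active column ids in nb_cols, free
  // in-bounds voxel linear ids in nb_free; returns counts via refs.
  void neighbours(int j, int* nb_cols, int& n_cols, int* nb_free,
                  int& n_free) const {
    int ci = coords[j], cj = coords[j + ncolS], ck = coords[j + 2 * ncolS];
    n_cols = 0; n_free = 0;
    const int di[6] = {-1, 1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, -1, 1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, -1, 1};
    for (int m = 0; m < 6; ++m) {
      int i2 = ci + di[m], j2 = cj + dj[m], k2 = ck + dk[m];
      if (i2 < 1 || i2 > nx || j2 < 1 || j2 > ny || k2 < 1 || k2 > nz)
        continue;
      int v = vox(i2, j2, k2);
      int col = index[v];
      if (col > 0) nb_cols[n_cols++] = col - 1;
      else nb_free[n_free++] = v;
    }
  }
};

// [[Rcpp::export]]
List spatial_scan_cpp(NumericMatrix S, IntegerVector index,
                      IntegerMatrix coords, LogicalVector active,
                      IntegerVector dims, double capacity,
                      double floor_frac, int seed, int hour,
                      IntegerVector free_slots, int max_passes = 30) {
  Scan sc;
  sc.S = REAL(S); sc.nr = S.nrow();
  sc.index = INTEGER(index);
  sc.coords = INTEGER(coords);
  sc.active = LOGICAL(active);
  sc.ncolS = coords.nrow();
  sc.nx = dims[0]; sc.ny = dims[1]; sc.nz = dims[2];
  sc.cap = capacity; sc.seed = seed; sc.hour = hour;
  const int ncol = S.ncol();
  if (coords.nrow() != ncol || active.size() != ncol)
    stop("coords/active not aligned with states");

  std::vector<double> tot(ncol, 0.0);
  std::vector<int> act;
  act.reserve(ncol);
  for (int j = 0; j < ncol; ++j)
    if (sc.active[j]) { act.push_back(j); tot[j] = sc.colsum(j); }

  int n_free_slots = free_slots.size();
  int next_slot = 0;
  int annexed = 0, dissolved = 0;
  bool out_of_slots = false;
  int nb_cols[6], nb_free[6], n_cols, n_free;
  const double tol = 1e-12 * capacity;

  // ---- spill passes: push surplus outward, annex at the boundary ----
  for (int pass = 0; pass < max_passes; ++pass) {
    std::vector<std::pair<double, int> > over;
    for (size_t a = 0; a < act.size(); ++a) {
      int j = act[a];
      if (sc.active[j] && tot[j] > capacity + tol)
        over.push_back(std::make_pair(tie_hash(sc.voxid(j) + 1, seed, hour), j));
    }
    if (over.empty()) break;
    std::sort(over.begin(), over.end());
    bool moved = false;
    for (size_t o = 0; o < over.size(); ++o) {
      int j = over[o].second;
      if (tot[j] <= capacity + tol) continue;
      sc.neighbours(j, nb_cols, n_cols, nb_free, n_free);
      int dest = -1;
      double best_tot = R_PosInf, best_hash = R_PosInf;
      for (int m = 0; m < n_cols; ++m) {
        int d = nb_cols[m];
        if (!sc.active[d] || tot[d] >= capacity) continue;
        double h = tie_hash(sc.voxid(d) + 1, seed, hour);
        if (tot[d] < best_tot || (tot[d] == best_tot && h < best_hash)) {
          best_tot = tot[d]; best_hash = h; dest = d;
        }
      }
      if (dest < 0 && n_free > 0) {
        // annex the free neighbour voxel with the smallest hash
        int pick = nb_free[0];
        double bh = tie_hash(nb_free[0] + 1, seed, hour);
        for (int m = 1; m < n_free; ++m) {
          double h = tie_hash(nb_free[m] + 1, seed, hour);
          if (h < bh) { bh = h; pick = nb_free[m]; }
        }
        if (next_slot >= n_free_slots) { out_of_slots = true; break; }
        dest = free_slots[next_slot++] - 1;
        for (int k = 0; k < sc.nr; ++k) sc.S[(R_xlen_t)sc.nr * dest + k] = 0.0;
        sc.active[dest] = TRUE;
        tot[dest] = 0.0;
        int k2 = pick / (sc.nx * sc.ny);
        int rem2 = pick - k2 * sc.nx * sc.ny;
        int j2 = rem2 / sc.nx, i2 = rem2 - j2 * sc.nx;
        sc.coords[dest] = i2 + 1;
        sc.coords[dest + sc.ncolS] = j2 + 1;
        sc.coords[dest + 2 * sc.ncolS] = k2 + 1;
        sc.index[pick] = dest + 1;
        act.push_back(dest);
        ++annexed;
      }
      if (dest < 0) continue;  // boxed in: surplus stays put
      double frac = (tot[j] - capacity) / tot[j];
      sc.move(j, dest, frac);
      tot[dest] = sc.colsum(dest);
      tot[j] = sc.colsum(j);
      moved = true;
    }
    if (out_of_slots || !moved) break;
  }

  // ---- dissolution: contract the shrinking tumour, boundary first ----
  {
    std::vector<int> low;
    for (size_t a = 0; a < act.size(); ++a) {
      int j = act[a];
      if (sc.active[j] && tot[j] < floor_frac * capacity) low.push_back(j);
    }
    if (!low.empty()) {
      // sort: most boundary-like first (fewest active neighbours), hash ties
      std::vector<std::pair<std::pair<int, double>, int> > keyed(low.size());
      for (size_t a = 0; a < low.size(); ++a) {
        sc.neighbours(low[a], nb_cols, n_cols, nb_free, n_free);
        int n_act = 0;
        for (int m = 0; m < n_cols; ++m) if (sc.active[nb_cols[m]]) ++n_act;
        keyed[a] = std::make_pair(
          std::make_pair(n_act, tie_hash(sc.voxid(low[a]) + 1, seed, hour)), low[a]);
      }
      std::sort(keyed.begin(), keyed.end());
      for (size_t a = 0; a < keyed.size(); ++a) {
        int j = keyed[a].second;
        if (!sc.active[j]) continue;
        double rem = tot[j];
        sc.neighbours(j, nb_cols, n_cols, nb_free, n_free);
        std::vector<std::pair<std::pair<double, double>, int> > dsts;
        for (int m = 0; m < n_cols; ++m) {
          int d = nb_cols[m];
          if (sc.active[d])
            dsts.push_back(std::make_pair(
              std::make_pair(-tot[d], tie_hash(sc.voxid(d) + 1, seed, hour)), d));
        }
        if (rem > 0 && dsts.empty()) continue;  // isolated remnant: keep
        std::sort(dsts.begin(), dsts.end());
        for (size_t m = 0; m < dsts.size() && rem > 0; ++m) {
          int d = dsts[m].second;
          double space = capacity - tot[d];
          if (space <= 0) continue;
          if (space >= rem) {
            sc.move(j, d, 1.0);   // column zeroes exactly
            tot[d] = sc.colsum(d);
            rem = 0.0;
          } else {
            sc.move(j, d, space / rem);
            tot[d] = sc.colsum(d);
            rem = sc.colsum(j);
            tot[j] = rem;
          }
        }
        if (rem == 0.0) {
          sc.active[j] = FALSE;
          tot[j] = 0.0;
          int ci = sc.coords[j], cj = sc.coords[j + sc.ncolS],
              ck = sc.coords[j + 2 * sc.ncolS];
          sc.index[sc.vox(ci, cj, ck)] = 0;
          ++dissolved;
        }
      }
    }
  }

  return List::create(_["annexed"] = annexed, _["dissolved"] = dissolved,
                      _["slots_used"] = next_slot,
                      _["out_of_slots"] = out_of_slots);
}

// Effective occupancy of each requested column: the maximum of its own
// total and its active 6-neighbours' totals.  Feeds the local-crowding
// proxy: a voxel adjacent to densely packed tissue shares its (saturated)
// nutrient supply, so only voxels inside a depleted neighbourhood see
// relaxed dormancy pressure.
// [[Rcpp::export]]
NumericVector neighbour_max_occ_cpp(IntegerVector index, IntegerMatrix coords,
                                    LogicalVector active, IntegerVector cols,
                                    NumericVector tot, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ncol = coords.nrow();
  const int* ix = INTEGER(index);
  const int* co = INTEGER(coords);
  const int* ac = LOGICAL(active);
  NumericVector out(cols.size());
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  for (int ii = 0; ii < cols.size(); ++ii) {
    int j = cols[ii] - 1;
    double m = tot[j];
    int ci = co[j], cj = co[j + ncol], ck = co[j + 2 * ncol];
    for (int q = 0; q < 6; ++q) {
      int i2 = ci + di[q], j2 = cj + dj[q], k2 = ck + dk[q];
      if (i2 < 1 || i2 > nx || j2 < 1 || j2 > ny || k2 < 1 || k2 > nz)
        continue;
      int col = ix[(i2 - 1) + nx * ((j2 - 1) + ny * (k2 - 1))];
      if (col > 0 && ac[col - 1] && tot[col - 1] > m) m = tot[col - 1];
    }
    out[ii] = m;
  }
  return out;
}
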