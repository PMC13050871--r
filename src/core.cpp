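// Low-level 3D image primitives: anisotropic Euclidean distance transform,
// 26-connected component labelling, seeded watershed (priority flood),
// local maxima, and pruned surface-to-surface distances.
//
// All arrays are passed as flat vectors with dims (ny, nx, nz) in R's
// column-major order; voxel spacing is physical (micrometres) per dimension
// in the same (y, x, z) order. 2D images are handled as nz == 1.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <unordered_set>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline R_xlen_t idx3(int i, int j, int k, int ny, int nx) {
  return (R_xlen_t)i + (R_xlen_t)ny * ((R_xlen_t)j + (R_xlen_t)nx * (R_xlen_t)k);
}

// ---------------------------------------------------------------------------
// 1D squared distance transform of a sampled function (Felzenszwalb &
// Huttenlocher lower-envelope algorithm), grid spacing w. Sites with
// f == +Inf are treated as absent.
static void dt1d(const std::vector<double>& f, double w,
                 std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    if (f[q] == R_PosInf) continue; // never part of the lower envelope
    double s = 0.0;
    bool replaced = false;
    while (true) {
      int p = v[k];
      if (f[p] == R_PosInf) {
        s = -INFINITY;
      } else {
        s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
            (2.0 * w2 * (q - p));
      }
      if (s <= z[k]) {
        --k;
        if (k < 0) { // q dominates everything so far
          k = 0;
          v[0] = q;
          z[0] = -INFINITY;
          z[1] = INFINITY;
          replaced = true;
          break;
        }
      } else {
        break;
      }
    }
    if (!replaced) {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INFINITY;
    }
  }
  d.resize(n);
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    double fp = f[v[k]];
    d[q] = (fp == R_PosInf) ? R_PosInf : w2 * dq * dq + fp;
  }
}

// Squared anisotropic EDT: squared distance from each foreground voxel to the
// nearest background voxel centre, in physical units. Background voxels get 0.
// [[Rcpp::export(name = ".edt_sq_3d")]]
NumericVector edt_sq_3d(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const double wy = spacing[0], wx = spacing[1], wz = spacing[2];
  NumericVector out(mask.size());
  for (R_xlen_t t = 0; t < mask.size(); ++t)
    out[t] = mask[t] ? R_PosInf : 0.0;

  std::vector<double> f, d;
  f.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < nx; ++j) {
      for (int i = 0; i < ny; ++i) f[i] = out[idx3(i, j, k, ny, nx)];
      dt1d(f, wy, d);
      for (int i = 0; i < ny; ++i) out[idx3(i, j, k, ny, nx)] = d[i];
    }
  f.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < ny; ++i) {
      for (int j = 0; j < nx; ++j) f[j] = out[idx3(i, j, k, ny, nx)];
      dt1d(f, wx, d);
      for (int j = 0; j < nx; ++j) out[idx3(i, j, k, ny, nx)] = d[j];
    }
  if (nz > 1) {
    f.resize(nz);
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i < ny; ++i) {
        for (int k = 0; k < nz; ++k) f[k] = out[idx3(i, j, k, ny, nx)];
        dt1d(f, wz, d);
        for (int k = 0; k < nz; ++k) out[idx3(i, j, k, ny, nx)] = d[k];
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected component labelling (8-connected when nz == 1).
// [[Rcpp::export(name = ".label_3d")]]
IntegerVector label_3d(LogicalVector mask, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < mask.size(); ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++next;
    lab[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % ny);
      int rem = (int)(cur / ny);
      int j = rem % nx;
      int k = rem / nx;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= ny || jj < 0 || jj >= nx || kk < 0 || kk >= nz)
              continue;
            R_xlen_t nb = idx3(ii, jj, kk, ny, nx);
            if (mask[nb] && lab[nb] == 0) {
              lab[nb] = next;
              stack.push_back(nb);
            }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Seeded watershed by priority flooding: grow seed labels over the mask in
// increasing order of `height` (pass the negated distance transform to flood
// from distance maxima outward). Ties broken by insertion order, so the
// result is deterministic. Every mask voxel reachable from a seed is
// labelled; the label set partitions the mask when every component is seeded.
struct PQItem {
  double h;
  uint64_t order;
  R_xlen_t idx;
};
struct PQCmp {
  bool operator()(const PQItem& a, const PQItem& b) const {
    if (a.h != b.h) return a.h > b.h;
    return a.order > b.order;
  }
};

// [[Rcpp::export(name = ".watershed_3d")]]
IntegerVector watershed_3d(NumericVector height, IntegerVector seeds,
                           LogicalVector mask, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  IntegerVector lab(mask.size(), 0);
  std::priority_queue<PQItem, std::vector<PQItem>, PQCmp> pq;
  uint64_t order = 0;
  for (R_xlen_t t = 0; t < seeds.size(); ++t) {
    if (seeds[t] > 0 && mask[t]) {
      lab[t] = seeds[t];
      pq.push({height[t], order++, t});
    }
  }
  while (!pq.empty()) {
    PQItem it = pq.top();
    pq.pop();
    R_xlen_t cur = it.idx;
    int lcur = lab[cur];
    int i = (int)(cur % ny);
    int rem = (int)(cur / ny);
    int j = rem % nx;
    int k = rem / nx;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= ny || jj < 0 || jj >= nx || kk < 0 || kk >= nz)
            continue;
          R_xlen_t nb = idx3(ii, jj, kk, ny, nx);
          if (mask[nb] && lab[nb] == 0) {
            lab[nb] = lcur;
            pq.push({height[nb], order++, nb});
          }
        }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Local maxima of `height` restricted to mask: voxel value >= all in-bounds
// 26-neighbours. Plateaus yield multiple candidates; the caller suppresses.
// [[Rcpp::export(name = ".local_max_3d")]]
LogicalVector local_max_3d(NumericVector height, LogicalVector mask,
                           IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  LogicalVector out(mask.size(), FALSE);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i < ny; ++i) {
        R_xlen_t cur = idx3(i, j, k, ny, nx);
        if (!mask[cur]) continue;
        double h = height[cur];
        bool ismax = true;
        for (int dk = -1; dk <= 1 && ismax; ++dk)
          for (int dj = -1; dj <= 1 && ismax; ++dj)
            for (int di = -1; di <= 1 && ismax; ++di) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= ny || jj < 0 || jj >= nx || kk < 0 ||
                  kk >= nz)
                continue;
              if (height[idx3(ii, jj, kk, ny, nx)] > h) ismax = false;
            }
        out[cur] = ismax;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Minimum distance between two voxelized objects, given integer voxel
// coordinates (n x 3 matrices, (i,j,k)) and physical spacing. Returns 0 when
// the sets share a voxel or are 26-adjacent (checked exactly via a hash of
// object A). Otherwise the minimum centre-to-centre distance, accelerated by
// sorting object B along the first axis and pruning voxels whose single-axis
// separation already exceeds the best distance found.
// [[Rcpp::export(name = ".min_voxel_dist")]]
double min_voxel_dist(IntegerMatrix a, IntegerMatrix b, NumericVector spacing) {
  const double wy = spacing[0], wx = spacing[1], wz = spacing[2];
  const int na = a.nrow(), nb = b.nrow();

  // exact overlap / 26-adjacency test
  std::unordered_set<int64_t> seta;
  seta.reserve(na * 2);
  auto key = [](int64_t i, int64_t j, int64_t k) {
    return (i + 2) + 1048576LL * ((j + 2) + 1048576LL * (k + 2));
  };
  for (int p = 0; p < na; ++p) seta.insert(key(a(p, 0), a(p, 1), a(p, 2)));
  for (int q = 0; q < nb; ++q)
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di)
          if (seta.count(key(b(q, 0) + di, b(q, 1) + dj, b(q, 2) + dk)))
            return 0.0;

  std::vector<int> ord(nb);
  for (int t = 0; t < nb; ++t) ord[t] = t;
  std::sort(ord.begin(), ord.end(),
            [&](int u, int v) { return b(u, 0) < b(v, 0); });
  std::vector<int> by(nb), bx(nb), bz(nb);
  for (int t = 0; t < nb; ++t) {
    by[t] = b(ord[t], 0);
    bx[t] = b(ord[t], 1);
    bz[t] = b(ord[t], 2);
  }
  double best = R_PosInf;
  for (int p = 0; p < na; ++p) {
    int ai = a(p, 0), aj = a(p, 1), ak = a(p, 2);
    int lo = (int)(std::lower_bound(by.begin(), by.end(), ai) - by.begin());
    for (int dir = 0; dir < 2; ++dir) {
      int t = dir == 0 ? lo : lo - 1;
      int step = dir == 0 ? 1 : -1;
      while (t >= 0 && t < nb) {
        double dy = wy * (double)(by[t] - ai);
        if (dy * dy >= best) break; // sorted: no closer band this direction
        double ddx = wx * (double)(bx[t] - aj);
        double ddz = wz * (double)(bz[t] - ak);
        double d2 = dy * dy + ddx * ddx + ddz * ddz;
        if (d2 < best) best = d2;
        t += step;
      }
    }
  }
  return std::sqrt(best);
}

// ---------------------------------------------------------------------------
// Saddle heights between adjacent watershed basins: for every 26-adjacent
// pair of differently-labelled voxels, the saddle of the label pair is the
// maximum over such pairs of min(height[a], height[b]).
// Returns a matrix with columns (label_a, label_b, saddle), label_a < label_b.
#include <map>
// [[Rcpp::export(name = ".label_saddles")]]
NumericMatrix label_saddles(IntegerVector lab, NumericVector height,
                            IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  std::map<std::pair<int, int>, double> sad;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i < ny; ++i) {
        R_xlen_t cur = idx3(i, j, k, ny, nx);
        int lc = lab[cur];
        if (lc <= 0) continue;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= ny || jj < 0 || jj >= nx || kk < 0 ||
                  kk >= nz)
                continue;
              R_xlen_t nb = idx3(ii, jj, kk, ny, nx);
              int ln = lab[nb];
              if (ln <= 0 || ln == lc) continue;
              std::pair<int, int> key(std::min(lc, ln), std::max(lc, ln));
              double s = std::min(height[cur], height[nb]);
              auto it = sad.find(key);
              if (it == sad.end() || s > it->second) sad[key] = s;
            }
      }
  NumericMatrix out(sad.size(), 3);
  int r = 0;
  for (auto& kv : sad) {
    out(r, 0) = kv.first.first;
    out(r, 1) = kv.first.second;
    out(r, 2) = kv.second;
    ++r;
  }
  return out;
}
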