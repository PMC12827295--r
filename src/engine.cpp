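// N-dimensional sliding-window engine: box counts and lacunarity via
// integral-image window sums, plus a subsampled estimator for 4D windows.
//
// Conventions shared by every entry point:
//  * arrays are column-major (R layout), dims has length d (2 <= d <= 4 used);
//  * stride_mode: stride == s tiles the array from the low corner with partial
//    edge windows clipped; stride == 1 glides; axes shorter than s collapse to
//    a single clipped window in either mode;
//  * windows are enumerated in column-major order of the window grid; ranges
//    [lo, hi) over that enumeration let callers chunk work across workers
//    without changing any result.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const int MAXD = 8;

struct WinGrid {
  int d;
  int dims[MAXD];     // array extents
  int s;              // window edge
  int stride;
  int nw[MAXD];       // windows per axis
  double nwin;        // total windows
};

static WinGrid make_grid(const IntegerVector& dims, int s, int stride) {
  WinGrid g;
  g.d = dims.size();
  if (g.d > MAXD) stop("too many dimensions");
  g.s = s; g.stride = stride; g.nwin = 1.0;
  for (int i = 0; i < g.d; ++i) {
    int e = dims[i];
    if (e < 1) stop("degenerate array extent");
    int n;
    if (stride == s) {                    // grid tiling, partial edges kept
      n = (e + s - 1) / s;
    } else {                              // gliding
      n = (e >= s) ? (e - s + 1) : 1;     // short axis -> one clipped window
    }
    g.dims[i] = e; g.nw[i] = n; g.nwin *= n;
  }
  return g;
}

// integral image: S has extents dims+1, S(i) = sum of A over [0, i)
// [[Rcpp::export]]
NumericVector cpp_integral(NumericVector a, IntegerVector dims) {
  int d = dims.size();
  std::vector<int> sd(d);
  R_xlen_t total = 1;
  for (int i = 0; i < d; ++i) { sd[i] = dims[i] + 1; total *= sd[i]; }
  NumericVector S(total);
  // copy A into the +1-offset block
  std::vector<int> idx(d, 0);
  R_xlen_t na = a.size();
  for (R_xlen_t k = 0; k < na; ++k) {
    R_xlen_t off = 0, mult = 1;
    for (int i = 0; i < d; ++i) { off += (R_xlen_t)(idx[i] + 1) * mult; mult *= sd[i]; }
    S[off] = a[k];
    for (int i = 0; i < d; ++i) { if (++idx[i] < dims[i]) break; idx[i] = 0; }
  }
  // cumulative sums along each axis
  for (int ax = 0; ax < d; ++ax) {
    R_xlen_t stride = 1;
    for (int i = 0; i < ax; ++i) stride *= sd[i];
    R_xlen_t len = sd[ax];
    R_xlen_t lines = total / len;
    for (R_xlen_t o = 0; o < lines; ++o) {
      R_xlen_t base = (o / stride) * stride * len + (o % stride);
      for (R_xlen_t j = 1; j < len; ++j)
        S[base + j * stride] += S[base + (j - 1) * stride];
    }
  }
  return S;
}

// sum of A over window [lo, hi) from integral image S (extents dims+1)
static inline double win_sum(const double* S, const int* sd, int d,
                             const int* lo, const int* hi) {
  double tot = 0.0;
  int corners = 1 << d;
  for (int c = 0; c < corners; ++c) {
    R_xlen_t off = 0, mult = 1;
    int sign = 1;
    for (int i = 0; i < d; ++i) {
      int v;
      if (c & (1 << i)) { v = hi[i]; } else { v = lo[i]; sign = -sign; }
      off += (R_xlen_t)v * mult; mult *= sd[i];
    }
    tot += sign * S[off];
  }
  return tot;
}

static inline void win_bounds(const WinGrid& g, int64_t w, int* lo, int* hi,
                              double* ncells) {
  int64_t rem = w; double nc = 1.0;
  for (int i = 0; i < g.d; ++i) {
    int wi = (int)(rem % g.nw[i]);
    rem /= g.nw[i];
    int a = wi * g.stride;
    int b = a + g.s;
    if (b > g.dims[i]) b = g.dims[i];
    lo[i] = a; hi[i] = b; nc *= (b - a);
  }
  *ncells = nc;
}

// [[Rcpp::export]]
double cpp_n_windows(IntegerVector dims, int s, int stride) {
  return make_grid(dims, s, stride).nwin;
}

// Box count: number of windows in [lo, hi) holding any mass.
// [[Rcpp::export]]
double cpp_box_count(NumericVector S, IntegerVector dims, int s, int stride,
                     double lo_w, double hi_w) {
  WinGrid g = make_grid(dims, s, stride);
  int sd[MAXD]; for (int i = 0; i < g.d; ++i) sd[i] = g.dims[i] + 1;
  int lo[MAXD], hi[MAXD]; double nc;
  double count = 0.0;
  for (int64_t w = (int64_t)lo_w; w < (int64_t)hi_w; ++w) {
    win_bounds(g, w, lo, hi, &nc);
    if (win_sum(REAL(S), sd, g.d, lo, hi) > 0.0) count += 1.0;
  }
  return count;
}

// Literal lacunarity partials: per window with mean > 0, CV^2 of voxel values.
// Returns (n_nonempty, sum of CV^2).
// [[Rcpp::export]]
NumericVector cpp_lacunarity_cv2(NumericVector S, NumericVector S2,
                                 IntegerVector dims, int s, int stride,
                                 double lo_w, double hi_w) {
  WinGrid g = make_grid(dims, s, stride);
  int sd[MAXD]; for (int i = 0; i < g.d; ++i) sd[i] = g.dims[i] + 1;
  int lo[MAXD], hi[MAXD]; double nc;
  double n_ne = 0.0, acc = 0.0;
  for (int64_t w = (int64_t)lo_w; w < (int64_t)hi_w; ++w) {
    win_bounds(g, w, lo, hi, &nc);
    double sum = win_sum(REAL(S), sd, g.d, lo, hi);
    if (sum <= 0.0) continue;
    double mu = sum / nc;
    double m2 = win_sum(REAL(S2), sd, g.d, lo, hi) / nc;
    double var = m2 - mu * mu;
    if (var < 0.0) var = 0.0;             // numeric guard
    n_ne += 1.0;
    acc += var / (mu * mu);
  }
  NumericVector out(2); out[0] = n_ne; out[1] = acc;
  return out;
}

// Gliding-box mass statistics: first/second moments of window masses over all
// window positions. Returns (n_windows, sum mass, sum mass^2).
// [[Rcpp::export]]
NumericVector cpp_mass_moments(NumericVector S, IntegerVector dims, int s,
                               int stride, double lo_w, double hi_w) {
  WinGrid g = make_grid(dims, s, stride);
  int sd[MAXD]; for (int i = 0; i < g.d; ++i) sd[i] = g.dims[i] + 1;
  int lo[MAXD], hi[MAXD]; double nc;
  double n = 0.0, s1 = 0.0, s2 = 0.0;
  for (int64_t w = (int64_t)lo_w; w < (int64_t)hi_w; ++w) {
    win_bounds(g, w, lo, hi, &nc);
    double m = win_sum(REAL(S), sd, g.d, lo, hi);
    n += 1.0; s1 += m; s2 += m * m;
  }
  NumericVector out(3); out[0] = n; out[1] = s1; out[2] = s2;
  return out;
}

// ---- counter-based RNG for subsampling ------------------------------------
// splitmix64: stateless mix of a 64-bit counter; streams are keyed by
// (seed, window index) so results do not depend on chunking/worker count.
static inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct KeyedRng {
  uint64_t state;
  KeyedRng(uint64_t seed, uint64_t key)
    : state(mix64(seed * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL * (key + 1))) {}
  inline uint64_t next() {
    state += 0x9E3779B97F4A7C15ULL;
    return mix64(state);
  }
  // uniform integer in [0, m), Lemire's method
  inline uint32_t bounded(uint32_t m) {
    uint64_t x = next() >> 32;
    return (uint32_t)((x * (uint64_t)m) >> 32);
  }
};

// Subsampled lacunarity on a binary occupancy array. Per window of n cells,
// k = min(n, max(min_cells, floor(rate * n))) cells are drawn uniformly
// without replacement (partial Fisher-Yates on a reusable index buffer);
// occupancy mean/variance are estimated from the sample (population variance
// of binary indicators = mu(1-mu)); windows whose sample holds no occupied
// cell are dropped. Returns (n_kept, sum CV^2).
// [[Rcpp::export]]
NumericVector cpp_lacunarity_sub(IntegerVector occ, IntegerVector dims, int s,
                                 int stride, double lo_w, double hi_w,
                                 double rate, int min_cells, double seed) {
  WinGrid g = make_grid(dims, s, stride);
  if (rate <= 0.0 || rate > 1.0) stop("rate must be in (0, 1]");
  uint64_t seed64 = (uint64_t)(int64_t)seed;

  // full-size window: relative linear offsets of its cells
  R_xlen_t arr_stride[MAXD];
  arr_stride[0] = 1;
  for (int i = 1; i < g.d; ++i) arr_stride[i] = arr_stride[i - 1] * g.dims[i - 1];
  std::vector<R_xlen_t> rel_full;
  {
    int full = 1; for (int i = 0; i < g.d; ++i) full *= std::min(g.s, g.dims[i]);
    rel_full.reserve(full);
  }
  auto build_rel = [&](const int* lo, const int* hi, std::vector<R_xlen_t>& rel) {
    rel.clear();
    int idx[MAXD], ext[MAXD];
    for (int i = 0; i < g.d; ++i) { idx[i] = 0; ext[i] = hi[i] - lo[i]; }
    for (;;) {
      R_xlen_t off = 0;
      for (int i = 0; i < g.d; ++i) off += (R_xlen_t)idx[i] * arr_stride[i];
      rel.push_back(off);
      int i = 0;
      for (; i < g.d; ++i) { if (++idx[i] < ext[i]) break; idx[i] = 0; }
      if (i == g.d) break;
    }
  };

  int lo[MAXD], hi[MAXD]; double ncells;
  // reference (unclipped-shape) window to detect when rel can be reused
  double full_cells = 1.0;
  for (int i = 0; i < g.d; ++i) full_cells *= std::min(g.s, g.dims[i]);
  std::vector<uint32_t> fy;            // Fisher-Yates buffer, identity at rest
  bool have_full = false;
  std::vector<R_xlen_t> rel_clip;      // scratch for clipped windows
  std::vector<uint32_t> rs;            // scratch for swap undo

  const int* op = INTEGER(occ);
  double n_kept = 0.0, acc = 0.0;

  for (int64_t w = (int64_t)lo_w; w < (int64_t)hi_w; ++w) {
    win_bounds(g, w, lo, hi, &ncells);
    const std::vector<R_xlen_t>* relp;
    if (ncells == full_cells) {
      if (!have_full) {
        build_rel(lo, hi, rel_full);
        fy.resize(rel_full.size());
        for (size_t j = 0; j < fy.size(); ++j) fy[j] = (uint32_t)j;
        have_full = true;
      }
      relp = &rel_full;
    } else {
      build_rel(lo, hi, rel_clip);
      relp = &rel_clip;
    }
    uint32_t n = (uint32_t)relp->size();
    uint32_t k = (uint32_t)std::floor(rate * (double)n);
    if (k < (uint32_t)min_cells) k = (uint32_t)min_cells;
    if (k > n) k = n;

    R_xlen_t base = 0;
    for (int i = 0; i < g.d; ++i) base += (R_xlen_t)lo[i] * arr_stride[i];

    uint32_t occ_n = 0;
    if (k == n) {                        // full enumeration
      for (uint32_t j = 0; j < n; ++j)
        if (op[base + (*relp)[j]]) ++occ_n;
    } else if (relp == &rel_full) {      // partial Fisher-Yates, then undo
      KeyedRng rng(seed64, (uint64_t)w);
      rs.resize(k);
      for (uint32_t j = 0; j < k; ++j) {
        uint32_t r = j + rng.bounded(n - j);
        rs[j] = r;
        uint32_t tmp = fy[j]; fy[j] = fy[r]; fy[r] = tmp;
        if (op[base + (*relp)[fy[j]]]) ++occ_n;
      }
      for (uint32_t j = k; j-- > 0;) {   // undo swaps -> identity again, O(k)
        uint32_t r = rs[j];
        uint32_t tmp = fy[j]; fy[j] = fy[r]; fy[r] = tmp;
      }
    } else {                             // clipped edge window
      KeyedRng rng(seed64, (uint64_t)w);
      std::vector<uint32_t> tmp(n);
      for (uint32_t j = 0; j < n; ++j) tmp[j] = j;
      for (uint32_t j = 0; j < k; ++j) {
        uint32_t r = j + rng.bounded(n - j);
        uint32_t t = tmp[j]; tmp[j] = tmp[r]; tmp[r] = t;
        if (op[base + (*relp)[tmp[j]]]) ++occ_n;
      }
    }
    if (occ_n == 0) continue;            // sampled-empty window dropped
    double mu = (double)occ_n / (double)k;
    n_kept += 1.0;
    acc += (1.0 - mu) / mu;              // CV^2 of binary sample, pop. variance
  }
  NumericVector out(2); out[0] = n_kept; out[1] = acc;
  return out;
}
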