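// Low-level raster primitives for the leaky-dye segmentation pipeline.
// All matrices are R column-major; (r, c) indexing is 0-based here.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 0, 0, 1};
static const int DC4[4] = {0, -1, 1, 0};

// Separable Gaussian convolution with edge-replication boundary.
// Kernel is truncated at ceil(3.5*sigma) and renormalised to sum 1, so a
// constant image is preserved exactly and the operator is exactly linear.
// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(const NumericMatrix& img, double sigmaPx) {
  const int nr = img.nrow(), nc = img.ncol();
  const int R = std::max(1, (int)std::ceil(3.5 * sigmaPx));
  std::vector<double> k(2 * R + 1);
  const double s2 = 2.0 * sigmaPx * sigmaPx;
  double sum = 0.0;
  for (int i = -R; i <= R; ++i) {
    k[i + R] = std::exp(-(double)(i * i) / s2);
    sum += k[i + R];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= sum;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c) {        // along-column (row direction) pass
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -R; i <= R; ++i) {
        int rr = r + i;
        if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
        acc += k[i + R] * img(rr, c);
      }
      tmp(r, c) = acc;
    }
  }
  for (int c = 0; c < nc; ++c) {        // along-row (column direction) pass
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -R; i <= R; ++i) {
        int cc = c + i;
        if (cc < 0) cc = 0; else if (cc >= nc) cc = nc - 1;
        acc += k[i + R] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// Grayscale erosion/dilation with a structuring function given as offset
// lists (dr, dc) and heights h. Out-of-image offsets are ignored, which for
// the erosion/dilation pair amounts to replicate-style boundary handling.
// [[Rcpp::export]]
NumericMatrix gray_morph_cpp(const NumericMatrix& img, const IntegerVector& dr,
                             const IntegerVector& dc, const NumericVector& h,
                             bool erode) {
  const int nr = img.nrow(), nc = img.ncol(), m = dr.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double best = erode ? R_PosInf : R_NegInf;
      for (int i = 0; i < m; ++i) {
        const int rr = r + dr[i], cc = c + dc[i];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const double v = erode ? img(rr, cc) - h[i] : img(rr, cc) + h[i];
        if (erode ? (v < best) : (v > best)) best = v;
      }
      out(r, c) = best;
    }
  }
  return out;
}

// Block-mean downsampling by integer factor s (partial border blocks kept).
// [[Rcpp::export]]
NumericMatrix block_mean_cpp(const NumericMatrix& img, int s) {
  const int nr = img.nrow(), nc = img.ncol();
  const int mr = (nr + s - 1) / s, mc = (nc + s - 1) / s;
  NumericMatrix out(mr, mc);
  for (int bc = 0; bc < mc; ++bc) {
    for (int br = 0; br < mr; ++br) {
      double acc = 0.0;
      int cnt = 0;
      const int r1 = br * s, r2 = std::min(nr, r1 + s);
      const int c1 = bc * s, c2 = std::min(nc, c1 + s);
      for (int c = c1; c < c2; ++c)
        for (int r = r1; r < r2; ++r) { acc += img(r, c); ++cnt; }
      out(br, bc) = acc / cnt;
    }
  }
  return out;
}

// Block-minimum downsampling by integer factor s (partial border blocks kept).
// [[Rcpp::export]]
NumericMatrix block_min_cpp(const NumericMatrix& img, int s) {
  const int nr = img.nrow(), nc = img.ncol();
  const int mr = (nr + s - 1) / s, mc = (nc + s - 1) / s;
  NumericMatrix out(mr, mc);
  for (int bc = 0; bc < mc; ++bc) {
    for (int br = 0; br < mr; ++br) {
      double mn = R_PosInf;
      const int r1 = br * s, r2 = std::min(nr, r1 + s);
      const int c1 = bc * s, c2 = std::min(nc, c1 + s);
      for (int c = c1; c < c2; ++c)
        for (int r = r1; r < r2; ++r)
          if (img(r, c) < mn) mn = img(r, c);
      out(br, bc) = mn;
    }
  }
  return out;
}

// Bilinear upsampling of a block-reduced image back to (nr, nc); block
// centres are mapped to full-resolution pixel centres.
// [[Rcpp::export]]
NumericMatrix bilinear_upscale_cpp(const NumericMatrix& small, int nr, int nc,
                                   int s) {
  const int mr = small.nrow(), mc = small.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    double u = (c + 0.5 - 0.5 * s) / s;           // fractional small-grid col
    if (u < 0) u = 0; if (u > mc - 1) u = mc - 1;
    const int c0 = (int)std::floor(u);
    const int c1 = std::min(mc - 1, c0 + 1);
    const double wc = u - c0;
    for (int r = 0; r < nr; ++r) {
      double v = (r + 0.5 - 0.5 * s) / s;
      if (v < 0) v = 0; if (v > mr - 1) v = mr - 1;
      const int r0 = (int)std::floor(v);
      const int r1 = std::min(mr - 1, r0 + 1);
      const double wr = v - r0;
      out(r, c) = (1 - wr) * ((1 - wc) * small(r0, c0) + wc * small(r0, c1)) +
                  wr * ((1 - wc) * small(r1, c0) + wc * small(r1, c1));
    }
  }
  return out;
}

// Connected-component labelling of a binary mask. Labels are assigned in
// raster-scan order (row by row) of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int nnb = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  int next = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pr = p % nr, pc = p / nr;
        for (int i = 0; i < nnb; ++i) {
          const int rr = pr + ((nnb == 8) ? DR8[i] : DR4[i]);
          const int cc = pc + ((nnb == 8) ? DC8[i] : DC4[i]);
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Find-Maxima-style seed detection. A candidate is a pixel with no strictly
// higher 8-neighbour. Candidates are visited in decreasing intensity (ties
// by raster position). From each unclaimed candidate at height v, a flood
// covers the 8-connected region with values in (v - tol, v]. The candidate
// is rejected (merged into a higher peak) if the flood touches an already
// claimed pixel or any flooded pixel has a neighbour above v; otherwise it
// is accepted as a seed. Either way the flooded region is claimed, so equal
// plateaus collapse to a single seed. Accepted seeds get labels 1..K in
// acceptance order. This reproduces ImageJ Find Maxima "noise tolerance"
// semantics: accepted maxima have topographic prominence >= tol.
// [[Rcpp::export]]
IntegerMatrix find_seeds_cpp(const NumericMatrix& img, double tol) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  IntegerMatrix seeds(nr, nc);
  std::vector<int> cand;
  cand.reserve(1024);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double v = img(r, c);
      bool isMax = true;
      for (int i = 0; i < 8 && isMax; ++i) {
        const int rr = r + DR8[i], cc = c + DC8[i];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (img(rr, cc) > v) isMax = false;
      }
      if (isMax) cand.push_back(r + c * nr);
    }
  }
  std::stable_sort(cand.begin(), cand.end(), [&](int a, int b) {
    const double va = img[a], vb = img[b];
    if (va != vb) return va > vb;
    return a < b;
  });

  std::vector<char> claimed(n, 0);
  std::vector<int> stamp(n, -1);
  std::vector<int> stack, flooded;
  int seedId = 0;
  for (size_t ci = 0; ci < cand.size(); ++ci) {
    const int p0 = cand[ci];
    if (claimed[p0]) continue;
    const double v = img[p0];
    const double lo = v - tol;
    bool reject = false;
    stack.clear(); flooded.clear();
    stack.push_back(p0);
    stamp[p0] = (int)ci;
    while (!stack.empty()) {
      const int p = stack.back(); stack.pop_back();
      flooded.push_back(p);
      if (claimed[p]) { reject = true; break; }
      const int pr = p % nr, pc = p / nr;
      for (int i = 0; i < 8; ++i) {
        const int rr = pr + DR8[i], cc = pc + DC8[i];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const double w = img(rr, cc);
        if (w > v) { reject = true; break; }
        const int q = rr + cc * nr;
        if (w > lo && stamp[q] != (int)ci) {
          stamp[q] = (int)ci;
          stack.push_back(q);
        }
      }
      if (reject) break;
    }
    for (size_t i = 0; i < flooded.size(); ++i) claimed[flooded[i]] = 1;
    // claim anything still on the stack too (partial flood on early reject)
    for (size_t i = 0; i < stack.size(); ++i) claimed[stack[i]] = 1;
    if (!reject) {
      ++seedId;
      seeds[p0] = seedId;
    }
  }
  return seeds;
}

// Meyer seeded watershed with watershed lines, 8-connected flooding.
// `surface` is flooded in ascending order (pass the negated image to grow
// basins downhill from intensity maxima). Ties are resolved FIFO, which
// places lines midway across flat valleys. A popped pixel adjacent to two
// different basins becomes a line pixel (0); hence no two pixels of
// different basins are ever 8-adjacent and basins stay 8-disconnected.
// [[Rcpp::export]]
IntegerMatrix watershed_cpp(const NumericMatrix& surface,
                            const IntegerMatrix& seeds) {
  const int nr = surface.nrow(), nc = surface.ncol(), n = nr * nc;
  IntegerMatrix lab = clone(seeds);   // >0 basin, -1 line, 0 unassigned
  struct QE { double v; long long t; int p; };
  struct Cmp {
    bool operator()(const QE& a, const QE& b) const {
      if (a.v != b.v) return a.v > b.v;
      return a.t > b.t;
    }
  };
  std::priority_queue<QE, std::vector<QE>, Cmp> pq;
  std::vector<char> queued(n, 0);
  long long tick = 0;
  for (int p = 0; p < n; ++p) {
    if (lab[p] <= 0) continue;
    const int pr = p % nr, pc = p / nr;
    for (int i = 0; i < 8; ++i) {
      const int rr = pr + DR8[i], cc = pc + DC8[i];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int q = rr + cc * nr;
      if (lab[q] == 0 && !queued[q]) {
        queued[q] = 1;
        pq.push(QE{surface[q], tick++, q});
      }
    }
  }
  while (!pq.empty()) {
    const QE e = pq.top(); pq.pop();
    const int p = e.p;
    if (lab[p] != 0) continue;
    const int pr = p % nr, pc = p / nr;
    int l1 = 0; bool multi = false;
    for (int i = 0; i < 8; ++i) {
      const int rr = pr + DR8[i], cc = pc + DC8[i];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int lq = lab(rr, cc);
      if (lq > 0) {
        if (l1 == 0) l1 = lq;
        else if (lq != l1) { multi = true; break; }
      }
    }
    if (multi || l1 == 0) {
      lab[p] = -1;                     // line (or line-enclosed pocket pixel)
    } else {
      lab[p] = l1;
    }
    for (int i = 0; i < 8; ++i) {
      const int rr = pr + DR8[i], cc = pc + DC8[i];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int q = rr + cc * nr;
      if (lab[q] == 0 && !queued[q]) {
        queued[q] = 1;
        pq.push(QE{surface[q], tick++, q});
      }
    }
  }
  for (int p = 0; p < n; ++p) if (lab[p] < 0) lab[p] = 0;
  return lab;
}
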