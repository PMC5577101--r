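#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <climits>
using namespace Rcpp;

// Pixel-level kernels for the ECM branching pipeline. All matrices are R
// column-major; a pixel (i, j) (0-based row, col) has linear index i + j*nr.
// Connectivity convention: 8-connectivity for foreground, 4-connectivity for
// background (the standard (8,4) digital-topology pair). Pixels outside the
// image count as background for local topology tests.

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// reflect an out-of-range coordinate back into [0, n) (half-sample symmetric:
// -1 -> 0, -2 -> 1, n -> n-1, ...)
static inline int reflect_idx(int t, int n) {
  while (t < 0 || t >= n) {
    if (t < 0) t = -t - 1;
    if (t >= n) t = 2 * n - 1 - t;
  }
  return t;
}

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_local_mean(NumericMatrix img, int window) {
  if (window < 3 || window % 2 == 0)
    stop("window must be an odd integer >= 3");
  const int nr = img.nrow(), nc = img.ncol();
  const int half = window / 2;
  const double sigma = window / 6.0;
  std::vector<double> w(window);
  double s = 0.0;
  for (int k = 0; k < window; ++k) {
    double x = (k - half) / sigma;
    w[k] = std::exp(-0.5 * x * x);
    s += w[k];
  }
  for (int k = 0; k < window; ++k) w[k] /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // vertical pass (along rows within a column), reflected border
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -half; k <= half; ++k)
        acc += w[k + half] * img(reflect_idx(i + k, nr), j);
      tmp(i, j) = acc;
    }
  // horizontal pass
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -half; k <= half; ++k)
        acc += w[k + half] * tmp(i, reflect_idx(j + k, nc));
      out(i, j) = acc;
    }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const int nnb = connectivity;
  static const int DR4[4] = {-1, 0, 0, 1};
  static const int DC4[4] = {0, -1, 1, 0};
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int ni = ci + (connectivity == 8 ? DR8[k] : DR4[k]);
          int nj = cj + (connectivity == 8 ? DC8[k] : DC4[k]);
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  return lab;
}

// Neighbourhood topology numbers for the (8,4) simple-point test.
// fg[] holds the 3x3 neighbourhood (row-major, centre at 4); out-of-image
// cells are background.
static void fill_nbhd(const LogicalMatrix& m, int i, int j, bool fg[9]) {
  const int nr = m.nrow(), nc = m.ncol();
  int p = 0;
  for (int dr = -1; dr <= 1; ++dr)
    for (int dc = -1; dc <= 1; ++dc, ++p) {
      int ni = i + dr, nj = j + dc;
      fg[p] = (ni >= 0 && ni < nr && nj >= 0 && nj < nc) ? (bool)m(ni, nj)
                                                         : false;
    }
}

static int count_fg_neighbours(const bool fg[9]) {
  int n = 0;
  for (int p = 0; p < 9; ++p)
    if (p != 4 && fg[p]) ++n;
  return n;
}

// number of 8-connected components of foreground ring cells
static int t8_components(const bool fg[9]) {
  // ring cell grid offsets: p -> (dr, dc) with dr = p/3 - 1, dc = p%3 - 1
  bool seen[9] = {false};
  int comps = 0;
  for (int p = 0; p < 9; ++p) {
    if (p == 4 || !fg[p] || seen[p]) continue;
    ++comps;
    std::vector<int> st{p};
    seen[p] = true;
    while (!st.empty()) {
      int q = st.back(); st.pop_back();
      int qr = q / 3 - 1, qc = q % 3 - 1;
      for (int r = 0; r < 9; ++r) {
        if (r == 4 || seen[r] || !fg[r]) continue;
        int rr = r / 3 - 1, rc = r % 3 - 1;
        if (std::abs(qr - rr) <= 1 && std::abs(qc - rc) <= 1) {
          seen[r] = true;
          st.push_back(r);
        }
      }
    }
  }
  return comps;
}

// number of 4-connected background components in the ring that touch a
// 4-neighbour of the centre
static int t4bar_components(const bool fg[9]) {
  bool seen[9] = {false};
  int comps = 0;
  static const bool is4nb[9] = {false, true, false, true, false,
                                true,  false, true, false};
  for (int p = 0; p < 9; ++p) {
    if (p == 4 || fg[p] || seen[p] || !is4nb[p]) continue;
    ++comps;
    std::vector<int> st{p};
    seen[p] = true;
    while (!st.empty()) {
      int q = st.back(); st.pop_back();
      int qr = q / 3 - 1, qc = q % 3 - 1;
      for (int r = 0; r < 9; ++r) {
        if (r == 4 || seen[r] || fg[r]) continue;
        int rr = r / 3 - 1, rc = r % 3 - 1;
        if (std::abs(qr - rr) + std::abs(qc - rc) == 1) {
          seen[r] = true;
          st.push_back(r);
        }
      }
    }
  }
  return comps;
}

static inline bool is_simple(const bool fg[9]) {
  return t8_components(fg) == 1 && t4bar_components(fg) == 1;
}

// Exposed for the exhaustive small-grid tests.
// [[Rcpp::export]]
bool cpp_is_simple_point(LogicalMatrix mask, int i, int j) {
  bool fg[9];
  fill_nbhd(mask, i, j, fg);
  return is_simple(fg);
}

// Fast-marching (first-order Eikonal, unit speed) distance from the
// background into the foreground. Background pixels have distance 0 and act
// as frozen sources; foreground pixels unreachable from any background pixel
// (a mask filling the whole frame) keep +Inf.
// [[Rcpp::export]]
NumericMatrix cpp_fmm_distance(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = R_PosInf;
  NumericMatrix d(nr, nc);
  std::vector<char> frozen((size_t)nr * nc, 0);
  typedef std::pair<double, int> DN;
  std::priority_queue<DN, std::vector<DN>, std::greater<DN> > heap;

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j)) d(i, j) = INF;
      else { d(i, j) = 0.0; frozen[i + (size_t)j * nr] = 1; }
    }

  static const int DR4[4] = {-1, 1, 0, 0};
  static const int DC4[4] = {0, 0, -1, 1};

  // Eikonal update at (i, j) from current neighbour values
  auto update = [&](int i, int j) -> double {
    double dx = INF, dy = INF;
    if (i > 0) dy = std::min(dy, d(i - 1, j));
    if (i < nr - 1) dy = std::min(dy, d(i + 1, j));
    if (j > 0) dx = std::min(dx, d(i, j - 1));
    if (j < nc - 1) dx = std::min(dx, d(i, j + 1));
    if (dx == INF && dy == INF) return INF;
    if (dx == INF || dy == INF || std::fabs(dx - dy) >= 1.0)
      return std::min(dx, dy) + 1.0;
    double diff = dx - dy;
    return (dx + dy + std::sqrt(2.0 - diff * diff)) / 2.0;
  };

  // seed trial band: foreground pixels 4-adjacent to background
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      bool near_bg = false;
      for (int k = 0; k < 4; ++k) {
        int ni = i + DR4[k], nj = j + DC4[k];
        if (ni >= 0 && ni < nr && nj >= 0 && nj < nc && !mask(ni, nj))
          near_bg = true;
      }
      if (near_bg) {
        double u = update(i, j);
        if (u < d(i, j)) d(i, j) = u;
        heap.push(DN(d(i, j), i + j * nr));
      }
    }

  while (!heap.empty()) {
    DN top = heap.top(); heap.pop();
    int idx = top.second;
    if (frozen[idx]) continue;
    int i = idx % nr, j = idx / nr;
    if (top.first > d(i, j)) continue;  // stale entry
    frozen[idx] = 1;
    for (int k = 0; k < 4; ++k) {
      int ni = i + DR4[k], nj = j + DC4[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      size_t nidx = ni + (size_t)nj * nr;
      if (!mask(ni, nj) || frozen[nidx]) continue;
      double u = update(ni, nj);
      if (u < d(ni, nj)) {
        d(ni, nj) = u;
        heap.push(DN(u, (int)nidx));
      }
    }
  }
  return d;
}

// Distance-ordered homotopic thinning: repeatedly delete the simple,
// non-endpoint foreground pixel with the smallest distance value until
// stable, then resolve any remaining 2x2 blocks. Deleting only simple
// points preserves the homotopy type (component and hole structure) of the
// mask; keeping endpoints (<= 1 foreground neighbour) preserves arm tips.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask, NumericMatrix dist) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out = clone(mask);
  typedef std::pair<double, int> DN;
  std::priority_queue<DN, std::vector<DN>, std::greater<DN> > heap;
  auto dval = [&](int i, int j) {
    double v = dist(i, j);
    return R_FINITE(v) ? v : 1e18;
  };
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (out(i, j)) heap.push(DN(dval(i, j), i + j * nr));

  bool fg[9];
  while (!heap.empty()) {
    int idx = heap.top().second; heap.pop();
    int i = idx % nr, j = idx / nr;
    if (!out(i, j)) continue;
    fill_nbhd(out, i, j, fg);
    if (count_fg_neighbours(fg) <= 1) continue;  // endpoint or isolated
    if (!is_simple(fg)) continue;
    out(i, j) = FALSE;
    for (int k = 0; k < 8; ++k) {
      int ni = i + DR8[k], nj = j + DC8[k];
      if (ni >= 0 && ni < nr && nj >= 0 && nj < nc && out(ni, nj))
        heap.push(DN(dval(ni, nj), ni + nj * nr));
    }
  }

  // Resolve remaining 2x2 blocks. A pixel inside an all-foreground 2x2
  // block has >= 3 neighbours, so removing simple block members never
  // deletes an endpoint. Rarely every block member is non-simple because
  // each anchors a short endpoint-protected arm (e.g. four diagonal arms
  // meeting in a 2x2 core); then the simple endpoint nearest to a block is
  // sacrificed and thinning resumes -- deletions stay simple-point only,
  // so the homotopy type is still preserved.
  auto in_block = [&](int i, int j) {
    for (int bi = i - 1; bi <= i; ++bi)
      for (int bj = j - 1; bj <= j; ++bj) {
        if (bi < 0 || bj < 0 || bi + 1 >= nr || bj + 1 >= nc) continue;
        if (out(bi, bj) && out(bi + 1, bj) && out(bi, bj + 1) &&
            out(bi + 1, bj + 1))
          return true;
      }
    return false;
  };
  int guard = 0;
  while (++guard < 10000) {
    bool changed = false;
    bool any_block = false;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        if (!out(i, j) || !in_block(i, j)) continue;
        any_block = true;
        fill_nbhd(out, i, j, fg);
        if (is_simple(fg)) { out(i, j) = FALSE; changed = true; }
      }
    if (!any_block) break;
    if (changed) continue;
    // stuck: erode the simple endpoint closest (chessboard) to any block
    std::vector<std::pair<int, int> > blocks;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        if (out(i, j) && in_block(i, j)) blocks.push_back({i, j});
    int best_i = -1, best_j = -1, best_d = INT_MAX;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        if (!out(i, j)) continue;
        fill_nbhd(out, i, j, fg);
        if (count_fg_neighbours(fg) > 1 || !is_simple(fg)) continue;
        for (size_t b = 0; b < blocks.size(); ++b) {
          int d = std::max(std::abs(i - blocks[b].first),
                           std::abs(j - blocks[b].second));
          if (d < best_d) { best_d = d; best_i = i; best_j = j; }
        }
      }
    if (best_i < 0) break;  // no simple endpoint anywhere: give up
    out(best_i, best_j) = FALSE;
  }
  return out;
}

// Number of foreground 8-neighbours per skeleton pixel (0 elsewhere).
// [[Rcpp::export]]
IntegerMatrix cpp_neighbour_count(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int n = 0;
      for (int k = 0; k < 8; ++k) {
        int ni = i + DR8[k], nj = j + DC8[k];
        if (ni >= 0 && ni < nr && nj >= 0 && nj < nc && mask(ni, nj)) ++n;
      }
      out(i, j) = n;
    }
  return out;
}

// Intensity-priority flood fill from labelled markers over the foreground
// mask. Queue entries are ordered by (pixel intensity descending, marker
// label ascending, insertion order ascending); a pixel takes the label of
// the first entry popped for it. Ties in intensity therefore go to the
// lowest marker label.
struct FloodEntry {
  double inten; int label; long order; int idx;
};
struct FloodCmp {
  bool operator()(const FloodEntry& a, const FloodEntry& b) const {
    if (a.inten != b.inten) return a.inten < b.inten;
    if (a.label != b.label) return a.label > b.label;
    return a.order > b.order;
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_priority_flood(NumericMatrix img, LogicalMatrix mask,
                                 IntegerMatrix markers) {
  const int nr = img.nrow(), nc = img.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc || markers.nrow() != nr ||
      markers.ncol() != nc)
    stop("image, mask and markers must share dimensions");
  IntegerMatrix labels = clone(markers);
  std::vector<char> expanded((size_t)nr * nc, 0);
  std::priority_queue<FloodEntry, std::vector<FloodEntry>, FloodCmp> heap;
  long counter = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (labels(i, j) > 0)
        heap.push(FloodEntry{img(i, j), labels(i, j), counter++, i + j * nr});

  while (!heap.empty()) {
    FloodEntry e = heap.top(); heap.pop();
    if (expanded[e.idx]) continue;
    int i = e.idx % nr, j = e.idx / nr;
    if (labels(i, j) == 0) labels(i, j) = e.label;
    expanded[e.idx] = 1;
    int lab = labels(i, j);
    for (int k = 0; k < 8; ++k) {
      int ni = i + DR8[k], nj = j + DC8[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      size_t nidx = ni + (size_t)nj * nr;
      if (mask(ni, nj) && !expanded[nidx] && labels(ni, nj) == 0)
        heap.push(FloodEntry{img(ni, nj), lab, counter++, (int)nidx});
    }
  }
  return labels;
}

// Render smooth fibres into an intensity field: for each polyline the
// Gaussian cross-section profile I * exp(-d^2 / (2 sigma^2)) is painted by
// dense sampling (step 0.25 px) with a per-pixel maximum, which approximates
// the distance-to-curve profile.
// [[Rcpp::export]]
NumericMatrix cpp_render_fibres(int nrow, int ncol, List fibres,
                                NumericVector sigmas,
                                NumericVector intensities) {
  NumericMatrix field(nrow, ncol);
  const double step = 0.25;
  for (int f = 0; f < fibres.size(); ++f) {
    NumericMatrix pts = fibres[f];  // columns: row, col (0-based, continuous)
    double sigma = sigmas[f], inten = intensities[f];
    int rad = (int)std::ceil(3.0 * sigma);
    double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    for (int s = 0; s + 1 < pts.nrow(); ++s) {
      double r0 = pts(s, 0), c0 = pts(s, 1);
      double r1 = pts(s + 1, 0), c1 = pts(s + 1, 1);
      double len = std::sqrt((r1 - r0) * (r1 - r0) + (c1 - c0) * (c1 - c0));
      int nstep = std::max(1, (int)std::ceil(len / step));
      for (int t = 0; t <= nstep; ++t) {
        double a = (double)t / nstep;
        double pr = r0 + a * (r1 - r0), pc = c0 + a * (c1 - c0);
        int ilo = std::max(0, (int)std::floor(pr) - rad);
        int ihi = std::min(nrow - 1, (int)std::ceil(pr) + rad);
        int jlo = std::max(0, (int)std::floor(pc) - rad);
        int jhi = std::min(ncol - 1, (int)std::ceil(pc) + rad);
        for (int j = jlo; j <= jhi; ++j)
          for (int i = ilo; i <= ihi; ++i) {
            double d2 = (i - pr) * (i - pr) + (j - pc) * (j - pc);
            double v = inten * std::exp(-d2 * inv2s2);
            if (v > field(i, j)) field(i, j) = v;
          }
      }
    }
  }
  return field;
}
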