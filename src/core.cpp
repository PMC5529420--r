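#include <Rcpp.h>
using namespace Rcpp;

// Neighbor offsets for the 3x3 ring, row-major order.
static const int NB8R[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int NB8C[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// ---------------------------------------------------------------------------
// Local entropy filter.
//
// For each pixel, the Shannon entropy (base 2) of the empirical distribution
// of quantized values in a square window, divided by log2 of the number of
// pixels actually inside the image, so values land on [0, 1] and borders are
// handled by shrinking the window rather than padding.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_local_entropy(IntegerMatrix img, int window) {
  const int nr = img.nrow(), nc = img.ncol(), h = window / 2;
  NumericMatrix out(nr, nc);
  std::vector<int> count(256, 0);
  std::vector<int> used;
  used.reserve(window * window);

  for (int j = 0; j < nc; ++j) {
    const int c0 = std::max(0, j - h), c1 = std::min(nc - 1, j + h);
    for (int i = 0; i < nr; ++i) {
      const int r0 = std::max(0, i - h), r1 = std::min(nr - 1, i + h);
      int n = 0;
      for (int cc = c0; cc <= c1; ++cc) {
        for (int rr = r0; rr <= r1; ++rr) {
          int v = img(rr, cc);
          if (count[v] == 0) used.push_back(v);
          ++count[v];
          ++n;
        }
      }
      double e = 0.0;
      for (size_t k = 0; k < used.size(); ++k) {
        double p = (double)count[used[k]] / n;
        e -= p * std::log2(p);
        count[used[k]] = 0;
      }
      used.clear();
      out(i, j) = (n > 1) ? e / std::log2((double)n) : 0.0;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling (4- or 8-connectivity), labels assigned in
// raster order of each component's first pixel.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < 8; ++k) {
          if (connectivity == 4 && NB8R[k] != 0 && NB8C[k] != 0) continue;
          int qi = pi + NB8R[k], qj = pj + NB8C[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Simple-point lookup table for topology-preserving thinning.
//
// A foreground pixel is "simple" (removable without changing topology) iff
// among its 8 neighbors the foreground forms exactly one 8-connected
// component and the background forms exactly one 4-connected component that
// is 4-adjacent to the center.  Foreground is 8-connected, background
// 4-connected (standard duality).
// ---------------------------------------------------------------------------

static bool ring_adjacent(int a, int b, bool eight) {
  int dr = std::abs(NB8R[a] - NB8R[b]);
  int dc = std::abs(NB8C[a] - NB8C[b]);
  if (dr > 1 || dc > 1) return false;
  if (dr == 0 && dc == 0) return false;
  if (!eight && dr + dc != 1) return false;
  return true;
}

static int ring_components(unsigned cfg, bool fg, bool eight, bool need_4adj) {
  bool in[8], seen[8] = {false};
  for (int k = 0; k < 8; ++k) {
    bool set = (cfg >> k) & 1u;
    in[k] = fg ? set : !set;
  }
  int comp = 0;
  for (int k = 0; k < 8; ++k) {
    if (!in[k] || seen[k]) continue;
    // flood this component over the ring
    std::vector<int> st(1, k);
    seen[k] = true;
    bool touches4 = false;
    while (!st.empty()) {
      int a = st.back(); st.pop_back();
      if (NB8R[a] == 0 || NB8C[a] == 0) touches4 = true;
      for (int b = 0; b < 8; ++b) {
        if (in[b] && !seen[b] && ring_adjacent(a, b, eight)) {
          seen[b] = true;
          st.push_back(b);
        }
      }
    }
    if (!need_4adj || touches4) ++comp;
  }
  return comp;
}

static std::vector<unsigned char> simple_lut() {
  std::vector<unsigned char> lut(256);
  for (unsigned cfg = 0; cfg < 256; ++cfg) {
    int cfg_fg = ring_components(cfg, true, true, false);
    int cfg_bg = ring_components(cfg, false, false, true);
    lut[cfg] = (cfg_fg == 1 && cfg_bg == 1) ? 1 : 0;
  }
  return lut;
}

// ---------------------------------------------------------------------------
// Topology-preserving thinning by layered simple-point peeling.
//
// The Chebyshev distance to background of the input mask is computed first;
// pass k may only remove pixels at depth k, so at most `iterations` one-pixel
// layers are peeled and no deeper pixel is ever touched.  Within a pass,
// pixels are visited in raster order against the current (partially updated)
// mask, so every removal is individually topology-safe.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask, int iterations) {
  static std::vector<unsigned char> lut = simple_lut();
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix M = clone(mask);

  // two-pass Chebyshev chamfer distance to background (pixels outside the
  // image count as background)
  IntegerMatrix d(nr, nc);
  const int INF = nr + nc + 2;
  const int FWD_R[4] = {-1, 0, 1, -1}, FWD_C[4] = {-1, -1, -1, 0};
  const int BWD_R[4] = {1, 0, -1, 1},  BWD_C[4] = {1, 1, 1, 0};
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (M(i, j) == 0) { d(i, j) = 0; continue; }
      int best = INF;
      for (int k = 0; k < 4; ++k) {
        int qi = i + FWD_R[k], qj = j + FWD_C[k];
        int v = (qi < 0 || qi >= nr || qj < 0 || qj >= nc) ? 0 : d(qi, qj);
        if (v < best) best = v;
      }
      d(i, j) = std::min(INF, best + 1);
    }
  }
  for (int j = nc - 1; j >= 0; --j) {
    for (int i = nr - 1; i >= 0; --i) {
      if (d(i, j) == 0) continue;
      int best = d(i, j) - 1;
      for (int k = 0; k < 4; ++k) {
        int qi = i + BWD_R[k], qj = j + BWD_C[k];
        int v = (qi < 0 || qi >= nr || qj < 0 || qj >= nc) ? 0 : d(qi, qj);
        if (v < best) best = v;
      }
      d(i, j) = best + 1;
    }
  }

  for (int k = 1; k <= iterations; ++k) {
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (M(i, j) == 0 || d(i, j) != k) continue;
        unsigned cfg = 0;
        for (int b = 0; b < 8; ++b) {
          int qi = i + NB8R[b], qj = j + NB8C[b];
          bool fgn = qi >= 0 && qi < nr && qj >= 0 && qj < nc && M(qi, qj) != 0;
          if (fgn) cfg |= (1u << b);
        }
        if (lut[cfg]) M(i, j) = 0;
      }
    }
  }
  return M;
}
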