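#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Zhang-Suen thinning. Input/output: 0/1 integer matrix. Preserves
// 8-connectivity of the foreground and reduces ribbons to 1-px curves.
// [[Rcpp::export(name = ".thin_cpp")]]
IntegerMatrix thin_cpp(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix img(clone(mask));
  // neighbour order P2..P9 clockwise starting north (Zhang-Suen convention)
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  std::vector<std::pair<int, int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (!img(r, c)) continue;
          int p[8], bsum = 0;
          for (int k = 0; k < 8; ++k) {
            int rr = r + dr[k], cc = c + dc[k];
            p[k] = (rr >= 0 && rr < H && cc >= 0 && cc < W) ? img(rr, cc) : 0;
            bsum += p[k];
          }
          if (bsum < 2 || bsum > 6) continue;
          int a = 0;  // 0->1 transitions in P2..P9,P2
          for (int k = 0; k < 8; ++k)
            if (!p[k] && p[(k + 1) % 8]) ++a;
          if (a != 1) continue;
          // P2 P4 P6 / P4 P6 P8 products (indices 0,2,4,6)
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          del.push_back(std::make_pair(r, c));
        }
      }
      if (!del.empty()) changed = true;
      for (size_t i = 0; i < del.size(); ++i) img(del[i].first, del[i].second) = 0;
    }
  }
  // Sequential cleanup: the parallel passes leave 2-px-thick diagonal
  // staircases (2x2 blocks survive Zhang-Suen). A non-endpoint pixel is
  // removed when it is a simple point: its foreground neighbours form one
  // 8-connected component and its background neighbours one 4-connected
  // component touching a 4-neighbour. Removal updates immediately, until
  // stable; this leaves a minimal 8-connected curve.
  changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        if (!img(r, c)) continue;
        int p[8], bsum = 0;
        for (int k = 0; k < 8; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          p[k] = (rr >= 0 && rr < H && cc >= 0 && cc < W) ? img(rr, cc) : 0;
          bsum += p[k];
        }
        if (bsum < 2 || bsum == 8) continue;
        // union-find over the 8 ring cells
        int par[8];
        for (int k = 0; k < 8; ++k) par[k] = k;
        // find with path halving
        #define FIND(x) ({ int _x = (x); while (par[_x] != _x) { par[_x] = par[par[_x]]; _x = par[_x]; } _x; })
        int cfg = 0;
        for (int k = 0; k < 8; ++k) {
          if (!p[k]) continue;
          for (int k2 = k + 1; k2 < 8; ++k2) {
            if (!p[k2]) continue;
            int ddr = dr[k] - dr[k2], ddc = dc[k] - dc[k2];
            if (ddr >= -1 && ddr <= 1 && ddc >= -1 && ddc <= 1) {
              int ra = FIND(k), rb = FIND(k2);
              if (ra != rb) par[ra] = rb;
            }
          }
        }
        for (int k = 0; k < 8; ++k)
          if (p[k] && FIND(k) == k) ++cfg;
        if (cfg != 1) continue;
        // background 4-components among the ring, seeded at 4-neighbours
        for (int k = 0; k < 8; ++k) par[k] = k;
        for (int k = 0; k < 8; ++k) {
          if (p[k]) continue;
          for (int k2 = k + 1; k2 < 8; ++k2) {
            if (p[k2]) continue;
            int ddr = dr[k] - dr[k2], ddc = dc[k] - dc[k2];
            if ((ddr == 0 && (ddc == 1 || ddc == -1)) ||
                (ddc == 0 && (ddr == 1 || ddr == -1))) {
              int ra = FIND(k), rb = FIND(k2);
              if (ra != rb) par[ra] = rb;
            }
          }
        }
        // 4-neighbour ring indices: N=0, E=2, S=4, W=6
        bool seen[8] = {false, false, false, false, false, false, false, false};
        int cbg = 0;
        const int four[4] = {0, 2, 4, 6};
        for (int t = 0; t < 4; ++t) {
          int k = four[t];
          if (p[k]) continue;
          int root = FIND(k);
          if (!seen[root]) { seen[root] = true; ++cbg; }
        }
        #undef FIND
        if (cbg != 1) continue;
        img(r, c) = 0;
        changed = true;
      }
    }
  }
  return img;
}

// Exact Euclidean distance transform with nearest-site feature transform
// (Felzenszwalb & Huttenlocher lower-envelope algorithm on squared
// distances, applied per column then per row). `sites` is 0/1; distances
// are measured to the nearest site pixel *center*. Returns the Euclidean
// distance matrix and the 1-based linear index (column-major, R layout) of
// the nearest site, or NA when there is no site at all.
// [[Rcpp::export(name = ".edt_cpp")]]
List edt_cpp(IntegerMatrix sites) {
  int H = sites.nrow(), W = sites.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix d2(H, W);
  IntegerMatrix nearr(H, W);  // row of nearest site within the same column
  // pass 1: along each column (1-D distance over rows)
  for (int c = 0; c < W; ++c) {
    int last = -1;
    for (int r = 0; r < H; ++r) {
      if (sites(r, c)) last = r;
      if (last >= 0) { d2(r, c) = double(r - last) * (r - last); nearr(r, c) = last; }
      else { d2(r, c) = INF; nearr(r, c) = -1; }
    }
    last = -1;
    for (int r = H - 1; r >= 0; --r) {
      if (sites(r, c)) last = r;
      if (last >= 0) {
        double dd = double(last - r) * (last - r);
        if (dd < d2(r, c)) { d2(r, c) = dd; nearr(r, c) = last; }
      }
    }
  }
  // pass 2: lower envelope along each row
  NumericMatrix dist(H, W);
  IntegerMatrix nearest(H, W);
  std::vector<int> v(W);        // sites (columns) of parabolas in envelope
  std::vector<double> z(W + 1); // break points
  for (int r = 0; r < H; ++r) {
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    // skip leading infinite columns
    int c0 = 0;
    while (c0 < W && d2(r, c0) == INF) ++c0;
    if (c0 == W) {
      for (int c = 0; c < W; ++c) { dist(r, c) = INF; nearest(r, c) = NA_INTEGER; }
      continue;
    }
    v[0] = c0;
    for (int c = c0 + 1; c < W; ++c) {
      if (d2(r, c) == INF) continue;
      double s;
      while (true) {
        int q = v[k];
        s = ((d2(r, c) + double(c) * c) - (d2(r, q) + double(q) * q)) / (2.0 * c - 2.0 * q);
        if (s <= z[k]) { --k; } else break;
      }
      ++k;
      v[k] = c;
      z[k] = s;
      z[k + 1] = INF;
    }
    int j = 0;
    for (int c = 0; c < W; ++c) {
      while (z[j + 1] < c) ++j;
      int q = v[j];
      double dd = double(c - q) * (c - q) + d2(r, q);
      dist(r, c) = std::sqrt(dd);
      int nr = nearr(r, q);
      nearest(r, c) = nr + q * H + 1;  // 1-based column-major index
    }
  }
  return List::create(_["dist"] = dist, _["nearest"] = nearest);
}

// Connected-component labeling, conn = 4 or 8. Returns 0 on background,
// labels 1..n on foreground.
// [[Rcpp::export(name = ".label_cpp")]]
IntegerMatrix label_cpp(IntegerMatrix mask, int conn) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  int nn = (conn == 8) ? 8 : 4;
  const int* DR = (conn == 8) ? dr8 : dr4;
  const int* DC = (conn == 8) ? dc8 : dc4;
  int cur = 0;
  std::vector<int> stack;
  stack.reserve(H * W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++cur;
      lab(r, c) = cur;
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % H, cc = idx / H;
        for (int k = 0; k < nn; ++k) {
          int r2 = rr + DR[k], c2 = cc + DC[k];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = cur;
            stack.push_back(r2 + c2 * H);
          }
        }
      }
    }
  }
  return lab;
}

// Count of 8-neighbours that are foreground, for skeleton graph building.
// [[Rcpp::export(name = ".neighbor_count_cpp")]]
IntegerMatrix neighbor_count_cpp(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix cnt(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      int s = 0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (!dr && !dc) continue;
          int rr = r + dr, cc = c + dc;
          if (rr >= 0 && rr < H && cc >= 0 && cc < W && mask(rr, cc)) ++s;
        }
      cnt(r, c) = s;
    }
  return cnt;
}

// Binary dilation with a (2k+1)x(2k+1) square (Chebyshev radius k).
// [[Rcpp::export(name = ".dilate_cpp")]]
IntegerMatrix dilate_cpp(IntegerMatrix mask, int k) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      for (int dr = -k; dr <= k; ++dr)
        for (int dc = -k; dc <= k; ++dc) {
          int rr = r + dr, cc = c + dc;
          if (rr >= 0 && rr < H && cc >= 0 && cc < W) out(rr, cc) = 1;
        }
    }
  return out;
}
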