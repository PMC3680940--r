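// Low-level raster operations used by the density pipeline: grayscale and
// binary morphology, exact Euclidean distance transform, distance-transform
// watershed, Zhang-Suen thinning, connected components, boundary tracing.
// All rasters are R matrices (column-major); coordinates are 0-based.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline bool inb(int r, int c, int nr, int nc) {
  return r >= 0 && r < nr && c >= 0 && c < nc;
}

// offsets of a flat disk structuring element of given radius
static std::vector<std::pair<int,int>> disk_offsets(int radius) {
  std::vector<std::pair<int,int>> off;
  int r2 = radius * radius;
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      if (dr * dr + dc * dc <= r2) off.push_back(std::make_pair(dr, dc));
  return off;
}

// [[Rcpp::export]]
NumericMatrix cpp_morph_disk(NumericMatrix img, int radius, bool dilate) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<std::pair<int,int>> off = disk_offsets(radius);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = dilate ? R_NegInf : R_PosInf;
      for (size_t k = 0; k < off.size(); ++k) {
        int rr = r + off[k].first, cc = c + off[k].second;
        if (!inb(rr, cc, nr, nc)) continue;  // border: restrict to image
        double p = img(rr, cc);
        if (dilate) { if (p > v) v = p; } else { if (p < v) v = p; }
      }
      out(r, c) = v;
    }
  }
  return out;
}

// grayscale erosion/dilation with a "ball" (spherical cap) structuring
// element of the given radius: erode subtracts the cap height, dilate adds it
// [[Rcpp::export]]
NumericMatrix cpp_morph_ball(NumericMatrix img, double radius, bool dilate) {
  int nr = img.nrow(), nc = img.ncol();
  int ir = (int)std::floor(radius);
  std::vector<int> dr, dc;
  std::vector<double> h;
  for (int a = -ir; a <= ir; ++a)
    for (int b = -ir; b <= ir; ++b) {
      double d2 = (double)a * a + (double)b * b;
      if (d2 <= radius * radius) {
        dr.push_back(a); dc.push_back(b);
        h.push_back(std::sqrt(radius * radius - d2));
      }
    }
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v = dilate ? R_NegInf : R_PosInf;
      for (size_t k = 0; k < dr.size(); ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (!inb(rr, cc, nr, nc)) continue;
        double p = dilate ? img(rr, cc) + h[k] : img(rr, cc) - h[k];
        if (dilate) { if (p > v) v = p; } else { if (p < v) v = p; }
      }
      out(r, c) = v;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> win;
  win.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      win.clear();
      for (int dr = -radius; dr <= radius; ++dr)
        for (int dc = -radius; dc <= radius; ++dc) {
          int rr = r + dr, cc = c + dc;
          if (inb(rr, cc, nr, nc)) win.push_back(img(rr, cc));
        }
      size_t n = win.size(), mid = n / 2;
      std::nth_element(win.begin(), win.begin() + mid, win.end());
      double m = win[mid];
      if (n % 2 == 0) {
        std::nth_element(win.begin(), win.begin() + mid - 1, win.begin() + mid);
        m = (m + win[mid - 1]) / 2.0;
      }
      out(r, c) = m;
    }
  return out;
}

// separable convolution with reflected borders (kernel must be odd-length)
// [[Rcpp::export]]
NumericMatrix cpp_convolve_sep(NumericMatrix img, NumericVector kernel) {
  int nr = img.nrow(), nc = img.ncol();
  int kl = kernel.size(), kh = kl / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0;
      for (int k = -kh; k <= kh; ++k) {
        int rr = r + k;
        if (rr < 0) rr = -rr - 1;
        if (rr >= nr) rr = 2 * nr - rr - 1;
        s += img(rr, c) * kernel[k + kh];
      }
      tmp(r, c) = s;
    }
  // along columns (horizontal)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0;
      for (int k = -kh; k <= kh; ++k) {
        int cc = c + k;
        if (cc < 0) cc = -cc - 1;
        if (cc >= nc) cc = 2 * nc - cc - 1;
        s += tmp(r, cc) * kernel[k + kh];
      }
      out(r, c) = s;
    }
  return out;
}

// 3x3 Sobel gradient magnitude, replicated borders
// [[Rcpp::export]]
NumericMatrix cpp_sobel(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double p[3][3];
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          int rr = std::min(std::max(r + dr, 0), nr - 1);
          int cc = std::min(std::max(c + dc, 0), nc - 1);
          p[dr + 1][dc + 1] = img(rr, cc);
        }
      double gx = (p[0][2] + 2 * p[1][2] + p[2][2]) -
                  (p[0][0] + 2 * p[1][0] + p[2][0]);
      double gy = (p[2][0] + 2 * p[2][1] + p[2][2]) -
                  (p[0][0] + 2 * p[0][1] + p[0][2]);
      out(r, c) = std::sqrt(gx * gx + gy * gy);
    }
  return out;
}

// connected components; connectivity 4 or 8; labels assigned in row-major
// scan order of the first pixel encountered (deterministic)
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  int nn = (connectivity == 8) ? 8 : 4;
  const int *DR = (connectivity == 8) ? dr8 : dr4;
  const int *DC = (connectivity == 8) ? dc8 : dc4;
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(r * nc + c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cr = idx / nc, cc0 = idx % nc;
        for (int k = 0; k < nn; ++k) {
          int rr = cr + DR[k], cc = cc0 + DC[k];
          if (inb(rr, cc, nr, nc) && mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            stack.push_back(rr * nc + cc);
          }
        }
      }
    }
  lab.attr("n_labels") = next;
  return lab;
}

// exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher):
// distance from each foreground pixel to the nearest background pixel
static void edt_1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = R_NegInf; z[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e12;
  NumericMatrix g(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // pass along columns of the image (each column an independent 1-D problem)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? BIG : 0.0;
    edt_1d(f, d, nr);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    edt_1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = d[c];
  }
  return out;
}

// distance-transform watershed of a binary mask: seeds are connected
// plateaus of local maxima of the EDT; flooding by descending distance.
// Labels partition the mask; label count >= component count.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed_binary(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix dist = cpp_edt_sq(mask);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  // local maxima (plateau-tolerant): no in-mask neighbour strictly higher
  LogicalMatrix peak(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) { peak(r, c) = false; continue; }
      bool ok = true;
      for (int k = 0; k < 8 && ok; ++k) {
        int rr = r + dr8[k], cc = c + dc8[k];
        if (inb(rr, cc, nr, nc) && mask(rr, cc) && dist(rr, cc) > dist(r, c))
          ok = false;
      }
      peak(r, c) = ok;
    }
  IntegerMatrix lab = cpp_label_components(peak, 8);
  // priority flood: highest distance first; FIFO order within ties
  struct Cmp {
    bool operator()(const std::pair<double, std::pair<long long, int>> &a,
                    const std::pair<double, std::pair<long long, int>> &b) const {
      if (a.first != b.first) return a.first < b.first;
      return a.second.first > b.second.first;  // earlier insertion first
    }
  };
  std::priority_queue<std::pair<double, std::pair<long long, int>>,
                      std::vector<std::pair<double, std::pair<long long, int>>>,
                      Cmp> pq;
  long long order = 0;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (lab(r, c) > 0)
        pq.push(std::make_pair(dist(r, c),
                               std::make_pair(order++, r * nc + c)));
  while (!pq.empty()) {
    int idx = pq.top().second.second; pq.pop();
    int r = idx / nc, c = idx % nc;
    int l = lab(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr8[k], cc = c + dc8[k];
      if (inb(rr, cc, nr, nc) && mask(rr, cc) && lab(rr, cc) == 0) {
        lab(rr, cc) = l;
        pq.push(std::make_pair(dist(rr, cc),
                               std::make_pair(order++, rr * nc + cc)));
      }
    }
  }
  // relabel to consecutive ids in row-major first-occurrence order
  int maxlab = 0;
  for (int i = 0; i < nr * nc; ++i) maxlab = std::max(maxlab, lab[i]);
  std::vector<int> remap(maxlab + 1, 0);
  int next = 0;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (lab(r, c) > 0 && remap[lab(r, c)] == 0) remap[lab(r, c)] = ++next;
  for (int i = 0; i < nr * nc; ++i) if (lab[i] > 0) lab[i] = remap[lab[i]];
  lab.attr("n_labels") = next;
  return lab;
}

// Zhang-Suen iterative thinning to a 1-px topological skeleton.
// Only pixels whose neighbourhood changed in the previous cycle are
// revisited (active-list formulation), which keeps large blobs cheap.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix input) {
  int nr = input.nrow(), nc = input.ncol();
  LogicalMatrix img = clone(input);
  const int drn[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dcn[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  std::vector<int> active, next_active, kill;
  std::vector<char> queued((size_t)nr * nc, 0);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (img(r, c)) active.push_back(r * nc + c);
  bool changed = true;
  while (changed) {
    changed = false;
    next_active.clear();
    std::fill(queued.begin(), queued.end(), 0);
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (size_t ai = 0; ai < active.size(); ++ai) {
        int r = active[ai] / nc, c = active[ai] % nc;
        {
          if (!img(r, c)) continue;
          // neighbours p2..p9 clockwise from north; outside counts as 0
          int p[8];
          for (int k = 0; k < 8; ++k) {
            int rr = r + drn[k], cc = c + dcn[k];
            p[k] = (inb(rr, cc, nr, nc) && img(rr, cc)) ? 1 : 0;
          }
          int B = 0;
          for (int k = 0; k < 8; ++k) B += p[k];
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int k = 0; k < 8; ++k)
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;  // p2*p4*p6
            if (p[2] * p[4] * p[6] != 0) continue;  // p4*p6*p8
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;  // p2*p4*p8
            if (p[0] * p[4] * p[6] != 0) continue;  // p2*p6*p8
          }
          kill.push_back(r * nc + c);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i) {
        int r = kill[i] / nc, c = kill[i] % nc;
        img(r, c) = false;
        for (int k = 0; k < 8; ++k) {
          int rr = r + drn[k], cc = c + dcn[k];
          if (inb(rr, cc, nr, nc) && img(rr, cc) && !queued[rr * nc + cc]) {
            queued[rr * nc + cc] = 1;
            next_active.push_back(rr * nc + cc);
          }
        }
      }
    }
    // survivors adjacent to a deletion are the only candidates next cycle
    active.clear();
    for (size_t i = 0; i < next_active.size(); ++i)
      if (img(next_active[i] / nc, next_active[i] % nc))
        active.push_back(next_active[i]);
    std::sort(active.begin(), active.end());
  }
  return img;
}

// outer-boundary perimeter per label by Moore tracing of the 8-connected
// chain, with the Vossepoel-Smeulders corrected step weights
// (0.980 axial + 1.406 diagonal - 0.091 per direction change), which make
// the digital perimeter of smooth shapes converge to the true length;
// single pixels get 0
// [[Rcpp::export]]
NumericVector cpp_perimeters(IntegerMatrix lab, int n_labels) {
  int nr = lab.nrow(), nc = lab.ncol();
  NumericVector per(n_labels);
  std::vector<int> startr(n_labels, -1), startc(n_labels, -1);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      int l = lab(r, c);
      if (l > 0 && startr[l - 1] < 0) { startr[l - 1] = r; startc[l - 1] = c; }
    }
  // Moore neighbourhood in clockwise order starting west
  const int dr8[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc8[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const double wt[8] = {0.980, 1.406, 0.980, 1.406,
                        0.980, 1.406, 0.980, 1.406};
  for (int l = 0; l < n_labels; ++l) {
    int sr = startr[l], sc = startc[l];
    if (sr < 0) { per[l] = NA_REAL; continue; }
    // isolated pixel?
    bool alone = true;
    for (int k = 0; k < 8 && alone; ++k) {
      int rr = sr + dr8[k], cc = sc + dc8[k];
      if (inb(rr, cc, nr, nc) && lab(rr, cc) == l + 1) alone = false;
    }
    if (alone) { per[l] = 0.0; continue; }
    double total = 0.0;
    int cr = sr, cc0 = sc;
    int backtrack = 0;  // came from west (start is topmost-leftmost)
    int firstdir = -1, prevdir = -1;
    long long guard = 0, lim = 8LL * nr * nc;
    while (true) {
      int dir = -1;
      for (int k = 0; k < 8; ++k) {
        int d = (backtrack + k) % 8;
        int rr = cr + dr8[d], cc = cc0 + dc8[d];
        if (inb(rr, cc, nr, nc) && lab(rr, cc) == l + 1) { dir = d; break; }
      }
      if (dir < 0) break;
      if (cr == sr && cc0 == sc) {
        if (firstdir < 0) firstdir = dir;
        else if (dir == firstdir && guard > 0) break;  // closed the contour
      }
      total += wt[dir];
      if (prevdir >= 0 && dir != prevdir) total -= 0.091;
      prevdir = dir;
      cr += dr8[dir];
      cc0 += dc8[dir];
      // resume the clockwise scan one slot past the direction pointing back
      // to the previous pixel ((dir+4)%8), i.e. at (dir+5)%8
      backtrack = (dir + 5) % 8;
      if (++guard > lim) break;
    }
    per[l] = total;
  }
  return per;
}

// min-pooling downscale by integer factor (used by rolling-ball shrink)
// [[Rcpp::export]]
NumericMatrix cpp_min_pool(NumericMatrix img, int factor) {
  int nr = img.nrow(), nc = img.ncol();
  int mr = (nr + factor - 1) / factor, mc = (nc + factor - 1) / factor;
  NumericMatrix out(mr, mc);
  for (int c = 0; c < mc; ++c)
    for (int r = 0; r < mr; ++r) {
      double v = R_PosInf;
      for (int dr = 0; dr < factor; ++dr)
        for (int dc = 0; dc < factor; ++dc) {
          int rr = r * factor + dr, cc = c * factor + dc;
          if (rr < nr && cc < nc && img(rr, cc) < v) v = img(rr, cc);
        }
      out(r, c) = v;
    }
  return out;
}

// bilinear upscale to an exact target size (inverse of cpp_min_pool grid)
// [[Rcpp::export]]
NumericMatrix cpp_bilinear_resize(NumericMatrix img, int nr_out, int nc_out) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr_out, nc_out);
  double sr = (double)nr / nr_out, sc = (double)nc / nc_out;
  for (int c = 0; c < nc_out; ++c)
    for (int r = 0; r < nr_out; ++r) {
      double y = (r + 0.5) * sr - 0.5, x = (c + 0.5) * sc - 0.5;
      int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
      double fy = y - y0, fx = x - x0;
      int y1 = std::min(y0 + 1, nr - 1), x1 = std::min(x0 + 1, nc - 1);
      y0 = std::max(y0, 0); x0 = std::max(x0, 0);
      out(r, c) = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
                  fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
    }
  return out;
}
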