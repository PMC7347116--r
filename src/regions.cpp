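// Pixel-region primitives: connected-component labelling, Moore-neighbor
// boundary tracing (Jacob's stopping criterion), shoelace polygon area, and
// boundary-inclusive even-odd polygon rasterization.
//
// Conventions (used package-wide): images are R matrices with nrow = height
// (y) and ncol = width (x); pixel coordinates are 0-based (x = column,
// y = row) with pixel centers at integer coordinates; polygons are n x 2
// matrices with columns (x, y).
#include <Rcpp.h>
#include <vector>
#include <set>
#include <utility>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& bin, int connectivity) {
  const int H = bin.nrow(), W = bin.ncol();
  IntegerMatrix labels(H, W);
  static const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  static const int dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int ndir = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (bin(r, c) == 0 || labels(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * H);
      labels(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % H, pc = p / H;
        for (int d = 0; d < ndir; ++d) {
          int nr = pr + dy8[d], nc = pc + dx8[d];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (bin(nr, nc) != 0 && labels(nr, nc) == 0) {
            labels(nr, nc) = next;
            stack.push_back(nr + nc * H);
          }
        }
      }
    }
  }
  labels.attr("n_labels") = next;
  return labels;
}

// Moore neighborhood in clockwise order (image coordinates, y down),
// starting from West.
static const int mdx[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int mdy[8] = {0, -1, -1, -1, 0, 1, 1, 1};

// Trace the outer boundary of the region labelled `lab`, clockwise, through
// pixel centers. Returns an n x 2 matrix of (x, y). Single pixels give a
// 1-vertex polygon.
// [[Rcpp::export]]
NumericMatrix cpp_trace_boundary(const IntegerMatrix& labels, int lab) {
  const int H = labels.nrow(), W = labels.ncol();
  auto inside = [&](int x, int y) {
    return x >= 0 && x < W && y >= 0 && y < H && labels(y, x) == lab;
  };
  int sx = -1, sy = -1;
  long long npix = 0;
  for (int y = 0; y < H && sx < 0; ++y)
    for (int x = 0; x < W; ++x)
      if (labels(y, x) == lab) { sx = x; sy = y; break; }
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      if (labels(y, x) == lab) ++npix;
  if (sx < 0) stop("label %d not present in label image", lab);

  std::vector<double> px, py;
  px.push_back(sx); py.push_back(sy);

  // Backtrack starts one pixel West of the start (scan order guarantees it
  // is background or outside).
  int b0x = sx - 1, b0y = sy;
  int cx = sx, cy = sy, bx = b0x, by = b0y;
  // Termination: stop when the tracing state (current pixel + backtrack
  // position) repeats. This subsumes Jacob's criterion (re-entering the
  // start with the original backtrack) and also closes cleanly on narrow
  // shapes whose re-entry backtrack differs from the artificial initial
  // one.
  std::set<std::pair<long long, long long>> seen;
  auto state = [&](int x, int y, int bxx, int byy) {
    return std::make_pair((long long)y * W + x,
                          (long long)(byy + 1) * (W + 2) + (bxx + 1));
  };
  seen.insert(state(cx, cy, bx, by));
  const long long maxit = 8 * npix + 16;
  for (long long it = 0; it < maxit; ++it) {
    // direction index from current pixel to backtrack pixel
    int bdir = -1;
    for (int d = 0; d < 8; ++d)
      if (cx + mdx[d] == bx && cy + mdy[d] == by) { bdir = d; break; }
    if (bdir < 0) stop("internal error: backtrack not adjacent");
    int foundx = -1, foundy = -1, prevx = bx, prevy = by;
    for (int k = 1; k <= 8; ++k) {
      int d = (bdir + k) % 8;
      int nx = cx + mdx[d], ny = cy + mdy[d];
      if (inside(nx, ny)) { foundx = nx; foundy = ny; break; }
      prevx = nx; prevy = ny;
    }
    if (foundx < 0) break;  // isolated single pixel
    if (!seen.insert(state(foundx, foundy, prevx, prevy)).second) break;
    px.push_back(foundx); py.push_back(foundy);
    cx = foundx; cy = foundy; bx = prevx; by = prevy;
  }
  NumericMatrix poly(px.size(), 2);
  for (size_t i = 0; i < px.size(); ++i) { poly(i, 0) = px[i]; poly(i, 1) = py[i]; }
  colnames(poly) = CharacterVector::create("x", "y");
  return poly;
}

// Shoelace (Green's theorem) area of a closed polygon given by its vertex
// list (closure implicit). Degenerate polygons (<3 vertices, collinear)
// give 0.
// [[Rcpp::export]]
double cpp_polygon_area(const NumericMatrix& poly) {
  const int n = poly.nrow();
  if (n < 3) return 0.0;
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    s += poly(i, 0) * poly(j, 1) - poly(j, 0) * poly(i, 1);
  }
  return std::fabs(s) / 2.0;
}

static bool near_int(double v, double eps) {
  return std::fabs(v - std::round(v)) < eps;
}

// Rasterize one simple polygon onto an H x W grid: pixel = 1 iff its center
// (integer coordinates) is inside under the even-odd rule, or lies exactly
// on the boundary.
// [[Rcpp::export]]
IntegerMatrix cpp_fill_polygon(const NumericMatrix& poly, int H, int W) {
  IntegerMatrix mask(H, W);
  const int n = poly.nrow();
  if (n < 3) stop("polygon needs at least 3 vertices");
  const double eps = 1e-9;

  double ymin = poly(0, 1), ymax = poly(0, 1);
  for (int i = 0; i < n; ++i) {
    ymin = std::min(ymin, poly(i, 1));
    ymax = std::max(ymax, poly(i, 1));
  }
  int y0 = std::max(0, (int)std::ceil(ymin - eps));
  int y1 = std::min(H - 1, (int)std::floor(ymax + eps));

  std::vector<double> xs;
  for (int y = y0; y <= y1; ++y) {
    xs.clear();
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      double ya = poly(i, 1), yb = poly(j, 1);
      double xa = poly(i, 0), xb = poly(j, 0);
      if (ya == yb) continue;  // horizontal edges handled by boundary pass
      double lo = std::min(ya, yb), hi = std::max(ya, yb);
      // half-open rule [lo, hi) for even-odd crossing parity
      if (y >= lo && y < hi) {
        double t = (y - ya) / (yb - ya);
        xs.push_back(xa + t * (xb - xa));
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int xlo = std::max(0, (int)std::ceil(xs[k] - eps));
      int xhi = std::min(W - 1, (int)std::floor(xs[k + 1] + eps));
      for (int x = xlo; x <= xhi; ++x) mask(y, x) = 1;
    }
  }

  // Boundary pass: pixel centers lying exactly on an edge count as inside.
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double ya = poly(i, 1), yb = poly(j, 1);
    double xa = poly(i, 0), xb = poly(j, 0);
    if (near_int(xa, eps) && near_int(ya, eps)) {
      int vx = (int)std::round(xa), vy = (int)std::round(ya);
      if (vx >= 0 && vx < W && vy >= 0 && vy < H) mask(vy, vx) = 1;
    }
    if (ya == yb) {
      if (!near_int(ya, eps)) continue;
      int y = (int)std::round(ya);
      if (y < 0 || y >= H) continue;
      int xlo = std::max(0, (int)std::ceil(std::min(xa, xb) - eps));
      int xhi = std::min(W - 1, (int)std::floor(std::max(xa, xb) + eps));
      for (int x = xlo; x <= xhi; ++x) mask(y, x) = 1;
    } else {
      int ylo = std::max(0, (int)std::ceil(std::min(ya, yb) - eps));
      int yhi = std::min(H - 1, (int)std::floor(std::max(ya, yb) + eps));
      for (int y = ylo; y <= yhi; ++y) {
        double t = (y - ya) / (yb - ya);
        if (t < -eps || t > 1 + eps) continue;
        double x = xa + t * (xb - xa);
        if (near_int(x, 1e-7)) {
          int xi = (int)std::round(x);
          if (xi >= 0 && xi < W) mask(y, xi) = 1;
        }
      }
    }
  }
  return mask;
}

// Even-odd point-in-polygon with boundary counted as inside, for scattered
// query points (used for centroid-in-polygon matching).
// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(const NumericMatrix& pts,
                                    const NumericMatrix& poly) {
  const int m = pts.nrow(), n = poly.nrow();
  if (n < 3) stop("polygon needs at least 3 vertices");
  LogicalVector out(m);
  const double eps = 1e-9;
  for (int p = 0; p < m; ++p) {
    double x = pts(p, 0), y = pts(p, 1);
    bool onb = false, in = false;
    for (int i = 0; i < n && !onb; ++i) {
      int j = (i + 1) % n;
      double xa = poly(i, 0), ya = poly(i, 1);
      double xb = poly(j, 0), yb = poly(j, 1);
      double cross = (xb - xa) * (y - ya) - (yb - ya) * (x - xa);
      if (std::fabs(cross) < eps &&
          x >= std::min(xa, xb) - eps && x <= std::max(xa, xb) + eps &&
          y >= std::min(ya, yb) - eps && y <= std::max(ya, yb) + eps)
        onb = true;
      if ((ya > y) != (yb > y)) {
        double xint = xa + (y - ya) / (yb - ya) * (xb - xa);
        if (x < xint) in = !in;
      }
    }
    out[p] = onb || in;
  }
  return out;
}
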