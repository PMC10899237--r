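#include <Rcpp.h>
using namespace Rcpp;

// Orthographic z rasterization of a triangle mesh onto a regular grid.
// Grid pixel (i, j) (1-based in R) is centred at
//   x = x0 + (i - 0.5) * pitch,  y = y0 + (j - 0.5) * pitch.
// front = true keeps the maximum z per pixel (surface nearest a viewer at
// +infinity on the z axis), front = false the minimum z.
// Returns an nx x ny matrix with NA where no triangle covers the pixel.
// [[Rcpp::export(name = ".cpp_rasterize_depth")]]
NumericMatrix cpp_rasterize_depth(NumericMatrix V, IntegerMatrix F,
                                  int nx, int ny,
                                  double x0, double y0, double pitch,
                                  bool front) {
  NumericMatrix out(nx, ny);
  std::fill(out.begin(), out.end(), NA_REAL);
  const double eps = 1e-12;
  for (int f = 0; f < F.nrow(); ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    double ax = V(a, 0), ay = V(a, 1), az = V(a, 2);
    double bx = V(b, 0), by = V(b, 1), bz = V(b, 2);
    double cx = V(c, 0), cy = V(c, 1), cz = V(c, 2);
    double xmin = std::min(ax, std::min(bx, cx));
    double xmax = std::max(ax, std::max(bx, cx));
    double ymin = std::min(ay, std::min(by, cy));
    double ymax = std::max(ay, std::max(by, cy));
    int i0 = std::max(0, (int)std::floor((xmin - x0) / pitch - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((xmax - x0) / pitch - 0.5));
    int j0 = std::max(0, (int)std::floor((ymin - y0) / pitch - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((ymax - y0) / pitch - 0.5));
    if (i1 < i0 || j1 < j0) continue;
    double d = (by - cy) * (ax - cx) + (cx - bx) * (ay - cy);
    if (std::fabs(d) < eps) continue; // degenerate in projection
    for (int i = i0; i <= i1; ++i) {
      double px = x0 + (i + 0.5) * pitch;
      for (int j = j0; j <= j1; ++j) {
        double py = y0 + (j + 0.5) * pitch;
        double l1 = ((by - cy) * (px - cx) + (cx - bx) * (py - cy)) / d;
        double l2 = ((cy - ay) * (px - cx) + (ax - cx) * (py - cy)) / d;
        double l3 = 1.0 - l1 - l2;
        if (l1 < -1e-9 || l2 < -1e-9 || l3 < -1e-9) continue;
        double z = l1 * az + l2 * bz + l3 * cz;
        double cur = out(i, j);
        if (NumericMatrix::is_na(cur) ||
            (front ? z > cur : z < cur)) out(i, j) = z;
      }
    }
  }
  return out;
}

// Non-local means denoising of a single channel. Patch radius 1 (3x3),
// search window radius `sr`. h is the filtering parameter on the same
// scale as the image values.
// [[Rcpp::export(name = ".cpp_nlm")]]
NumericMatrix cpp_nlm(NumericMatrix img, double h, int sr) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const int pr = 1; // patch radius
  double h2 = h * h * (2 * pr + 1) * (2 * pr + 1);
  if (h2 <= 0) return clone(img);
  auto at = [&](int r, int c) {
    if (r < 0) r = -r;
    if (c < 0) c = -c;
    if (r >= nr) r = 2 * nr - 2 - r;
    if (c >= nc) c = 2 * nc - 2 - c;
    return img(r, c);
  };
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double wsum = 0.0, acc = 0.0;
      for (int dr = -sr; dr <= sr; ++dr) {
        for (int dc = -sr; dc <= sr; ++dc) {
          double d2 = 0.0;
          for (int pr_ = -pr; pr_ <= pr; ++pr_)
            for (int pc = -pr; pc <= pr; ++pc) {
              double diff = at(r + pr_, c + pc) -
                            at(r + dr + pr_, c + dc + pc);
              d2 += diff * diff;
            }
          double w = std::exp(-d2 / h2);
          wsum += w;
          acc += w * at(r + dr, c + dc);
        }
      }
      out(r, c) = acc / wsum;
    }
  }
  return out;
}

static inline double fade(double t) {
  return t * t * t * (t * (t * 6 - 15) + 10);
}
static inline double lerp_(double a, double b, double t) {
  return a + t * (b - a);
}
static inline double grad3(int hash, double x, double y, double z) {
  int h = hash & 15;
  double u = h < 8 ? x : y;
  double v = h < 4 ? y : (h == 12 || h == 14 ? x : z);
  return ((h & 1) ? -u : u) + ((h & 2) ? -v : v);
}

// Classic 3D Perlin gradient noise with a seed-shuffled permutation table.
// Vectorized over sample points; values roughly in [-1, 1].
// [[Rcpp::export(name = ".cpp_perlin3")]]
NumericVector cpp_perlin3(NumericVector x, NumericVector y, NumericVector z,
                          int seed) {
  int perm[512];
  int p[256];
  for (int i = 0; i < 256; ++i) p[i] = i;
  // deterministic LCG Fisher-Yates shuffle
  unsigned int s = (unsigned int)seed * 747796405u + 2891336453u;
  for (int i = 255; i > 0; --i) {
    s = s * 1664525u + 1013904223u;
    int j = s % (i + 1);
    std::swap(p[i], p[j]);
  }
  for (int i = 0; i < 512; ++i) perm[i] = p[i & 255];

  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double xf = x[i], yf = y[i], zf = z[i];
    int X = (int)std::floor(xf) & 255;
    int Y = (int)std::floor(yf) & 255;
    int Z = (int)std::floor(zf) & 255;
    xf -= std::floor(x[i]); yf -= std::floor(y[i]); zf -= std::floor(z[i]);
    double u = fade(xf), v = fade(yf), w = fade(zf);
    int A = perm[X] + Y, AA = perm[A] + Z, AB = perm[A + 1] + Z;
    int B = perm[X + 1] + Y, BA = perm[B] + Z, BB = perm[B + 1] + Z;
    out[i] = lerp_(
      lerp_(lerp_(grad3(perm[AA], xf, yf, zf),
                  grad3(perm[BA], xf - 1, yf, zf), u),
            lerp_(grad3(perm[AB], xf, yf - 1, zf),
                  grad3(perm[BB], xf - 1, yf - 1, zf), u), v),
      lerp_(lerp_(grad3(perm[AA + 1], xf, yf, zf - 1),
                  grad3(perm[BA + 1], xf - 1, yf, zf - 1), u),
            lerp_(grad3(perm[AB + 1], xf, yf - 1, zf - 1),
                  grad3(perm[BB + 1], xf - 1, yf - 1, zf - 1), u), v),
      w);
  }
  return out;
}
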