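// Low-level 3-D volume primitives: trilinear rigid resampling, joint-histogram
// mutual information, seeded region growing, connected-component labelling,
// binary morphology with a spherical element, per-slice hole filling and
// block-mean downsampling.  All arrays are R column-major 3-D arrays; voxel
// (i,j,k) (1-based in R) maps to linear index (i-1) + (j-1)*d0 + (k-1)*d0*d1.
// Physical coordinate of a voxel is (index - 1) * spacing, no origin offset.

#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t lin(int i, int j, int k, const int* d) {
  return (R_xlen_t)i + (R_xlen_t)j * d[0] + (R_xlen_t)k * d[0] * d[1];
}

// Trilinear interpolation at continuous 0-based index (x,y,z).
// Valid only when all eight neighbours lie inside the grid.
static inline double trilinear(const double* v, const int* d,
                               double x, double y, double z, bool& ok) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > d[0] - 1.0 || y > d[1] - 1.0 || z > d[2] - 1.0) {
    ok = false;
    return 0.0;
  }
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == d[0] - 1) x0--;
  if (y0 == d[1] - 1) y0--;
  if (z0 == d[2] - 1) z0--;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const double* p = v;
  double c00 = p[lin(x0, y0, z0, d)] * (1 - fx) + p[lin(x0 + 1, y0, z0, d)] * fx;
  double c10 = p[lin(x0, y0 + 1, z0, d)] * (1 - fx) + p[lin(x0 + 1, y0 + 1, z0, d)] * fx;
  double c01 = p[lin(x0, y0, z0 + 1, d)] * (1 - fx) + p[lin(x0 + 1, y0, z0 + 1, d)] * fx;
  double c11 = p[lin(x0, y0 + 1, z0 + 1, d)] * (1 - fx) + p[lin(x0 + 1, y0 + 1, z0 + 1, d)] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  ok = true;
  return c0 * (1 - fz) + c1 * fz;
}

// Resample `mov` onto a reference grid.  M is the 4x4 homogeneous matrix
// mapping reference physical coordinates into moving physical coordinates.
// [[Rcpp::export]]
List cpp_resample_rigid(NumericVector mov, IntegerVector mdim, NumericVector mspacing,
                        NumericMatrix M, IntegerVector rdim, NumericVector rspacing,
                        double fill) {
  const int md[3] = {mdim[0], mdim[1], mdim[2]};
  const int rd[3] = {rdim[0], rdim[1], rdim[2]};
  R_xlen_t n = (R_xlen_t)rd[0] * rd[1] * rd[2];
  NumericVector out(n);
  LogicalVector valid(n);
  const double* mv = REAL(mov);
  double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2), m03 = M(0, 3);
  double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2), m13 = M(1, 3);
  double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2), m23 = M(2, 3);
  R_xlen_t idx = 0;
  for (int k = 0; k < rd[2]; k++) {
    double pz = k * rspacing[2];
    for (int j = 0; j < rd[1]; j++) {
      double py = j * rspacing[1];
      for (int i = 0; i < rd[0]; i++, idx++) {
        double px = i * rspacing[0];
        double qx = m00 * px + m01 * py + m02 * pz + m03;
        double qy = m10 * px + m11 * py + m12 * pz + m13;
        double qz = m20 * px + m21 * py + m22 * pz + m23;
        bool ok;
        double val = trilinear(mv, md, qx / mspacing[0], qy / mspacing[1],
                               qz / mspacing[2], ok);
        out[idx] = ok ? val : fill;
        valid[idx] = ok;
      }
    }
  }
  out.attr("dim") = rdim;
  valid.attr("dim") = rdim;
  return List::create(_["data"] = out, _["valid"] = valid);
}

// Mutual information (nats) between `fixed` and `mov` resampled through M
// (fixed physical -> moving physical), from a bins x bins joint histogram.
// Intensities are min/max normalized per volume using the supplied ranges.
// [[Rcpp::export]]
List cpp_mi_rigid(NumericVector fixed, IntegerVector fdim, NumericVector fspacing,
                  NumericVector mov, IntegerVector mdim, NumericVector mspacing,
                  NumericMatrix M, int bins,
                  double fmin, double fmax, double mmin, double mmax) {
  const int fd[3] = {fdim[0], fdim[1], fdim[2]};
  const int md[3] = {mdim[0], mdim[1], mdim[2]};
  const double* fv = REAL(fixed);
  const double* mv = REAL(mov);
  std::vector<double> hist((size_t)bins * bins, 0.0);
  double fscale = (fmax > fmin) ? (bins / (fmax - fmin)) : 0.0;
  double mscale = (mmax > mmin) ? (bins / (mmax - mmin)) : 0.0;
  double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2), m03 = M(0, 3);
  double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2), m13 = M(1, 3);
  double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2), m23 = M(2, 3);
  R_xlen_t idx = 0, nval = 0;
  for (int k = 0; k < fd[2]; k++) {
    double pz = k * fspacing[2];
    for (int j = 0; j < fd[1]; j++) {
      double py = j * fspacing[1];
      for (int i = 0; i < fd[0]; i++, idx++) {
        double px = i * fspacing[0];
        double qx = m00 * px + m01 * py + m02 * pz + m03;
        double qy = m10 * px + m11 * py + m12 * pz + m13;
        double qz = m20 * px + m21 * py + m22 * pz + m23;
        bool ok;
        double val = trilinear(mv, md, qx / mspacing[0], qy / mspacing[1],
                               qz / mspacing[2], ok);
        if (!ok) continue;
        int bf = (int)((fv[idx] - fmin) * fscale);
        int bm = (int)((val - mmin) * mscale);
        if (bf < 0) bf = 0; if (bf >= bins) bf = bins - 1;
        if (bm < 0) bm = 0; if (bm >= bins) bm = bins - 1;
        hist[(size_t)bf + (size_t)bins * bm] += 1.0;
        nval++;
      }
    }
  }
  if (nval == 0)
    return List::create(_["mi"] = NA_REAL, _["n"] = 0);
  std::vector<double> pf(bins, 0.0), pm(bins, 0.0);
  double nd = (double)nval;
  for (int b = 0; b < bins; b++)
    for (int c = 0; c < bins; c++) {
      double p = hist[(size_t)b + (size_t)bins * c] / nd;
      pf[b] += p;
      pm[c] += p;
    }
  double mi = 0.0;
  for (int b = 0; b < bins; b++)
    for (int c = 0; c < bins; c++) {
      double p = hist[(size_t)b + (size_t)bins * c] / nd;
      if (p > 0.0) mi += p * std::log(p / (pf[b] * pm[c]));
    }
  if (mi < 0.0) mi = 0.0;  // guard rounding
  return List::create(_["mi"] = mi, _["n"] = (double)nval);
}

// Seeded region growing (6-connectivity) over lo <= v <= hi, optionally
// restricted to `allowed` (length-0 to disable the restriction).
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dim, IntegerVector seed,
                              double lo, double hi, LogicalVector allowed) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  bool restrict_ = allowed.size() > 0;
  const double* v = REAL(vol);
  LogicalVector mask(n);
  int si = seed[0] - 1, sj = seed[1] - 1, sk = seed[2] - 1;
  if (si < 0 || sj < 0 || sk < 0 || si >= d[0] || sj >= d[1] || sk >= d[2])
    stop("seed outside the volume");
  R_xlen_t s = lin(si, sj, sk, d);
  if (v[s] < lo || v[s] > hi || (restrict_ && !allowed[s])) return mask;
  std::queue<R_xlen_t> q;
  mask[s] = TRUE;
  q.push(s);
  const R_xlen_t strides[3] = {1, d[0], (R_xlen_t)d[0] * d[1]};
  while (!q.empty()) {
    R_xlen_t c = q.front();
    q.pop();
    int ci = (int)(c % d[0]);
    int cj = (int)((c / d[0]) % d[1]);
    int ck = (int)(c / ((R_xlen_t)d[0] * d[1]));
    int coord[3] = {ci, cj, ck};
    for (int ax = 0; ax < 3; ax++) {
      for (int dir = -1; dir <= 1; dir += 2) {
        int cc = coord[ax] + dir;
        if (cc < 0 || cc >= d[ax]) continue;
        R_xlen_t nb = c + dir * strides[ax];
        if (mask[nb]) continue;
        if (v[nb] < lo || v[nb] > hi) continue;
        if (restrict_ && !allowed[nb]) continue;
        mask[nb] = TRUE;
        q.push(nb);
      }
    }
  }
  mask.attr("dim") = dim;
  return mask;
}

// 6-connected component labelling of a binary mask; labels 1..K, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  IntegerVector lab(n);
  const R_xlen_t strides[3] = {1, d[0], (R_xlen_t)d[0] * d[1]};
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t c = q.front();
      q.pop();
      int ci = (int)(c % d[0]);
      int cj = (int)((c / d[0]) % d[1]);
      int ck = (int)(c / ((R_xlen_t)d[0] * d[1]));
      int coord[3] = {ci, cj, ck};
      for (int ax = 0; ax < 3; ax++)
        for (int dir = -1; dir <= 1; dir += 2) {
          int cc = coord[ax] + dir;
          if (cc < 0 || cc >= d[ax]) continue;
          R_xlen_t nb = c + dir * strides[ax];
          if (mask[nb] && lab[nb] == 0) {
            lab[nb] = next;
            q.push(nb);
          }
        }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

static LogicalVector morph(LogicalVector mask, IntegerVector dim, double radius,
                           bool dilate) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  int r = (int)std::floor(radius);
  std::vector<int> off;
  for (int dz = -r; dz <= r; dz++)
    for (int dy = -r; dy <= r; dy++)
      for (int dx = -r; dx <= r; dx++)
        if (dx * dx + dy * dy + dz * dz <= radius * radius) {
          off.push_back(dx);
          off.push_back(dy);
          off.push_back(dz);
        }
  LogicalVector out(n);
  for (int k = 0; k < d[2]; k++)
    for (int j = 0; j < d[1]; j++)
      for (int i = 0; i < d[0]; i++) {
        R_xlen_t c = lin(i, j, k, d);
        bool hit = dilate ? false : true;
        for (size_t o = 0; o < off.size(); o += 3) {
          int ii = i + off[o], jj = j + off[o + 1], kk = k + off[o + 2];
          bool inside = ii >= 0 && jj >= 0 && kk >= 0 &&
                        ii < d[0] && jj < d[1] && kk < d[2];
          bool val = inside ? (bool)mask[lin(ii, jj, kk, d)] : false;
          if (dilate) {
            if (val) { hit = true; break; }
          } else {
            if (!val) { hit = false; break; }
          }
        }
        out[c] = hit;
      }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_binary_dilate(LogicalVector mask, IntegerVector dim, double radius) {
  return morph(mask, dim, radius, true);
}

// [[Rcpp::export]]
LogicalVector cpp_binary_erode(LogicalVector mask, IntegerVector dim, double radius) {
  return morph(mask, dim, radius, false);
}

// Fill in-plane holes slice by slice along the first (axial) array axis:
// background connected (4-connectivity) to the slice border stays background,
// enclosed background becomes foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_slices(LogicalVector mask, IntegerVector dim) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  LogicalVector out = clone(mask);
  std::vector<char> reach((size_t)d[1] * d[2]);
  for (int i = 0; i < d[0]; i++) {
    std::fill(reach.begin(), reach.end(), 0);
    std::queue<int> q;
    for (int k = 0; k < d[2]; k++)
      for (int j = 0; j < d[1]; j++) {
        bool border = (j == 0 || k == 0 || j == d[1] - 1 || k == d[2] - 1);
        if (!border) continue;
        if (!mask[lin(i, j, k, d)] && !reach[j + (size_t)d[1] * k]) {
          reach[j + (size_t)d[1] * k] = 1;
          q.push(j + d[1] * k);
        }
      }
    while (!q.empty()) {
      int c = q.front();
      q.pop();
      int j = c % d[1], k = c / d[1];
      const int dj[4] = {1, -1, 0, 0};
      const int dk[4] = {0, 0, 1, -1};
      for (int t = 0; t < 4; t++) {
        int jj = j + dj[t], kk = k + dk[t];
        if (jj < 0 || kk < 0 || jj >= d[1] || kk >= d[2]) continue;
        size_t rc = jj + (size_t)d[1] * kk;
        if (reach[rc] || mask[lin(i, jj, kk, d)]) continue;
        reach[rc] = 1;
        q.push(jj + d[1] * kk);
      }
    }
    for (int k = 0; k < d[2]; k++)
      for (int j = 0; j < d[1]; j++)
        if (!mask[lin(i, j, k, d)] && !reach[j + (size_t)d[1] * k])
          out[lin(i, j, k, d)] = TRUE;
  }
  out.attr("dim") = dim;
  return out;
}

// Block-mean downsampling by an integer factor (partial edge blocks averaged).
// [[Rcpp::export]]
List cpp_downsample(NumericVector vol, IntegerVector dim, int factor) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  int od[3];
  for (int a = 0; a < 3; a++) od[a] = (d[a] + factor - 1) / factor;
  R_xlen_t n = (R_xlen_t)od[0] * od[1] * od[2];
  NumericVector out(n);
  const double* v = REAL(vol);
  for (int k = 0; k < od[2]; k++)
    for (int j = 0; j < od[1]; j++)
      for (int i = 0; i < od[0]; i++) {
        double s = 0.0;
        int cnt = 0;
        for (int kk = k * factor; kk < std::min((k + 1) * factor, d[2]); kk++)
          for (int jj = j * factor; jj < std::min((j + 1) * factor, d[1]); jj++)
            for (int ii = i * factor; ii < std::min((i + 1) * factor, d[0]); ii++) {
              s += v[lin(ii, jj, kk, d)];
              cnt++;
            }
        out[lin(i, j, k, od)] = s / cnt;
      }
  out.attr("dim") = IntegerVector::create(od[0], od[1], od[2]);
  return List::create(_["data"] = out,
                      _["dim"] = IntegerVector::create(od[0], od[1], od[2]));
}
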