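// Per-voxel descriptor hot loop: block statistics, directional absolute
// differences, and GLCM Haralick properties over 13 3D directions for every
// VOI voxel. Definitions mirror the scalar R implementations in R/features.R,
// which serve as the independent oracle in the test suite.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericMatrix cpp_extract_features(NumericVector vol, IntegerVector quant,
                                   IntegerMatrix vox0, IntegerMatrix dirs,
                                   int n_levels, int half, int agg_code) {
  IntegerVector dims = vol.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nv = vox0.nrow(), nd = dirs.nrow();
  const int ncol = 5 + 4 * nd;
  NumericMatrix out(nv, ncol);
  const double *I = REAL(vol);
  const int *Q = INTEGER(quant);
  const long sxy = (long)nx * ny;

  std::vector<double> P((size_t)n_levels * n_levels);
  std::vector<double> px(n_levels), py(n_levels);

  for (int v = 0; v < nv; ++v) {
    const int cx = vox0(v, 0), cy = vox0(v, 1), cz = vox0(v, 2);
    const long cidx = cx + (long)cy * nx + (long)cz * sxy;

    // feature 1: normalized intensity at the voxel
    out(v, 0) = I[cidx];

    // block bounds, cropped to the volume
    const int x0 = std::max(0, cx - half), x1 = std::min(nx - 1, cx + half);
    const int y0 = std::max(0, cy - half), y1 = std::min(ny - 1, cy + half);
    const int z0 = std::max(0, cz - half), z1 = std::min(nz - 1, cz + half);

    // features 2-3: block mean and population std
    double s = 0, s2 = 0; long n = 0;
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          const double val = I[x + (long)y * nx + (long)z * sxy];
          s += val; s2 += val * val; ++n;
        }
    const double m = s / n;
    out(v, 1) = m;
    double var = s2 / n - m * m;
    out(v, 2) = var > 0 ? std::sqrt(var) : 0.0;

    // features 4-5: directional absolute differences, steps 1 and 2
    const double v0 = I[cidx];
    for (int step = 1; step <= 2; ++step) {
      double acc = (agg_code == 1) ? 0.0 : 0.0;
      double mx = 0.0, sum = 0.0;
      for (int d = 0; d < nd; ++d) {
        const int xx = clampi(cx + step * dirs(d, 0), 0, nx - 1);
        const int yy = clampi(cy + step * dirs(d, 1), 0, ny - 1);
        const int zz = clampi(cz + step * dirs(d, 2), 0, nz - 1);
        const double diff = std::fabs(v0 - I[xx + (long)yy * nx + (long)zz * sxy]);
        sum += diff;
        if (diff > mx) mx = diff;
      }
      if (agg_code == 0) acc = sum / nd;       // mean
      else if (agg_code == 1) acc = mx;        // max
      else acc = sum;                          // sum
      out(v, 2 + step) = acc;
    }

    // features 6..57: GLCM contrast / correlation / energy / homogeneity
    for (int d = 0; d < nd; ++d) {
      const int dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
      std::fill(P.begin(), P.end(), 0.0);
      double tot = 0.0;
      for (int z = z0; z <= z1; ++z)
        for (int y = y0; y <= y1; ++y)
          for (int x = x0; x <= x1; ++x) {
            const int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < x0 || xx > x1 || yy < y0 || yy > y1 || zz < z0 || zz > z1)
              continue;
            const int l1 = Q[x + (long)y * nx + (long)z * sxy];
            const int l2 = Q[xx + (long)yy * nx + (long)zz * sxy];
            P[l1 * n_levels + l2] += 1.0;
            P[l2 * n_levels + l1] += 1.0;
            tot += 2.0;
          }
      double contrast = 0, corr = 0, energy = 0, homog = 0;
      if (tot > 0) {
        std::fill(px.begin(), px.end(), 0.0);
        std::fill(py.begin(), py.end(), 0.0);
        for (int a = 0; a < n_levels; ++a)
          for (int b = 0; b < n_levels; ++b) {
            const double p = P[a * n_levels + b] / tot;
            P[a * n_levels + b] = p;
            px[a] += p; py[b] += p;
            contrast += p * (a - b) * (a - b);
            energy += p * p;
            homog += p / (1.0 + std::abs(a - b));
          }
        double mux = 0, muy = 0;
        for (int a = 0; a < n_levels; ++a) { mux += a * px[a]; muy += a * py[a]; }
        double sx2 = 0, sy2 = 0;
        for (int a = 0; a < n_levels; ++a) {
          sx2 += (a - mux) * (a - mux) * px[a];
          sy2 += (a - muy) * (a - muy) * py[a];
        }
        const double sxsy = std::sqrt(sx2) * std::sqrt(sy2);
        if (sxsy > 0) {
          double cov = 0;
          for (int a = 0; a < n_levels; ++a)
            for (int b = 0; b < n_levels; ++b)
              cov += (a - mux) * (b - muy) * P[a * n_levels + b];
          corr = cov / sxsy;
        }
      }
      out(v, 5 + d) = contrast;
      out(v, 5 + nd + d) = corr;
      out(v, 5 + 2 * nd + d) = energy;
      out(v, 5 + 3 * nd + d) = homog;
    }
  }
  return out;
}
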