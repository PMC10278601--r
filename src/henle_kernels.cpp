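#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Conventions shared with the R layer:
//  - en-face maps are matrices [row = y, col = x];
//  - xdeg / ydeg hold pixel-centre coordinates in degrees (monotone increasing);
//  - azimuth phi = atan2(-dx, cy - y), measured from the upward vertical
//    through the fovea centre, counterclockwise, in [0, 360);
//  - eccentricity is computed in degree space (pixels are anisotropic).

static inline int first_ge(const NumericVector& v, double x) {
  return static_cast<int>(std::lower_bound(v.begin(), v.end(), x) - v.begin());
}

// Accumulate per-segment sums of a complex field Z = (re, im) over the annulus
// rin <= ecc < rout around (cx, cy) (all in degrees).
static void seg_accumulate(const NumericMatrix& re, const NumericMatrix& im,
                           const LogicalMatrix& valid,
                           const NumericVector& xdeg, const NumericVector& ydeg,
                           double cx, double cy, double rin, double rout,
                           int nseg, double* sr, double* si, int* n) {
  const int ny = re.nrow(), nx = re.ncol();
  std::fill(sr, sr + nseg, 0.0);
  std::fill(si, si + nseg, 0.0);
  std::fill(n, n + nseg, 0);
  const int r0 = first_ge(ydeg, cy - rout);
  const int c0 = first_ge(xdeg, cx - rout);
  for (int r = r0; r < ny && ydeg[r] <= cy + rout; ++r) {
    const double dyup = cy - ydeg[r];
    for (int c = c0; c < nx && xdeg[c] <= cx + rout; ++c) {
      if (!valid(r, c)) continue;
      const double dx = xdeg[c] - cx;
      const double ecc = std::sqrt(dx * dx + dyup * dyup);
      if (ecc < rin || ecc >= rout) continue;
      const double zr = re(r, c), zi = im(r, c);
      if (!R_finite(zr) || !R_finite(zi)) continue;
      double phi = std::atan2(-dx, dyup) * (180.0 / M_PI);
      if (phi < 0) phi += 360.0;
      int s = static_cast<int>(std::floor(phi * nseg / 360.0));
      if (s >= nseg) s = nseg - 1;
      if (s < 0) s = 0;
      sr[s] += zr;
      si[s] += zi;
      ++n[s];
    }
  }
}

static double md_from_sums(const double* sr, const double* si, const int* n,
                           const NumericVector& idealRe, const NumericVector& idealIm,
                           int nseg, double minFrac) {
  int used = 0;
  double acc = 0.0;
  for (int s = 0; s < nseg; ++s) {
    if (n[s] == 0) continue;
    const double mr = sr[s] / n[s], mi = si[s] / n[s];
    acc += std::fabs(mr - idealRe[s]) + std::fabs(mi - idealIm[s]);
    ++used;
  }
  if (used == 0 || used < minFrac * nseg) return NA_REAL;
  return acc / used;
}

// [[Rcpp::export(name = ".segment_sums_cpp")]]
List segment_sums_cpp(NumericMatrix re, NumericMatrix im, LogicalMatrix valid,
                      NumericVector xdeg, NumericVector ydeg,
                      double cx, double cy, double rin, double rout, int nseg) {
  std::vector<double> sr(nseg), si(nseg);
  std::vector<int> n(nseg);
  seg_accumulate(re, im, valid, xdeg, ydeg, cx, cy, rin, rout, nseg,
                 sr.data(), si.data(), n.data());
  return List::create(_["sumRe"] = NumericVector(sr.begin(), sr.end()),
                      _["sumIm"] = NumericVector(si.begin(), si.end()),
                      _["n"] = IntegerVector(n.begin(), n.end()));
}

// MD for every candidate centre pixel in a (2*half+1)^2 window around the
// pixel (cxpx, cypx) (1-based column / row indices). Entry [dy+half, dx+half]
// (1-based) is the MD with the centre displaced by (dx, dy) pixels; candidates
// falling outside the grid, or annuli with too few populated segments, give NA.
// [[Rcpp::export(name = ".window_md_cpp")]]
NumericMatrix window_md_cpp(NumericMatrix re, NumericMatrix im, LogicalMatrix valid,
                            NumericVector xdeg, NumericVector ydeg,
                            int cxpx, int cypx, int half,
                            double rin, double rout, int nseg,
                            NumericVector idealRe, NumericVector idealIm,
                            double minFrac) {
  const int ny = re.nrow(), nx = re.ncol();
  const int w = 2 * half + 1;
  NumericMatrix out(w, w);
  std::vector<double> sr(nseg), si(nseg);
  std::vector<int> n(nseg);
  for (int dy = -half; dy <= half; ++dy) {
    for (int dx = -half; dx <= half; ++dx) {
      const int r = cypx - 1 + dy, c = cxpx - 1 + dx;
      if (r < 0 || r >= ny || c < 0 || c >= nx) {
        out(dy + half, dx + half) = NA_REAL;
        continue;
      }
      seg_accumulate(re, im, valid, xdeg, ydeg, xdeg[c], ydeg[r],
                     rin, rout, nseg, sr.data(), si.data(), n.data());
      out(dy + half, dx + half) =
          md_from_sums(sr.data(), si.data(), n.data(), idealRe, idealIm, nseg, minFrac);
    }
  }
  return out;
}
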