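#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Conventions (shared with the R side, see ?angles):
//  - matrices are indexed [row, col]; internally 0-based here;
//  - a direction angle phi (degrees) has unit vector
//      d_row = -sin(phi), d_col = +cos(phi)
//    i.e. 0 deg points along +col and positive angles turn counter-clockwise
//    on screen (rows increase downward);
//  - orientations are 180-degree periodic and reported in (-90, 90].
//
// Sampling semantics: a sample at fractional offset (dr, dc) from pixel
// (i, j) is in bounds iff (i+dr, j+dc) lies in [0, nr-1] x [0, nc-1];
// in-bounds samples are bilinearly interpolated, out-of-bounds samples are
// dropped. Because the fractional part of the offset is constant across
// pixels for a fixed (angle, t), each (angle, t) contributes a constant
// 4-tap stencil applied over a rectangular valid region, which is how the
// loops below are organized.

static const double DEG = M_PI / 180.0;

// Angle grid covering (-90, 90] in steps of `step` degrees, visited in order
// of increasing |angle| (ties: the more negative angle first) so that a
// strict `>` update implements the smallest-|angle| tie-break.
static std::vector<double> angle_grid_ordered(double step) {
  int k = (int)std::floor(180.0 / step + 1e-9);
  std::vector<double> ang(k);
  for (int j = 0; j < k; j++) ang[j] = -90.0 + step * (j + 1);
  std::sort(ang.begin(), ang.end(), [](double a, double b) {
    double fa = std::fabs(a), fb = std::fabs(b);
    if (fa != fb) return fa < fb;
    return a < b;
  });
  return ang;
}

struct Stencil {
  int i0, j0;      // integer part of the offset
  int er, ec;      // 1 when a second row/col tap is needed
  double w00, w01, w10, w11;
  int ilo, ihi, jlo, jhi;  // valid base-pixel range (inclusive)
  bool empty;
};

// Snap an offset to an exact half-integer when within 1e-9 of one.
// Grid-angle offsets like t*sin(30 deg) vs t*cos(60 deg) differ by one ulp
// around .5; without snapping, rotation-partner angles would sample
// different neighbors. Exact halves then round away from zero (lround).
static inline double snap_half(double x) {
  double y = std::round(2.0 * x) / 2.0;
  return std::fabs(x - y) < 1e-9 ? y : x;
}

static Stencil make_stencil(double dr, double dc, int nr, int nc) {
  Stencil s;
  dr = snap_half(dr);
  dc = snap_half(dc);
  double fi = std::floor(dr), fj = std::floor(dc);
  s.i0 = (int)fi;
  s.j0 = (int)fj;
  double fr = dr - fi, fc = dc - fj;
  // snap near-integer offsets so exact-boundary samples use one tap
  if (fr < 1e-12) fr = 0.0;
  if (fr > 1 - 1e-12) { fr = 0.0; s.i0 += 1; }
  if (fc < 1e-12) fc = 0.0;
  if (fc > 1 - 1e-12) { fc = 0.0; s.j0 += 1; }
  s.er = fr > 0.0 ? 1 : 0;
  s.ec = fc > 0.0 ? 1 : 0;
  s.w00 = (1 - fr) * (1 - fc);
  s.w01 = (1 - fr) * fc;
  s.w10 = fr * (1 - fc);
  s.w11 = fr * fc;
  s.ilo = std::max(0, -s.i0);
  s.ihi = std::min(nr - 1, nr - 1 - s.er - s.i0);
  s.jlo = std::max(0, -s.j0);
  s.jhi = std::min(nc - 1, nc - 1 - s.ec - s.j0);
  s.empty = s.ilo > s.ihi || s.jlo > s.jhi;
  return s;
}

// Line filter transform: per pixel, the maximum over swept angles of the
// mean image intensity sampled along a segment of half-length r (unit
// steps, bilinear interpolation, out-of-bounds samples dropped and the
// mean renormalized by the in-bounds count).
// [[Rcpp::export]]
List lft_cpp(NumericMatrix img, int r, double angle_step) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<double> ang = angle_grid_ordered(angle_step);
  NumericMatrix intensity(nr, nc), orientation(nr, nc);
  std::fill(intensity.begin(), intensity.end(), R_NegInf);
  std::vector<double> acc((size_t)nr * nc), cnt((size_t)nr * nc);
  const double* I = img.begin();
  for (double a : ang) {
    double sn = std::sin(a * DEG), cs = std::cos(a * DEG);
    std::fill(acc.begin(), acc.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int t = -r; t <= r; t++) {
      Stencil s = make_stencil(-t * sn, t * cs, nr, nc);
      if (s.empty) continue;
      for (int j = s.jlo; j <= s.jhi; j++) {
        const double* c00 = I + (size_t)(j + s.j0) * nr + s.i0;
        const double* c01 = I + (size_t)(j + s.j0 + s.ec) * nr + s.i0;
        const double* c10 = c00 + s.er;
        const double* c11 = c01 + s.er;
        double* A = acc.data() + (size_t)j * nr;
        double* C = cnt.data() + (size_t)j * nr;
        for (int i = s.ilo; i <= s.ihi; i++) {
          A[i] += s.w00 * c00[i] + s.w01 * c01[i] + s.w10 * c10[i] +
                  s.w11 * c11[i];
          C[i] += 1.0;
        }
      }
    }
    double* Mv = intensity.begin();
    double* Ov = orientation.begin();
    for (size_t k = 0; k < (size_t)nr * nc; k++) {
      double m = acc[k] / cnt[k];  // cnt >= 1: t = 0 is always in bounds
      // angles are visited in order of |angle|, so refusing near-tie
      // updates implements the smallest-|angle| tie-break
      if (Mv[k] == R_NegInf ||
          m > Mv[k] + 1e-9 * (1.0 + std::fabs(Mv[k]))) {
        Mv[k] = m;
        Ov[k] = a;
      }
    }
  }
  return List::create(_["intensity"] = intensity,
                      _["orientation"] = orientation);
}

// Orientation filter transform. Each neighbor sample along a probe angle
// alpha contributes rho * cos(2 * (theta - alpha)), rho interpolated
// bilinearly and theta taken at the nearest pixel. alpha_max maximizes
// |sum| over the angle grid (ties toward the smallest |alpha|); the signed
// sum at alpha_max is stored.
// [[Rcpp::export]]
List oft_cpp(NumericMatrix intensity, NumericMatrix orientation, int r,
             double angle_step) {
  int nr = intensity.nrow(), nc = intensity.ncol();
  size_t n = (size_t)nr * nc;
  std::vector<double> ang = angle_grid_ordered(angle_step);
  // cos(2(theta - alpha)) = cos2theta*cos2alpha + sin2theta*sin2alpha
  std::vector<double> c2t(n), s2t(n);
  for (size_t k = 0; k < n; k++) {
    c2t[k] = std::cos(2.0 * orientation[k] * DEG);
    s2t[k] = std::sin(2.0 * orientation[k] * DEG);
  }
  NumericMatrix oft(nr, nc), alpha(nr, nc);
  std::vector<double> best_abs(n, -1.0), acc(n);
  const double* R0 = intensity.begin();
  for (double a : ang) {
    double sn = std::sin(a * DEG), cs = std::cos(a * DEG);
    double c2a = std::cos(2.0 * a * DEG), s2a = std::sin(2.0 * a * DEG);
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int t = -r; t <= r; t++) {
      double dr = snap_half(-t * sn), dc = snap_half(t * cs);
      Stencil s = make_stencil(dr, dc, nr, nc);
      if (s.empty) continue;
      int ri = (int)std::lround(dr), cj = (int)std::lround(dc);
      for (int j = s.jlo; j <= s.jhi; j++) {
        const double* c00 = R0 + (size_t)(j + s.j0) * nr + s.i0;
        const double* c01 = R0 + (size_t)(j + s.j0 + s.ec) * nr + s.i0;
        const double* c10 = c00 + s.er;
        const double* c11 = c01 + s.er;
        const double* ct = c2t.data() + (size_t)(j + cj) * nr + ri;
        const double* st = s2t.data() + (size_t)(j + cj) * nr + ri;
        double* A = acc.data() + (size_t)j * nr;
        for (int i = s.ilo; i <= s.ihi; i++) {
          double rho = s.w00 * c00[i] + s.w01 * c01[i] + s.w10 * c10[i] +
                       s.w11 * c11[i];
          A[i] += rho * (c2a * ct[i] + s2a * st[i]);
        }
      }
    }
    double* Sv = oft.begin();
    double* Av = alpha.begin();
    for (size_t k = 0; k < n; k++) {
      double ab = std::fabs(acc[k]);
      if (ab > best_abs[k] + 1e-9 * (1.0 + best_abs[k])) {
        best_abs[k] = ab;
        Sv[k] = acc[k];
        Av[k] = a;
      }
    }
  }
  return List::create(_["oft"] = oft, _["alpha"] = alpha);
}

// Zhang-Suen thinning of a binary mask followed by staircase pruning: a
// pixel with >= 2 neighbors whose neighbors form a single 8-connected
// component (within the 3x3 box) is redundant for connectivity and is
// removed, yielding a minimally 8-thin skeleton.
// [[Rcpp::export]]
IntegerMatrix thin_cpp(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img(clone(mask));
  auto at = [&](int i, int j) -> int {
    if (i < 0 || j < 0 || i >= nr || j >= nc) return 0;
    return img(i, j) != 0;
  };
  bool changed = true;
  std::vector<std::pair<int, int>> kill;
  while (changed) {
    changed = false;
    for (int phase = 0; phase < 2; phase++) {
      kill.clear();
      for (int i = 0; i < nr; i++) {
        for (int j = 0; j < nc; j++) {
          if (!img(i, j)) continue;
          // neighbors p2..p9 clockwise from north
          int p2 = at(i - 1, j), p3 = at(i - 1, j + 1), p4 = at(i, j + 1),
              p5 = at(i + 1, j + 1), p6 = at(i + 1, j), p7 = at(i + 1, j - 1),
              p8 = at(i, j - 1), p9 = at(i - 1, j - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int aTrans = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                       (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                       (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                       (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (aTrans != 1) continue;
          if (phase == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back({i, j});
        }
      }
      for (auto& p : kill) img(p.first, p.second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  // staircase pruning (sequential, to a fixed point)
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  changed = true;
  while (changed) {
    changed = false;
    for (int i = 0; i < nr; i++) {
      for (int j = 0; j < nc; j++) {
        if (!img(i, j)) continue;
        int ni[8], nj[8], b = 0;
        for (int k = 0; k < 8; k++) {
          if (at(i + di[k], j + dj[k])) {
            ni[b] = di[k];
            nj[b] = dj[k];
            b++;
          }
        }
        if (b < 2) continue;
        // count 8-connected components among the neighbor pixels
        int comp[8];
        for (int k = 0; k < b; k++) comp[k] = k;
        for (int k = 0; k < b; k++) {
          for (int l = k + 1; l < b; l++) {
            if (std::abs(ni[k] - ni[l]) <= 1 && std::abs(nj[k] - nj[l]) <= 1) {
              int ck = comp[k], cl = comp[l];
              if (ck != cl) {
                for (int m = 0; m < b; m++) {
                  if (comp[m] == cl) comp[m] = ck;
                }
              }
            }
          }
        }
        int ncomp = 0;
        for (int k = 0; k < b; k++) {
          if (comp[k] == k) ncomp++;
        }
        if (ncomp == 1) {
          img(i, j) = 0;
          changed = true;
        }
      }
    }
  }
  return img;
}
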