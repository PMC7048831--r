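#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// ---- helpers ----------------------------------------------------------------

// whole-sample reflection of index i into [0, n-1]
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i = i % period;
  if (i < 0) i += period;
  if (i >= n) i = period - i;
  return i;
}

static inline double tri_area(double x1, double y1, double z1,
                              double x2, double y2, double z2,
                              double x3, double y3, double z3) {
  double ux = x2 - x1, uy = y2 - y1, uz = z2 - z1;
  double vx = x3 - x1, vy = y3 - y1, vz = z3 - z1;
  double cx = uy * vz - uz * vy;
  double cy = uz * vx - ux * vz;
  double cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// least-squares slope of y on x
static double ls_slope(const std::vector<double>& x, const std::vector<double>& y) {
  int n = x.size();
  double mx = 0, my = 0;
  for (int i = 0; i < n; i++) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sxy = 0, sxx = 0;
  for (int i = 0; i < n; i++) { sxy += (x[i] - mx) * (y[i] - my); sxx += (x[i] - mx) * (x[i] - mx); }
  if (sxx <= 0) return NA_REAL;
  return sxy / sxx;
}

// ---- PTPSA ------------------------------------------------------------------

// Total triangular-prism surface area of a height field at corner spacing s,
// for each s in steps. Patch corners sampled at integer points spaced s;
// requires (nrow-1) and (ncol-1) divisible by s.
// [[Rcpp::export]]
NumericVector cpp_ptpsa_areas(NumericMatrix patch, IntegerVector steps) {
  int nr = patch.nrow(), nc = patch.ncol();
  NumericVector out(steps.size());
  for (int k = 0; k < steps.size(); k++) {
    int s = steps[k];
    double total = 0.0;
    for (int i = 0; i + s <= nr - 1; i += s) {
      for (int j = 0; j + s <= nc - 1; j += s) {
        double z00 = patch(i, j),     z10 = patch(i + s, j);
        double z01 = patch(i, j + s), z11 = patch(i + s, j + s);
        double zc = 0.25 * (z00 + z10 + z01 + z11);
        double h = 0.5 * s;
        double x0 = i, y0 = j;
        // four triangles: each edge of the cell with the central point
        total += tri_area(x0,     y0,     z00, x0 + s, y0,     z10, x0 + h, y0 + h, zc);
        total += tri_area(x0 + s, y0,     z10, x0 + s, y0 + s, z11, x0 + h, y0 + h, zc);
        total += tri_area(x0 + s, y0 + s, z11, x0,     y0 + s, z01, x0 + h, y0 + h, zc);
        total += tri_area(x0,     y0 + s, z01, x0,     y0,     z00, x0 + h, y0 + h, zc);
      }
    }
    out[k] = total;
  }
  return out;
}

// ---- separable 2D DWT (Daubechies 4-vanishing-moment, periodic) -------------

static const double DB4_LO[8] = {
  -0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
  -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
  0.7148465705529157, 0.2303778133088965 };
static const double DB4_HI[8] = {
  -0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
  -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
  -0.0328830116668852, -0.010597401785069032 };

// one periodic analysis step along a vector of even length n -> n/2 approx + n/2 detail
static void dwt_step(const std::vector<double>& x, std::vector<double>& lo,
                     std::vector<double>& hi) {
  int n = x.size(), nh = n / 2;
  lo.assign(nh, 0.0); hi.assign(nh, 0.0);
  for (int k = 0; k < nh; k++) {
    double a = 0, d = 0;
    for (int m = 0; m < 8; m++) {
      int idx = (2 * k + m) % n;
      a += DB4_LO[m] * x[idx];
      d += DB4_HI[m] * x[idx];
    }
    lo[k] = a; hi[k] = d;
  }
}

// Per-level variance of all detail coefficients (LH, HL, HH pooled) of a
// J-level separable periodic DWT. Input side lengths must be divisible by 2^J.
// [[Rcpp::export]]
NumericVector cpp_dwt2_detail_vars(NumericMatrix patch, int J) {
  int nr = patch.nrow(), nc = patch.ncol();
  std::vector<double> ll(patch.begin(), patch.end()); // column-major nr x nc
  NumericVector vars(J);
  int cr = nr, cc = nc;
  for (int j = 0; j < J; j++) {
    // rows transform: apply along columns index? operate along each dimension.
    // first along rows (fix column, filter down the rows)
    int hr = cr / 2;
    std::vector<double> rowlo(hr * cc), rowhi(hr * cc), x(cr), lo, hi;
    for (int c = 0; c < cc; c++) {
      for (int r = 0; r < cr; r++) x[r] = ll[r + c * cr];
      dwt_step(x, lo, hi);
      for (int r = 0; r < hr; r++) { rowlo[r + c * hr] = lo[r]; rowhi[r + c * hr] = hi[r]; }
    }
    // then along columns of both halves
    int hc = cc / 2;
    std::vector<double> LL(hr * hc), LH(hr * hc), HL(hr * hc), HH(hr * hc), y(cc);
    for (int r = 0; r < hr; r++) {
      for (int c = 0; c < cc; c++) y[c] = rowlo[r + c * hr];
      dwt_step(y, lo, hi);
      for (int c = 0; c < hc; c++) { LL[r + c * hr] = lo[c]; LH[r + c * hr] = hi[c]; }
      for (int c = 0; c < cc; c++) y[c] = rowhi[r + c * hr];
      dwt_step(y, lo, hi);
      for (int c = 0; c < hc; c++) { HL[r + c * hr] = lo[c]; HH[r + c * hr] = hi[c]; }
    }
    // pooled variance of detail coefficients at this level
    double sum = 0, sum2 = 0; int n = 3 * hr * hc;
    for (int i = 0; i < hr * hc; i++) {
      sum += LH[i] + HL[i] + HH[i];
      sum2 += LH[i] * LH[i] + HL[i] * HL[i] + HH[i] * HH[i];
    }
    double mean = sum / n;
    vars[j] = sum2 / n - mean * mean;
    ll = LL; cr = hr; cc = hc;
  }
  return vars;
}

// ---- characterization maps --------------------------------------------------

static inline int vidx(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// extract an axial (x,y) patch of side `side` centered at (cx,cy) on slice z,
// reflecting at volume boundaries
static void extract_patch(const NumericVector& vol, int nx, int ny, int z,
                          int cx, int cy, int side, NumericMatrix& patch) {
  int half = side / 2;
  for (int i = 0; i < side; i++) {
    int xi = reflect_idx(cx - half + i, nx);
    for (int j = 0; j < side; j++) {
      int yj = reflect_idx(cy - half + j, ny);
      patch(i, j) = vol[vidx(xi, yj, z, nx, ny)];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_ptpsa_map(NumericVector vol, IntegerVector dim, IntegerVector roi,
                            int window, IntegerVector steps) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  int maxs = 0;
  for (int k = 0; k < steps.size(); k++) maxs = std::max(maxs, steps[k]);
  int side = ((window - 1) / maxs) * maxs + 1; // (side-1) divisible by every power-of-two step
  NumericMatrix patch(side, side);
  std::vector<double> lx(steps.size()), ly(steps.size());
  for (int k = 0; k < steps.size(); k++) lx[k] = std::log((double)steps[k]);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int id = vidx(x, y, z, nx, ny);
        if (!roi[id]) continue;
        extract_patch(vol, nx, ny, z, x, y, side, patch);
        NumericVector A = cpp_ptpsa_areas(patch, steps);
        bool ok = true;
        for (int k = 0; k < steps.size(); k++) {
          if (A[k] <= 0) { ok = false; break; }
          ly[k] = std::log(A[k]);
        }
        double D = 2.0;
        if (ok) {
          double sl = ls_slope(lx, ly);
          if (R_finite(sl)) D = 2.0 - sl;
        }
        out[id] = std::min(3.0, std::max(2.0, D));
      }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_mbm_map(NumericVector vol, IntegerVector dim, IntegerVector roi,
                          int window, int J) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  int block = 1 << J;
  int side = (window / block) * block; // even side divisible by 2^J
  if (side < block) side = block;
  NumericMatrix patch(side, side);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int id = vidx(x, y, z, nx, ny);
        if (!roi[id]) continue;
        extract_patch(vol, nx, ny, z, x, y, side, patch);
        NumericVector V = cpp_dwt2_detail_vars(patch, J);
        double msq = 0;
        for (int i = 0; i < side * side; i++) msq += patch[i] * patch[i];
        double floorv = 1e-20 * (1 + msq / (side * side));
        std::vector<double> jx, vy;
        for (int j = 0; j < J; j++)
          if (V[j] > floorv) { jx.push_back(j + 1.0); vy.push_back(std::log2(V[j])); }
        double H;
        if ((int)jx.size() < 2) {
          H = 1.0; // degenerate (flat) patch
        } else {
          double beta = ls_slope(jx, vy);
          H = (beta - 2.0) / 2.0;
        }
        out[id] = std::min(1.0, std::max(0.0, H));
      }
  return out;
}

// oscillation (max - min) of vol within Chebyshev balls of each radius around
// each in-roi voxel; boundary handled by reflection
// [[Rcpp::export]]
NumericVector cpp_holder_map(NumericVector vol, IntegerVector dim, IntegerVector roi,
                             IntegerVector radii, double eps, double alpha_cap) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  int nr = radii.size();
  std::vector<double> lr(nr), losc(nr);
  for (int k = 0; k < nr; k++) lr[k] = std::log((double)radii[k]);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int id = vidx(x, y, z, nx, ny);
        if (!roi[id]) continue;
        bool allconst = true;
        for (int k = 0; k < nr; k++) {
          int r = radii[k];
          double mx = -1e300, mn = 1e300;
          for (int dz = -r; dz <= r; dz++) {
            int zz = reflect_idx(z + dz, nz);
            for (int dy = -r; dy <= r; dy++) {
              int yy = reflect_idx(y + dy, ny);
              for (int dx = -r; dx <= r; dx++) {
                int xx = reflect_idx(x + dx, nx);
                double v = vol[vidx(xx, yy, zz, nx, ny)];
                if (v > mx) mx = v;
                if (v < mn) mn = v;
              }
            }
          }
          double osc = mx - mn;
          if (osc >= eps) allconst = false;
          losc[k] = std::log(osc + eps);
        }
        double a;
        if (allconst) a = alpha_cap;
        else a = ls_slope(lr, losc);
        if (!R_finite(a)) a = alpha_cap;
        out[id] = std::min(alpha_cap, std::max(0.0, a));
      }
  return out;
}

// ---- gray-level texture matrices -------------------------------------------

// the 13 unique 3D direction offsets at Chebyshev distance 1
static const int OFF13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

// symmetric normalized GLCM merged over the 13 offsets; q has levels 1..Ng in
// mask, 0 outside; out-of-mask neighbors are not counted
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector q, IntegerVector dim, int Ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix M(Ng, Ng);
  double total = 0;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int a = q[vidx(x, y, z, nx, ny)];
        if (a == 0) continue;
        for (int o = 0; o < 13; o++) {
          int xx = x + OFF13[o][0], yy = y + OFF13[o][1], zz = z + OFF13[o][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          int b = q[vidx(xx, yy, zz, nx, ny)];
          if (b == 0) continue;
          M(a - 1, b - 1) += 1; M(b - 1, a - 1) += 1;
          total += 2;
        }
      }
  if (total > 0) for (int i = 0; i < Ng * Ng; i++) M[i] /= total;
  return M;
}

// run-length counts merged over 13 directions: rows = gray level, cols = run length
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector q, IntegerVector dim, int Ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxlen = std::max(nx, std::max(ny, nz));
  NumericMatrix M(Ng, maxlen);
  int maxused = 1;
  for (int o = 0; o < 13; o++) {
    int dx = OFF13[o][0], dy = OFF13[o][1], dz = OFF13[o][2];
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
          int a = q[vidx(x, y, z, nx, ny)];
          if (a == 0) continue;
          // run start: predecessor missing or different
          int px = x - dx, py = y - dy, pz = z - dz;
          bool pin = px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz;
          if (pin && q[vidx(px, py, pz, nx, ny)] == a) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz &&
                 q[vidx(cx, cy, cz, nx, ny)] == a) {
            len++; cx += dx; cy += dy; cz += dz;
          }
          M(a - 1, len - 1) += 1;
          if (len > maxused) maxused = len;
        }
  }
  return M(Range(0, Ng - 1), Range(0, maxused - 1));
}

// size-zone counts (26-connected zones of constant level): rows = level, cols = size
// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector q, IntegerVector dim, int Ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int,int> > zones; // (level, size)
  int maxsize = 1;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int id = vidx(x, y, z, nx, ny);
        int a = q[id];
        if (a == 0 || seen[id]) continue;
        int size = 0;
        std::queue<int> bfs;
        bfs.push(id); seen[id] = 1;
        while (!bfs.empty()) {
          int cur = bfs.front(); bfs.pop();
          size++;
          int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
          for (int dz = -1; dz <= 1; dz++)
            for (int dy = -1; dy <= 1; dy++)
              for (int dx = -1; dx <= 1; dx++) {
                if (!dx && !dy && !dz) continue;
                int xx = cx + dx, yy = cy + dy, zz = cz + dz;
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
                int nid = vidx(xx, yy, zz, nx, ny);
                if (!seen[nid] && q[nid] == a) { seen[nid] = 1; bfs.push(nid); }
              }
        }
        zones.push_back(std::make_pair(a, size));
        if (size > maxsize) maxsize = size;
      }
  NumericMatrix M(Ng, maxsize);
  for (size_t i = 0; i < zones.size(); i++) M(zones[i].first - 1, zones[i].second - 1) += 1;
  return M;
}

// NGTDM accumulators: per level i, n_i = count of valid voxels, s_i = sum of
// |x - mean(26-neighborhood in mask)|; voxels with no in-mask neighbor skipped
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector q, IntegerVector dim, int Ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector s(Ng), ni(Ng);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int a = q[vidx(x, y, z, nx, ny)];
        if (a == 0) continue;
        double sum = 0; int cnt = 0;
        for (int dz = -1; dz <= 1; dz++)
          for (int dy = -1; dy <= 1; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
              int b = q[vidx(xx, yy, zz, nx, ny)];
              if (b == 0) continue;
              sum += b; cnt++;
            }
        if (cnt == 0) continue;
        s[a - 1] += std::fabs(a - sum / cnt);
        ni[a - 1] += 1;
      }
  return List::create(_["s"] = s, _["n"] = ni);
}
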