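// Numerical core: trilinear displacement fields and warps on a regular
// deformation grid, tetrahedral L1 volume-change energy, per-cell image
// statistics, and the attention-gated simulated-annealing stage loop.
//
// Array layout everywhere: R column-major double arrays with dim (nz, ny, nx),
// voxel (z, y, x) zero-based at linear index z + nz*(y + ny*x).
// Node displacements: dim (gz, gy, gx, 3), last index = (dz, dy, dx) in voxel
// units; node (iz, iy, ix) at linear index iz + gz*(iy + gy*ix).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct Geo {
  int nz, ny, nx, gz, gy, gx;
  double hz, hy, hx;                       // node spacing (voxels)
  std::vector<int> zs, ze, ys, ye, xs, xe; // per-cell inclusive voxel ranges
};

static void axis_ranges(int n, int g, double h, std::vector<int>& s,
                        std::vector<int>& e) {
  s.assign(g - 1, n);
  e.assign(g - 1, -1);
  for (int i = 0; i < n; i++) {
    int c = std::min((int)(i / h), g - 2);
    if (i < s[c]) s[c] = i;
    if (i > e[c]) e[c] = i;
  }
}

static Geo make_geo(const IntegerVector& vdim, const IntegerVector& gdim) {
  Geo G;
  G.nz = vdim[0]; G.ny = vdim[1]; G.nx = vdim[2];
  G.gz = gdim[0]; G.gy = gdim[1]; G.gx = gdim[2];
  G.hz = (G.nz - 1.0) / (G.gz - 1);
  G.hy = (G.ny - 1.0) / (G.gy - 1);
  G.hx = (G.nx - 1.0) / (G.gx - 1);
  axis_ranges(G.nz, G.gz, G.hz, G.zs, G.ze);
  axis_ranges(G.ny, G.gy, G.hy, G.ys, G.ye);
  axis_ranges(G.nx, G.gx, G.hx, G.xs, G.xe);
  return G;
}

// trilinear interpolation of node displacements at (possibly fractional)
// voxel coordinates; coordinates outside the lattice are clamped to it
static inline void field_at(const Geo& G, const double* D, double z, double y,
                            double x, double* f) {
  double uz = z / G.hz, uy = y / G.hy, ux = x / G.hx;
  int cz = std::max(0, std::min((int)uz, G.gz - 2));
  int cy = std::max(0, std::min((int)uy, G.gy - 2));
  int cx = std::max(0, std::min((int)ux, G.gx - 2));
  double tz = std::max(0.0, std::min(uz - cz, 1.0));
  double ty = std::max(0.0, std::min(uy - cy, 1.0));
  double tx = std::max(0.0, std::min(ux - cx, 1.0));
  int nn = G.gz * G.gy * G.gx;
  f[0] = f[1] = f[2] = 0.0;
  for (int a = 0; a < 2; a++)
    for (int b = 0; b < 2; b++)
      for (int c = 0; c < 2; c++) {
        double w = (a ? tz : 1 - tz) * (b ? ty : 1 - ty) * (c ? tx : 1 - tx);
        if (w == 0) continue;
        int ni = (cz + a) + G.gz * ((cy + b) + G.gy * (cx + c));
        f[0] += w * D[ni];
        f[1] += w * D[ni + nn];
        f[2] += w * D[ni + 2 * nn];
      }
}

// trilinear sample with zero outside the source extent; positions within
// 1e-9 voxel of an integer snap to it so integer displacement fields warp
// exactly (weight products of an interpolated field carry ~1e-16 rounding)
static inline double snap_int(double p) {
  double r = std::nearbyint(p);
  return (std::fabs(p - r) < 1e-9) ? r : p;
}

static inline double sample0(const double* s, int nz, int ny, int nx,
                             double pz, double py, double px) {
  pz = snap_int(pz);
  py = snap_int(py);
  px = snap_int(px);
  if (!(pz >= 0 && py >= 0 && px >= 0 && pz <= nz - 1 && py <= ny - 1 &&
        px <= nx - 1))
    return 0.0;
  int z0 = (int)pz, y0 = (int)py, x0 = (int)px;
  double fz = pz - z0, fy = py - y0, fx = px - x0;
  int z1 = z0 + (z0 < nz - 1), y1 = y0 + (y0 < ny - 1), x1 = x0 + (x0 < nx - 1);
#define V(zz, yy, xx) s[(zz) + nz * ((yy) + ny * (xx))]
  double c00 = V(z0, y0, x0) * (1 - fz) + V(z1, y0, x0) * fz;
  double c10 = V(z0, y1, x0) * (1 - fz) + V(z1, y1, x0) * fz;
  double c01 = V(z0, y0, x1) * (1 - fz) + V(z1, y0, x1) * fz;
  double c11 = V(z0, y1, x1) * (1 - fz) + V(z1, y1, x1) * fz;
#undef V
  double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fx) + c1 * fx;
}

// ---- tetrahedralization: 5 tetrahedra per hexahedral cell, alternating
// parity so faces conform across neighbouring cells --------------------------

static int TETS[2][5][4];
static bool TETS_READY = false;

static void init_tets() {
  if (TETS_READY) return;
  for (int p = 0; p < 2; p++) {
    int central_par = (p == 0) ? 1 : 0; // corner code bit-parity of central tet
    int ci = 0;
    for (int code = 0; code < 8; code++) {
      int pc = (((code >> 2) ^ (code >> 1) ^ code) & 1);
      if (pc == central_par) TETS[p][0][ci++] = code;
    }
    int ti = 1;
    for (int code = 0; code < 8; code++) {
      int pc = (((code >> 2) ^ (code >> 1) ^ code) & 1);
      if (pc == central_par) continue;
      TETS[p][ti][0] = code;
      TETS[p][ti][1] = code ^ 4;
      TETS[p][ti][2] = code ^ 2;
      TETS[p][ti][3] = code ^ 1;
      ti++;
    }
  }
  TETS_READY = true;
}

static inline double tet_signed(const double P[8][3], const int* t) {
  double a[3], b[3], c[3];
  for (int k = 0; k < 3; k++) {
    a[k] = P[t[1]][k] - P[t[0]][k];
    b[k] = P[t[2]][k] - P[t[0]][k];
    c[k] = P[t[3]][k] - P[t[0]][k];
  }
  double det = a[0] * (b[1] * c[2] - b[2] * c[1]) -
               a[1] * (b[0] * c[2] - b[2] * c[0]) +
               a[2] * (b[0] * c[1] - b[1] * c[0]);
  return det / 6.0;
}

// sum over the cell's 5 tetrahedra of |V_deformed - V_rest| (voxel^3)
static double cell_energy(const Geo& G, const double* D, int cz, int cy,
                          int cx) {
  init_tets();
  double P[8][3], R[8][3];
  int nn = G.gz * G.gy * G.gx;
  for (int code = 0; code < 8; code++) {
    int dz = (code >> 2) & 1, dy = (code >> 1) & 1, dx = code & 1;
    int iz = cz + dz, iy = cy + dy, ix = cx + dx;
    int ni = iz + G.gz * (iy + G.gy * ix);
    R[code][0] = iz * G.hz;
    R[code][1] = iy * G.hy;
    R[code][2] = ix * G.hx;
    P[code][0] = R[code][0] + D[ni];
    P[code][1] = R[code][1] + D[ni + nn];
    P[code][2] = R[code][2] + D[ni + 2 * nn];
  }
  int p = (cz + cy + cx) & 1;
  double e = 0;
  for (int t = 0; t < 5; t++)
    e += std::fabs(tet_signed(P, TETS[p][t]) - tet_signed(R, TETS[p][t]));
  return e;
}

// ---- exported primitives ----------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_displacement_field(IntegerVector vdim, NumericVector disp,
                                     IntegerVector gdim) {
  Geo G = make_geo(vdim, gdim);
  R_xlen_t n = (R_xlen_t)G.nz * G.ny * G.nx;
  NumericVector out(n * 3);
  const double* D = disp.begin();
  double f[3];
  for (int x = 0; x < G.nx; x++)
    for (int y = 0; y < G.ny; y++)
      for (int z = 0; z < G.nz; z++) {
        field_at(G, D, z, y, x, f);
        R_xlen_t idx = z + (R_xlen_t)G.nz * (y + (R_xlen_t)G.ny * x);
        out[idx] = f[0];
        out[idx + n] = f[1];
        out[idx + 2 * n] = f[2];
      }
  out.attr("dim") = IntegerVector::create(G.nz, G.ny, G.nx, 3);
  return out;
}

// field at arbitrary (z,y,x) zero-based voxel coordinates, one row per point
// [[Rcpp::export]]
NumericMatrix cpp_field_at_points(NumericMatrix pts, IntegerVector vdim,
                                  NumericVector disp, IntegerVector gdim) {
  Geo G = make_geo(vdim, gdim);
  NumericMatrix out(pts.nrow(), 3);
  const double* D = disp.begin();
  double f[3];
  for (int i = 0; i < pts.nrow(); i++) {
    field_at(G, D, pts(i, 0), pts(i, 1), pts(i, 2), f);
    out(i, 0) = f[0];
    out(i, 1) = f[1];
    out(i, 2) = f[2];
  }
  return out;
}

// backward warp: out(x) = src(x + field(x)), zero outside
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector src, IntegerVector vdim,
                       NumericVector disp, IntegerVector gdim) {
  Geo G = make_geo(vdim, gdim);
  R_xlen_t n = (R_xlen_t)G.nz * G.ny * G.nx;
  NumericVector out(n);
  const double* S = src.begin();
  const double* D = disp.begin();
  double f[3];
  for (int x = 0; x < G.nx; x++)
    for (int y = 0; y < G.ny; y++)
      for (int z = 0; z < G.nz; z++) {
        field_at(G, D, z, y, x, f);
        out[z + (R_xlen_t)G.nz * (y + (R_xlen_t)G.ny * x)] =
            sample0(S, G.nz, G.ny, G.nx, z + f[0], y + f[1], x + f[2]);
      }
  out.attr("dim") = IntegerVector::create(G.nz, G.ny, G.nx);
  return out;
}

// [[Rcpp::export]]
double cpp_deformation_energy(IntegerVector vdim, NumericVector disp,
                              IntegerVector gdim) {
  Geo G = make_geo(vdim, gdim);
  const double* D = disp.begin();
  double e = 0;
  for (int cx = 0; cx < G.gx - 1; cx++)
    for (int cy = 0; cy < G.gy - 1; cy++)
      for (int cz = 0; cz < G.gz - 1; cz++)
        e += cell_energy(G, D, cz, cy, cx);
  double vtot = (double)(G.nz - 1) * (G.ny - 1) * (G.nx - 1);
  return e / vtot;
}

// per-cell L1 difference between two images on the grid's cells
// [[Rcpp::export]]
NumericVector cpp_cell_l1(NumericVector a, NumericVector b, IntegerVector vdim,
                          IntegerVector gdim) {
  Geo G = make_geo(vdim, gdim);
  int ncz = G.gz - 1, ncy = G.gy - 1, ncx = G.gx - 1;
  NumericVector out(ncz * ncy * ncx);
  const double* A = a.begin();
  const double* B = b.begin();
  for (int cx = 0; cx < ncx; cx++)
    for (int cy = 0; cy < ncy; cy++)
      for (int cz = 0; cz < ncz; cz++) {
        double s = 0;
        for (int x = G.xs[cx]; x <= G.xe[cx]; x++)
          for (int y = G.ys[cy]; y <= G.ye[cy]; y++)
            for (int z = G.zs[cz]; z <= G.ze[cz]; z++) {
              R_xlen_t idx = z + (R_xlen_t)G.nz * (y + (R_xlen_t)G.ny * x);
              s += std::fabs(A[idx] - B[idx]);
            }
        out[cz + ncz * (cy + ncy * cx)] = s;
      }
  out.attr("dim") = IntegerVector::create(ncz, ncy, ncx);
  return out;
}

// trilinear resampling: in-coordinate = out-coordinate * scale (per axis)
// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector src, IntegerVector vdim,
                                     IntegerVector odim, NumericVector scale) {
  int nz = vdim[0], ny = vdim[1], nx = vdim[2];
  int oz = odim[0], oy = odim[1], ox = odim[2];
  NumericVector out((R_xlen_t)oz * oy * ox);
  const double* S = src.begin();
  for (int x = 0; x < ox; x++)
    for (int y = 0; y < oy; y++)
      for (int z = 0; z < oz; z++)
        out[z + (R_xlen_t)oz * (y + (R_xlen_t)oy * x)] =
            sample0(S, nz, ny, nx, z * scale[0], y * scale[1], x * scale[2]);
  out.attr("dim") = odim;
  return out;
}

// affine backward sampling: source coordinate = A %*% out + b
// [[Rcpp::export]]
NumericVector cpp_affine_sample(NumericVector src, IntegerVector vdim,
                                IntegerVector odim, NumericMatrix A,
                                NumericVector b, bool nearest) {
  int nz = vdim[0], ny = vdim[1], nx = vdim[2];
  int oz = odim[0], oy = odim[1], ox = odim[2];
  NumericVector out((R_xlen_t)oz * oy * ox);
  const double* S = src.begin();
  for (int x = 0; x < ox; x++)
    for (int y = 0; y < oy; y++)
      for (int z = 0; z < oz; z++) {
        double pz = A(0, 0) * z + A(0, 1) * y + A(0, 2) * x + b[0];
        double py = A(1, 0) * z + A(1, 1) * y + A(1, 2) * x + b[1];
        double px = A(2, 0) * z + A(2, 1) * y + A(2, 2) * x + b[2];
        double v;
        if (nearest) {
          int iz = (int)std::lround(pz), iy = (int)std::lround(py),
              ix = (int)std::lround(px);
          v = (iz >= 0 && iy >= 0 && ix >= 0 && iz < nz && iy < ny && ix < nx)
                  ? S[iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix)]
                  : 0.0;
        } else {
          v = sample0(S, nz, ny, nx, pz, py, px);
        }
        out[z + (R_xlen_t)oz * (y + (R_xlen_t)oy * x)] = v;
      }
  out.attr("dim") = odim;
  return out;
}

// ---- simulated-annealing stage ---------------------------------------------

struct CellStats {
  double sw, sw2, swt, l1;
};

static void cell_image_stats(const Geo& G, const double* src,
                             const double* tgt, const double* D, int cz,
                             int cy, int cx, CellStats& S, double* Wout) {
  S.sw = S.sw2 = S.swt = S.l1 = 0;
  double f[3];
  for (int x = G.xs[cx]; x <= G.xe[cx]; x++)
    for (int y = G.ys[cy]; y <= G.ye[cy]; y++)
      for (int z = G.zs[cz]; z <= G.ze[cz]; z++) {
        field_at(G, D, z, y, x, f);
        double v = sample0(src, G.nz, G.ny, G.nx, z + f[0], y + f[1],
                           x + f[2]);
        R_xlen_t idx = z + (R_xlen_t)G.nz * (y + (R_xlen_t)G.ny * x);
        if (Wout) Wout[idx] = v;
        double t = tgt[idx];
        S.sw += v;
        S.sw2 += v * v;
        S.swt += v * t;
        S.l1 += std::fabs(v - t);
      }
}

static inline double pearson_from_sums(double n, double SW, double SW2,
                                       double SWT, double ST, double ST2) {
  double vw = n * SW2 - SW * SW, vt = n * ST2 - ST * ST;
  if (vw <= 0 || vt <= 0) return 0.0;
  return (n * SWT - SW * ST) / std::sqrt(vw * vt);
}

// One coarse-to-fine stage of attention-gated simulated annealing over the
// node displacements. RNG draws (R's stream) per iteration, in fixed order:
// node-choice uniform, three N(0, sigma) displacement components, acceptance
// uniform (always consumed, also in greedy mode).
// [[Rcpp::export]]
List cpp_sa_stage(NumericVector src, NumericVector tgt, IntegerVector vdim,
                  NumericVector disp, IntegerVector gdim, double lambda,
                  double t0, double t_ratio, int iters, double sigma0,
                  double sigma_lo, double sigma_hi, bool greedy,
                  bool attention, int recompute_every) {
  Geo G = make_geo(vdim, gdim);
  R_xlen_t n = (R_xlen_t)G.nz * G.ny * G.nx;
  int nn = G.gz * G.gy * G.gx;
  int ncz = G.gz - 1, ncy = G.gy - 1, ncx = G.gx - 1;
  int ncell = ncz * ncy * ncx;
  double vtot = (double)(G.nz - 1) * (G.ny - 1) * (G.nx - 1);

  std::vector<double> D(disp.begin(), disp.end());
  std::vector<double> W(n), candW(n);
  std::vector<CellStats> cs(ncell);
  std::vector<double> cen(ncell);
  std::vector<double> wbuf(nn);
  const double* S = src.begin();
  const double* T = tgt.begin();

  double ST_ = 0, ST2_ = 0;
  for (R_xlen_t i = 0; i < n; i++) {
    ST_ += T[i];
    ST2_ += T[i] * T[i];
  }

  double SW = 0, SW2 = 0, SWT = 0, Esum = 0, r = 0, obj = 0;

  auto full_recompute = [&]() {
    SW = SW2 = SWT = Esum = 0;
    for (int cx = 0; cx < ncx; cx++)
      for (int cy = 0; cy < ncy; cy++)
        for (int cz = 0; cz < ncz; cz++) {
          int ci = cz + ncz * (cy + ncy * cx);
          cell_image_stats(G, S, T, D.data(), cz, cy, cx, cs[ci], W.data());
          cen[ci] = cell_energy(G, D.data(), cz, cy, cx);
          SW += cs[ci].sw;
          SW2 += cs[ci].sw2;
          SWT += cs[ci].swt;
          Esum += cen[ci];
        }
    r = pearson_from_sums((double)n, SW, SW2, SWT, ST_, ST2_);
    obj = r - lambda * Esum / vtot;
  };
  full_recompute();

  NumericVector tr_sim(iters), tr_en(iters), tr_obj(iters), tr_t(iters),
      tr_sig(iters);
  IntegerVector tr_acc(iters), tr_node(iters);

  double sigma = sigma0;
  int cells[24]; // (cz,cy,cx) triples for up to 8 incident cells
  CellStats ncs[8];
  double nce[8];
  int cids[8];

  for (int i = 0; i < iters; i++) {
    double t = (iters > 1) ? t0 * std::pow(t_ratio, (double)i / (iters - 1))
                           : t0;

    // node selection
    double u = unif_rand();
    int node;
    if (attention) {
      double tot = 0;
      for (int nd = 0; nd < nn; nd++) {
        int iz = nd % G.gz, iy = (nd / G.gz) % G.gy, ix = nd / (G.gz * G.gy);
        double w = 1e-12;
        for (int a = std::max(0, iz - 1); a <= std::min(ncz - 1, iz); a++)
          for (int b = std::max(0, iy - 1); b <= std::min(ncy - 1, iy); b++)
            for (int c = std::max(0, ix - 1); c <= std::min(ncx - 1, ix); c++)
              w += cs[a + ncz * (b + ncy * c)].l1;
        wbuf[nd] = w;
        tot += w;
      }
      double targ = u * tot, acc = 0;
      node = nn - 1;
      for (int nd = 0; nd < nn; nd++) {
        acc += wbuf[nd];
        if (targ <= acc) {
          node = nd;
          break;
        }
      }
    } else {
      node = std::min((int)(u * nn), nn - 1);
    }

    double pz = norm_rand() * sigma, py = norm_rand() * sigma,
           px = norm_rand() * sigma;

    int iz = node % G.gz, iy = (node / G.gz) % G.gy, ix = node / (G.gz * G.gy);
    double o0 = D[node], o1 = D[node + nn], o2 = D[node + 2 * nn];
    D[node] += pz;
    D[node + nn] += py;
    D[node + 2 * nn] += px;

    // incident cells
    int ncells_i = 0;
    for (int a = std::max(0, iz - 1); a <= std::min(ncz - 1, iz); a++)
      for (int b = std::max(0, iy - 1); b <= std::min(ncy - 1, iy); b++)
        for (int c = std::max(0, ix - 1); c <= std::min(ncx - 1, ix); c++) {
          cells[ncells_i * 3] = a;
          cells[ncells_i * 3 + 1] = b;
          cells[ncells_i * 3 + 2] = c;
          // (packed below; 8 cells max so reuse flat storage)
          ncells_i++;
          if (ncells_i == 8) goto donecells;
        }
  donecells:;
    // flat cell coords were packed 3-per-cell into `cells`; recover below
    double dSW = 0, dSW2 = 0, dSWT = 0, dEn = 0;
    for (int k = 0; k < ncells_i; k++) {
      int a = cells[k * 3], b = cells[k * 3 + 1], c = cells[k * 3 + 2];
      int ci = a + ncz * (b + ncy * c);
      cids[k] = ci;
      cell_image_stats(G, S, T, D.data(), a, b, c, ncs[k], candW.data());
      nce[k] = cell_energy(G, D.data(), a, b, c);
      dSW += ncs[k].sw - cs[ci].sw;
      dSW2 += ncs[k].sw2 - cs[ci].sw2;
      dSWT += ncs[k].swt - cs[ci].swt;
      dEn += nce[k] - cen[ci];
    }
    double SWc = SW + dSW, SW2c = SW2 + dSW2, SWTc = SWT + dSWT;
    double Ec = Esum + dEn;
    double rc = pearson_from_sums((double)n, SWc, SW2c, SWTc, ST_, ST2_);
    double objc = rc - lambda * Ec / vtot;
    double dObj = objc - obj;
    if (!std::isfinite(objc)) {
      stop("non-finite objective at iteration %d", i + 1);
    }

    double ua = unif_rand();
    bool accept;
    if (greedy)
      accept = dObj > 0;
    else
      accept = (dObj >= 0) || (ua < std::exp(dObj / t));

    if (accept) {
      for (int k = 0; k < ncells_i; k++) {
        int a = cells[k * 3], b = cells[k * 3 + 1], c = cells[k * 3 + 2];
        for (int x = G.xs[c]; x <= G.xe[c]; x++)
          for (int y = G.ys[b]; y <= G.ye[b]; y++)
            for (int z = G.zs[a]; z <= G.ze[a]; z++) {
              R_xlen_t idx = z + (R_xlen_t)G.nz * (y + (R_xlen_t)G.ny * x);
              W[idx] = candW[idx];
            }
        cs[cids[k]] = ncs[k];
        cen[cids[k]] = nce[k];
      }
      SW = SWc;
      SW2 = SW2c;
      SWT = SWTc;
      Esum = Ec;
      r = rc;
      obj = objc;
      sigma /= 0.99;
    } else {
      D[node] = o0;
      D[node + nn] = o1;
      D[node + 2 * nn] = o2;
      sigma *= 0.99;
    }
    sigma = std::min(std::max(sigma, sigma_lo), sigma_hi);

    tr_sim[i] = r;
    tr_en[i] = Esum / vtot;
    tr_obj[i] = obj;
    tr_acc[i] = accept ? 1 : 0;
    tr_node[i] = node + 1;
    tr_t[i] = t;
    tr_sig[i] = sigma;

    if (recompute_every > 0 && ((i + 1) % recompute_every == 0))
      full_recompute();
  }

  double cached = obj;
  full_recompute();
  double drift = std::fabs(cached - obj);

  NumericVector dout(D.begin(), D.end());
  dout.attr("dim") = IntegerVector::create(G.gz, G.gy, G.gx, 3);
  return List::create(
      _["disp"] = dout, _["sigma"] = sigma, _["similarity"] = r,
      _["energy"] = Esum / vtot, _["objective"] = obj, _["drift"] = drift,
      _["trace"] = DataFrame::create(
          _["iteration"] = seq_len(iters), _["similarity"] = tr_sim,
          _["energy"] = tr_en, _["objective"] = tr_obj,
          _["accepted"] = tr_acc, _["node"] = tr_node,
          _["temperature"] = tr_t, _["sigma"] = tr_sig));
}
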