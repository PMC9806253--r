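#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// helpers: 3D array indexing (R column-major: i + n0*(j + n1*k))
// ---------------------------------------------------------------------------

static inline int idx3(int i, int j, int k, int n0, int n1) {
  return i + n0 * (j + n1 * k);
}

static IntegerVector dims_of(SEXP x) {
  IntegerVector d = as<IntegerVector>(Rf_getAttrib(x, R_DimSymbol));
  if (d.size() != 3) stop("expected a 3D array");
  return d;
}

// ---------------------------------------------------------------------------
// single-level 1D DWT / IDWT, half-point symmetric extension, redundant
// boundary coefficients (coefficient length floor((n + F - 1) / 2)); exact
// perfect reconstruction for any signal length
// ---------------------------------------------------------------------------

static void dwt1(const std::vector<double> &x,
                 const std::vector<double> &lo, const std::vector<double> &hi,
                 std::vector<double> &cA, std::vector<double> &cD) {
  const int n = (int)x.size(), F = (int)lo.size();
  const int ne = n + 2 * (F - 1);
  std::vector<double> ext(ne);
  for (int i = 0; i < F - 1; ++i) ext[i] = x[F - 2 - i];            // left mirror
  for (int i = 0; i < n; ++i) ext[F - 1 + i] = x[i];
  for (int i = 0; i < F - 1; ++i) ext[F - 1 + n + i] = x[n - 1 - i]; // right mirror
  const int nz = n + F - 1;            // valid convolution length
  const int L = nz / 2;                // keep odd indices 1,3,...
  cA.assign(L, 0.0); cD.assign(L, 0.0);
  for (int t = 0; t < L; ++t) {
    const int k = 2 * t + 1;
    double sa = 0.0, sd = 0.0;
    for (int j = 0; j < F; ++j) {
      const double v = ext[k + F - 1 - j];
      sa += lo[j] * v;
      sd += hi[j] * v;
    }
    cA[t] = sa; cD[t] = sd;
  }
}

static void idwt1(const std::vector<double> &cA, const std::vector<double> &cD,
                  const std::vector<double> &lo, const std::vector<double> &hi,
                  int n, std::vector<double> &out) {
  const int L = (int)cA.size(), F = (int)lo.size();
  const int nu = 2 * L - 1;                 // upsampled length
  const int nf = nu + F - 1;                // full convolution length
  std::vector<double> y(nf, 0.0);
  for (int i = 0; i < L; ++i) {
    const double a = cA[i], d = cD[i];
    const int base = 2 * i;
    for (int j = 0; j < F; ++j) y[base + j] += a * lo[j] + d * hi[j];
  }
  out.assign(n, 0.0);
  const int off = F - 2;                    // crop boundary redundancy
  for (int i = 0; i < n; ++i) out[i] = y[off + i];
}

// decompose/reconstruct along one axis of a 3D array stored column-major
static void dwt_axis(const std::vector<double> &vol, const int dim[3], int axis,
                     const std::vector<double> &lo, const std::vector<double> &hi,
                     std::vector<double> &A, std::vector<double> &D, int outdim[3]) {
  const int n = dim[axis];
  const int F = (int)lo.size();
  const int L = (n + F - 1) / 2;
  outdim[0] = dim[0]; outdim[1] = dim[1]; outdim[2] = dim[2];
  outdim[axis] = L;
  A.assign((size_t)outdim[0] * outdim[1] * outdim[2], 0.0);
  D.assign(A.size(), 0.0);
  std::vector<double> line(n), cA, cD;
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const int o0 = outdim[0], o1 = outdim[1];
  if (axis == 0) {
    for (int k = 0; k < n2; ++k) for (int j = 0; j < n1; ++j) {
      for (int i = 0; i < n; ++i) line[i] = vol[idx3(i, j, k, n0, n1)];
      dwt1(line, lo, hi, cA, cD);
      for (int i = 0; i < L; ++i) { A[idx3(i, j, k, o0, o1)] = cA[i]; D[idx3(i, j, k, o0, o1)] = cD[i]; }
    }
  } else if (axis == 1) {
    for (int k = 0; k < n2; ++k) for (int i = 0; i < n0; ++i) {
      for (int j = 0; j < n; ++j) line[j] = vol[idx3(i, j, k, n0, n1)];
      dwt1(line, lo, hi, cA, cD);
      for (int j = 0; j < L; ++j) { A[idx3(i, j, k, o0, o1)] = cA[j]; D[idx3(i, j, k, o0, o1)] = cD[j]; }
    }
  } else {
    for (int j = 0; j < n1; ++j) for (int i = 0; i < n0; ++i) {
      for (int k = 0; k < n; ++k) line[k] = vol[idx3(i, j, k, n0, n1)];
      dwt1(line, lo, hi, cA, cD);
      for (int k = 0; k < L; ++k) { A[idx3(i, j, k, o0, o1)] = cA[k]; D[idx3(i, j, k, o0, o1)] = cD[k]; }
    }
  }
}

static void idwt_axis(const std::vector<double> &A, const std::vector<double> &D,
                      const int dim[3], int axis, int nOrig,
                      const std::vector<double> &lo, const std::vector<double> &hi,
                      std::vector<double> &out, int outdim[3]) {
  outdim[0] = dim[0]; outdim[1] = dim[1]; outdim[2] = dim[2];
  outdim[axis] = nOrig;
  out.assign((size_t)outdim[0] * outdim[1] * outdim[2], 0.0);
  const int L = dim[axis];
  std::vector<double> cA(L), cD(L), line;
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const int o0 = outdim[0], o1 = outdim[1];
  if (axis == 0) {
    for (int k = 0; k < n2; ++k) for (int j = 0; j < n1; ++j) {
      for (int i = 0; i < L; ++i) { cA[i] = A[idx3(i, j, k, n0, n1)]; cD[i] = D[idx3(i, j, k, n0, n1)]; }
      idwt1(cA, cD, lo, hi, nOrig, line);
      for (int i = 0; i < nOrig; ++i) out[idx3(i, j, k, o0, o1)] = line[i];
    }
  } else if (axis == 1) {
    for (int k = 0; k < n2; ++k) for (int i = 0; i < n0; ++i) {
      for (int j = 0; j < L; ++j) { cA[j] = A[idx3(i, j, k, n0, n1)]; cD[j] = D[idx3(i, j, k, n0, n1)]; }
      idwt1(cA, cD, lo, hi, nOrig, line);
      for (int j = 0; j < nOrig; ++j) out[idx3(i, j, k, o0, o1)] = line[j];
    }
  } else {
    for (int j = 0; j < n1; ++j) for (int i = 0; i < n0; ++i) {
      for (int k = 0; k < L; ++k) { cA[k] = A[idx3(i, j, k, n0, n1)]; cD[k] = D[idx3(i, j, k, n0, n1)]; }
      idwt1(cA, cD, lo, hi, nOrig, line);
      for (int k = 0; k < nOrig; ++k) out[idx3(i, j, k, o0, o1)] = line[k];
    }
  }
}

// Single-level separable 3D DWT; scale the all-low-pass (LLL) sub-band by
// `ratio`, keep the seven detail sub-bands at weight 1; inverse transform.
// [[Rcpp::export]]
NumericVector cpp_wavelet_ratio(NumericVector vol,
                                NumericVector dec_lo, NumericVector dec_hi,
                                NumericVector rec_lo, NumericVector rec_hi,
                                double ratio) {
  IntegerVector dv = dims_of(vol);
  int dim[3] = {dv[0], dv[1], dv[2]};
  const int F = dec_lo.size();
  for (int a = 0; a < 3; ++a)
    if (dim[a] < F) stop("volume smaller than the wavelet filter support along axis %d", a + 1);
  std::vector<double> lo_d(dec_lo.begin(), dec_lo.end()), hi_d(dec_hi.begin(), dec_hi.end());
  std::vector<double> lo_r(rec_lo.begin(), rec_lo.end()), hi_r(rec_hi.begin(), rec_hi.end());
  std::vector<double> v(vol.begin(), vol.end());

  // decompose axis 0, 1, 2 -> 8 sub-bands; band index bitmask, bit a set =
  // detail along axis a, so band 0 is LLL
  std::vector<std::vector<double>> bands(1, v);
  int curdim[3] = {dim[0], dim[1], dim[2]};
  for (int axis = 0; axis < 3; ++axis) {
    std::vector<std::vector<double>> nb;
    int od[3];
    for (size_t b = 0; b < bands.size(); ++b) {
      std::vector<double> A, D;
      dwt_axis(bands[b], curdim, axis, lo_d, hi_d, A, D, od);
      nb.push_back(A); nb.push_back(D);
    }
    // order: for band b, children 2b (approx) and 2b+1 (detail); relabel so
    // that bitmask convention holds: after axis a, index bit a = detail
    std::vector<std::vector<double>> re(nb.size());
    for (size_t b = 0; b < bands.size(); ++b) {
      re[b] = nb[2 * b];                      // approx keeps same low bits
      re[b + bands.size()] = nb[2 * b + 1];   // detail sets bit `axis`
    }
    bands = re;
    curdim[0] = od[0]; curdim[1] = od[1]; curdim[2] = od[2];
  }
  for (size_t t = 0; t < bands[0].size(); ++t) bands[0][t] *= ratio;

  // reconstruct axis 2, 1, 0
  for (int axis = 2; axis >= 0; --axis) {
    const size_t half = bands.size() / 2;
    std::vector<std::vector<double>> nb(half);
    int od[3];
    for (size_t b = 0; b < half; ++b) {
      std::vector<double> out;
      idwt_axis(bands[b], bands[b + half], curdim, axis, dim[axis], lo_r, hi_r, out, od);
      nb[b] = out;
    }
    bands = nb;
    curdim[0] = od[0]; curdim[1] = od[1]; curdim[2] = od[2];
  }
  NumericVector res(bands[0].begin(), bands[0].end());
  res.attr("dim") = dv;
  return res;
}

// ---------------------------------------------------------------------------
// texture matrices; `levels` holds 1..G inside the ROI and 0 outside
// ---------------------------------------------------------------------------

// symmetric co-occurrence counts accumulated over the supplied directions
// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(IntegerVector levels, int G, int dist, IntegerMatrix dirs) {
  IntegerVector dv = dims_of(levels);
  const int n0 = dv[0], n1 = dv[1], n2 = dv[2];
  NumericMatrix C(G, G);
  for (int d = 0; d < dirs.nrow(); ++d) {
    const int dx = dirs(d, 0) * dist, dy = dirs(d, 1) * dist, dz = dirs(d, 2) * dist;
    for (int k = 0; k < n2; ++k) for (int j = 0; j < n1; ++j) for (int i = 0; i < n0; ++i) {
      const int a = levels[idx3(i, j, k, n0, n1)];
      if (a == 0) continue;
      const int i2 = i + dx, j2 = j + dy, k2 = k + dz;
      if (i2 < 0 || i2 >= n0 || j2 < 0 || j2 >= n1 || k2 < 0 || k2 >= n2) continue;
      const int b = levels[idx3(i2, j2, k2, n0, n1)];
      if (b == 0) continue;
      C(a - 1, b - 1) += 1.0;
      C(b - 1, a - 1) += 1.0;
    }
  }
  return C;
}

// run-length counts for one direction; matrix G x maxRun
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_counts(IntegerVector levels, int G, IntegerVector dir) {
  IntegerVector dv = dims_of(levels);
  const int n0 = dv[0], n1 = dv[1], n2 = dv[2];
  const int dx = dir[0], dy = dir[1], dz = dir[2];
  std::vector<std::vector<double>> counts(G);
  int maxRun = 1;
  for (int k = 0; k < n2; ++k) for (int j = 0; j < n1; ++j) for (int i = 0; i < n0; ++i) {
    const int a = levels[idx3(i, j, k, n0, n1)];
    if (a == 0) continue;
    const int pi = i - dx, pj = j - dy, pk = k - dz;  // run starts only
    if (pi >= 0 && pi < n0 && pj >= 0 && pj < n1 && pk >= 0 && pk < n2 &&
        levels[idx3(pi, pj, pk, n0, n1)] == a) continue;
    int len = 1, ci = i + dx, cj = j + dy, ck = k + dz;
    while (ci >= 0 && ci < n0 && cj >= 0 && cj < n1 && ck >= 0 && ck < n2 &&
           levels[idx3(ci, cj, ck, n0, n1)] == a) {
      ++len; ci += dx; cj += dy; ck += dz;
    }
    if (len > maxRun) maxRun = len;
    std::vector<double> &row = counts[a - 1];
    if ((int)row.size() < len) row.resize(len, 0.0);
    row[len - 1] += 1.0;
  }
  NumericMatrix M(G, maxRun);
  for (int g = 0; g < G; ++g)
    for (size_t r = 0; r < counts[g].size(); ++r) M(g, r) = counts[g][r];
  return M;
}

// size-zone counts: 26-connected components of equal level; matrix G x maxZone
// [[Rcpp::export]]
NumericMatrix cpp_glszm_counts(IntegerVector levels, int G) {
  IntegerVector dv = dims_of(levels);
  const int n0 = dv[0], n1 = dv[1], n2 = dv[2];
  const int n = n0 * n1 * n2;
  std::vector<char> seen(n, 0);
  std::vector<std::vector<double>> counts(G);
  int maxZone = 1;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    const int lev = levels[s];
    if (lev == 0 || seen[s]) continue;
    int size = 0;
    stack.clear(); stack.push_back(s); seen[s] = 1;
    while (!stack.empty()) {
      const int cur = stack.back(); stack.pop_back();
      ++size;
      const int ci = cur % n0, cj = (cur / n0) % n1, ck = cur / (n0 * n1);
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int i2 = ci + dx, j2 = cj + dy, k2 = ck + dz;
        if (i2 < 0 || i2 >= n0 || j2 < 0 || j2 >= n1 || k2 < 0 || k2 >= n2) continue;
        const int t = idx3(i2, j2, k2, n0, n1);
        if (!seen[t] && levels[t] == lev) { seen[t] = 1; stack.push_back(t); }
      }
    }
    if (size > maxZone) maxZone = size;
    std::vector<double> &row = counts[lev - 1];
    if ((int)row.size() < size) row.resize(size, 0.0);
    row[size - 1] += 1.0;
  }
  NumericMatrix M(G, maxZone);
  for (int g = 0; g < G; ++g)
    for (size_t z = 0; z < counts[g].size(); ++z) M(g, z) = counts[g][z];
  return M;
}

// neighborhood gray-tone difference table: per level i, n_i (voxels with at
// least one in-ROI 26-neighbor) and s_i = sum |i - mean(neighbor levels)|
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm_table(IntegerVector levels, int G) {
  IntegerVector dv = dims_of(levels);
  const int n0 = dv[0], n1 = dv[1], n2 = dv[2];
  NumericMatrix M(G, 2);  // col 0: n_i, col 1: s_i
  for (int k = 0; k < n2; ++k) for (int j = 0; j < n1; ++j) for (int i = 0; i < n0; ++i) {
    const int a = levels[idx3(i, j, k, n0, n1)];
    if (a == 0) continue;
    double sum = 0.0; int cnt = 0;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
      if (dx == 0 && dy == 0 && dz == 0) continue;
      const int i2 = i + dx, j2 = j + dy, k2 = k + dz;
      if (i2 < 0 || i2 >= n0 || j2 < 0 || j2 >= n1 || k2 < 0 || k2 >= n2) continue;
      const int b = levels[idx3(i2, j2, k2, n0, n1)];
      if (b > 0) { sum += b; ++cnt; }
    }
    if (cnt == 0) continue;
    M(a - 1, 0) += 1.0;
    M(a - 1, 1) += std::fabs((double)a - sum / cnt);
  }
  return M;
}

// ---------------------------------------------------------------------------
// exact Euclidean distance transform (squared), anisotropic spacing in mm
// (Felzenszwalb & Huttenlocher separable lower-envelope algorithm)
// ---------------------------------------------------------------------------

static const double DT_INF = 1e30;

static void dt1d(std::vector<double> &f, int n, double w2,
                 std::vector<int> &v, std::vector<double> &z, std::vector<double> &d) {
  int k = 0;
  v[0] = 0; z[0] = -DT_INF; z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// squared distance (mm^2) from every voxel to the nearest voxel where
// `background` is TRUE; DT_INF-like values where no background exists
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector background, NumericVector spacing) {
  IntegerVector dv = dims_of(background);
  const int n0 = dv[0], n1 = dv[1], n2 = dv[2];
  const size_t n = (size_t)n0 * n1 * n2;
  std::vector<double> D(n);
  for (size_t t = 0; t < n; ++t) D[t] = background[t] ? 0.0 : DT_INF;
  const int nmax = std::max(n0, std::max(n1, n2));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 0
  double w2 = spacing[0] * spacing[0];
  for (int k = 0; k < n2; ++k) for (int j = 0; j < n1; ++j) {
    for (int i = 0; i < n0; ++i) f[i] = D[idx3(i, j, k, n0, n1)];
    dt1d(f, n0, w2, v, z, d);
    for (int i = 0; i < n0; ++i) D[idx3(i, j, k, n0, n1)] = d[i];
  }
  // axis 1
  w2 = spacing[1] * spacing[1];
  for (int k = 0; k < n2; ++k) for (int i = 0; i < n0; ++i) {
    for (int j = 0; j < n1; ++j) f[j] = D[idx3(i, j, k, n0, n1)];
    dt1d(f, n1, w2, v, z, d);
    for (int j = 0; j < n1; ++j) D[idx3(i, j, k, n0, n1)] = d[j];
  }
  // axis 2
  w2 = spacing[2] * spacing[2];
  for (int j = 0; j < n1; ++j) for (int i = 0; i < n0; ++i) {
    for (int k = 0; k < n2; ++k) f[k] = D[idx3(i, j, k, n0, n1)];
    dt1d(f, n2, w2, v, z, d);
    for (int k = 0; k < n2; ++k) D[idx3(i, j, k, n0, n1)] = d[k];
  }
  NumericVector out(D.begin(), D.end());
  out.attr("dim") = dv;
  return out;
}

// ---------------------------------------------------------------------------
// resampling: voxel centers at index * spacing, origins aligned
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector vol, NumericVector spacing,
                                     IntegerVector outDim, NumericVector outSpacing) {
  IntegerVector dv = dims_of(vol);
  const int n0 = dv[0], n1 = dv[1], n2 = dv[2];
  const int m0 = outDim[0], m1 = outDim[1], m2 = outDim[2];
  NumericVector out((size_t)m0 * m1 * m2);
  for (int k = 0; k < m2; ++k) for (int j = 0; j < m1; ++j) for (int i = 0; i < m0; ++i) {
    double x = i * outSpacing[0] / spacing[0];
    double y = j * outSpacing[1] / spacing[1];
    double zc = k * outSpacing[2] / spacing[2];
    x = std::min(std::max(x, 0.0), (double)(n0 - 1));
    y = std::min(std::max(y, 0.0), (double)(n1 - 1));
    zc = std::min(std::max(zc, 0.0), (double)(n2 - 1));
    const int x0 = std::min((int)std::floor(x), n0 - 1), x1 = std::min(x0 + 1, n0 - 1);
    const int y0 = std::min((int)std::floor(y), n1 - 1), y1 = std::min(y0 + 1, n1 - 1);
    const int z0 = std::min((int)std::floor(zc), n2 - 1), z1 = std::min(z0 + 1, n2 - 1);
    const double fx = x - x0, fy = y - y0, fz = zc - z0;
    double acc = 0.0;
    acc += vol[idx3(x0, y0, z0, n0, n1)] * (1 - fx) * (1 - fy) * (1 - fz);
    acc += vol[idx3(x1, y0, z0, n0, n1)] * fx * (1 - fy) * (1 - fz);
    acc += vol[idx3(x0, y1, z0, n0, n1)] * (1 - fx) * fy * (1 - fz);
    acc += vol[idx3(x1, y1, z0, n0, n1)] * fx * fy * (1 - fz);
    acc += vol[idx3(x0, y0, z1, n0, n1)] * (1 - fx) * (1 - fy) * fz;
    acc += vol[idx3(x1, y0, z1, n0, n1)] * fx * (1 - fy) * fz;
    acc += vol[idx3(x0, y1, z1, n0, n1)] * (1 - fx) * fy * fz;
    acc += vol[idx3(x1, y1, z1, n0, n1)] * fx * fy * fz;
    out[idx3(i, j, k, m0, m1)] = acc;
  }
  out.attr("dim") = outDim;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_resample_nearest(IntegerVector vol, NumericVector spacing,
                                   IntegerVector outDim, NumericVector outSpacing) {
  IntegerVector dv = dims_of(vol);
  const int n0 = dv[0], n1 = dv[1], n2 = dv[2];
  const int m0 = outDim[0], m1 = outDim[1], m2 = outDim[2];
  IntegerVector out((size_t)m0 * m1 * m2);
  for (int k = 0; k < m2; ++k) for (int j = 0; j < m1; ++j) for (int i = 0; i < m0; ++i) {
    int x = (int)std::lround(i * outSpacing[0] / spacing[0]);
    int y = (int)std::lround(j * outSpacing[1] / spacing[1]);
    int zc = (int)std::lround(k * outSpacing[2] / spacing[2]);
    x = std::min(std::max(x, 0), n0 - 1);
    y = std::min(std::max(y, 0), n1 - 1);
    zc = std::min(std::max(zc, 0), n2 - 1);
    out[idx3(i, j, k, m0, m1)] = vol[idx3(x, y, zc, n0, n1)];
  }
  out.attr("dim") = outDim;
  return out;
}

// ---------------------------------------------------------------------------
// separable Gaussian smoothing (sigma in voxels, reflected boundaries,
// kernel truncated at 3 sigma); used by the phantom generator
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_smooth_gauss(NumericVector vol, double sigma) {
  IntegerVector dv = dims_of(vol);
  const int n0 = dv[0], n1 = dv[1], n2 = dv[2];
  if (sigma <= 0) return clone(vol);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) { ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma)); s += ker[t + r]; }
  for (double &v : ker) v /= s;
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  const int dims[3] = {n0, n1, n2};
  for (int axis = 0; axis < 3; ++axis) {
    const int n = dims[axis];
    for (int k = 0; k < (axis == 2 ? 1 : n2); ++k)
      for (int j = 0; j < (axis == 1 ? 1 : n1); ++j)
        for (int i = 0; i < (axis == 0 ? 1 : n0); ++i) {
          // iterate lines along `axis`; (i,j,k) fixes the other two coords
          for (int t = 0; t < n; ++t) {
            double acc = 0.0;
            for (int u = -r; u <= r; ++u) {
              int p = t + u;
              if (p < 0) p = -p - 1;              // reflect
              if (p >= n) p = 2 * n - p - 1;
              int ii = i, jj = j, kk = k;
              if (axis == 0) ii = p; else if (axis == 1) jj = p; else kk = p;
              acc += ker[u + r] * a[idx3(ii, jj, kk, n0, n1)];
            }
            int ii = i, jj = j, kk = k;
            if (axis == 0) ii = t; else if (axis == 1) jj = t; else kk = t;
            b[idx3(ii, jj, kk, n0, n1)] = acc;
          }
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dv;
  return out;
}

// ---------------------------------------------------------------------------
// low-pass-only path: reconstruction of the LLL sub-band alone. By linearity
// of the DWT, the band-weighted filter output equals v + (ratio - 1) * A
// where A is this approximation reconstruction; sharing A across the four
// ratios of a family avoids redundant full decompositions.
// ---------------------------------------------------------------------------

static void dwt_axis_lo(const std::vector<double> &vol, const int dim[3], int axis,
                        const std::vector<double> &lo,
                        std::vector<double> &A, int outdim[3]) {
  const int n = dim[axis];
  const int F = (int)lo.size();
  const int L = (n + F - 1) / 2;
  outdim[0] = dim[0]; outdim[1] = dim[1]; outdim[2] = dim[2];
  outdim[axis] = L;
  A.assign((size_t)outdim[0] * outdim[1] * outdim[2], 0.0);
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const int o0 = outdim[0], o1 = outdim[1];
  std::vector<double> line(n), cA, cD;
  std::vector<double> hi(F, 0.0);  // unused detail branch
  if (axis == 0) {
    for (int k = 0; k < n2; ++k) for (int j = 0; j < n1; ++j) {
      for (int i = 0; i < n; ++i) line[i] = vol[idx3(i, j, k, n0, n1)];
      dwt1(line, lo, hi, cA, cD);
      for (int i = 0; i < L; ++i) A[idx3(i, j, k, o0, o1)] = cA[i];
    }
  } else if (axis == 1) {
    for (int k = 0; k < n2; ++k) for (int i = 0; i < n0; ++i) {
      for (int j = 0; j < n; ++j) line[j] = vol[idx3(i, j, k, n0, n1)];
      dwt1(line, lo, hi, cA, cD);
      for (int j = 0; j < L; ++j) A[idx3(i, j, k, o0, o1)] = cA[j];
    }
  } else {
    for (int j = 0; j < n1; ++j) for (int i = 0; i < n0; ++i) {
      for (int k = 0; k < n; ++k) line[k] = vol[idx3(i, j, k, n0, n1)];
      dwt1(line, lo, hi, cA, cD);
      for (int k = 0; k < L; ++k) A[idx3(i, j, k, o0, o1)] = cA[k];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_wavelet_approx(NumericVector vol,
                                 NumericVector dec_lo, NumericVector rec_lo) {
  IntegerVector dv = dims_of(vol);
  int dim[3] = {dv[0], dv[1], dv[2]};
  const int F = dec_lo.size();
  for (int a = 0; a < 3; ++a)
    if (dim[a] < F) stop("volume smaller than the wavelet filter support along axis %d", a + 1);
  std::vector<double> lo_d(dec_lo.begin(), dec_lo.end());
  std::vector<double> lo_r(rec_lo.begin(), rec_lo.end());
  std::vector<double> zero_r(F, 0.0);
  std::vector<double> cur(vol.begin(), vol.end());
  int curdim[3] = {dim[0], dim[1], dim[2]};
  for (int axis = 0; axis < 3; ++axis) {
    std::vector<double> A;
    int od[3];
    dwt_axis_lo(cur, curdim, axis, lo_d, A, od);
    cur = A;
    curdim[0] = od[0]; curdim[1] = od[1]; curdim[2] = od[2];
  }
  for (int axis = 2; axis >= 0; --axis) {
    std::vector<double> zero(cur.size(), 0.0), out;
    int od[3];
    idwt_axis(cur, zero, curdim, axis, dim[axis], lo_r, zero_r, out, od);
    cur = out;
    curdim[0] = od[0]; curdim[1] = od[1]; curdim[2] = od[2];
  }
  NumericVector res(cur.begin(), cur.end());
  res.attr("dim") = dv;
  return res;
}

// ---------------------------------------------------------------------------
// fused per-image texture kernel: discretization + all 64 features in one
// pass. Must agree exactly with the modular R path (firstOrderFeatures,
// glcmFeatures, glrlmFeatures, glszmFeatures, ngtdmFeatures), which the
// test suite asserts; the R path stays the documented reference.
// ---------------------------------------------------------------------------

static const int DIRS13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
  {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};

static double quantile7(std::vector<double> x, double p) {
  std::sort(x.begin(), x.end());
  const int n = (int)x.size();
  if (n == 1) return x[0];
  const double h = (n - 1) * p;
  const int lo = (int)std::floor(h);
  const int hi = std::min(lo + 1, n - 1);
  return x[lo] + (h - lo) * (x[hi] - x[lo]);
}

// [[Rcpp::export]]
NumericVector cpp_texture_features(NumericVector raw, LogicalVector mask, int G) {
  IntegerVector dv = dims_of(raw);
  const int n0 = dv[0], n1 = dv[1], n2 = dv[2];
  const size_t nTot = (size_t)n0 * n1 * n2;
  std::vector<double> x;
  x.reserve(1024);
  for (size_t t = 0; t < nTot; ++t) if (mask[t]) x.push_back(raw[t]);
  const int n = (int)x.size();
  if (n == 0) stop("empty mask");

  // discretization: level = min(G, floor(G*(x-min)/(max-min)) + 1)
  double mn = x[0], mx = x[0];
  for (double v : x) { if (v < mn) mn = v; if (v > mx) mx = v; }
  IntegerVector levels(raw.size());
  levels.attr("dim") = dv;
  for (size_t t = 0; t < nTot; ++t) {
    if (!mask[t]) { levels[t] = 0; continue; }
    if (mx == mn) { levels[t] = 1; continue; }
    int lv = (int)std::floor(G * (raw[t] - mn) / (mx - mn)) + 1;
    if (lv > G) lv = G;
    levels[t] = lv;
  }

  NumericVector out(64);
  int o = 0;

  // ---- first order (14) ----
  double mu = 0; for (double v : x) mu += v; mu /= n;
  double m2 = 0, m3 = 0, m4 = 0, en = 0, madv = 0;
  for (double v : x) {
    const double d = v - mu;
    m2 += d * d; m3 += d * d * d; m4 += d * d * d * d;
    en += v * v; madv += std::fabs(d);
  }
  m2 /= n; m3 /= n; m4 /= n; madv /= n;
  std::vector<double> hist(G, 0.0);
  for (size_t t = 0; t < nTot; ++t) if (levels[t] > 0) hist[levels[t] - 1] += 1.0;
  double fentropy = 0, funif = 0;
  for (int g = 0; g < G; ++g) {
    const double p = hist[g] / n;
    if (p > 0) { fentropy -= p * std::log2(p); funif += p * p; }
  }
  out[o++] = mu;                                        // mean
  out[o++] = quantile7(x, 0.5);                         // median
  out[o++] = mn;                                        // min
  out[o++] = mx;                                        // max
  out[o++] = mx - mn;                                   // range
  out[o++] = m2;                                        // variance
  out[o++] = m2 > 0 ? m3 / std::pow(m2, 1.5) : 0.0;     // skewness
  out[o++] = m2 > 0 ? m4 / (m2 * m2) - 3.0 : 0.0;       // kurtosis (excess)
  out[o++] = en;                                        // energy
  out[o++] = fentropy;                                  // entropy
  out[o++] = std::sqrt(en / n);                         // rms
  out[o++] = madv;                                      // mad
  out[o++] = funif;                                     // uniformity
  out[o++] = quantile7(x, 0.75) - quantile7(x, 0.25);   // iqr

  // ---- GLCM (13) ----
  std::vector<double> P((size_t)G * G, 0.0);
  double tot = 0;
  for (int d = 0; d < 13; ++d) {
    const int dx = DIRS13[d][0], dy = DIRS13[d][1], dz = DIRS13[d][2];
    for (int k = 0; k < n2; ++k) for (int j = 0; j < n1; ++j) for (int i = 0; i < n0; ++i) {
      const int a = levels[idx3(i, j, k, n0, n1)];
      if (a == 0) continue;
      const int i2 = i + dx, j2 = j + dy, k2 = k + dz;
      if (i2 < 0 || i2 >= n0 || j2 < 0 || j2 >= n1 || k2 < 0 || k2 >= n2) continue;
      const int b = levels[idx3(i2, j2, k2, n0, n1)];
      if (b == 0) continue;
      P[(a - 1) + (size_t)G * (b - 1)] += 1.0;
      P[(b - 1) + (size_t)G * (a - 1)] += 1.0;
      tot += 2.0;
    }
  }
  if (tot == 0) stop("degenerate ROI: no in-mask voxel pairs");
  for (double &v : P) v /= tot;
  std::vector<double> px(G, 0.0);
  for (int a = 0; a < G; ++a) for (int b = 0; b < G; ++b) px[a] += P[a + (size_t)G * b];
  double mux = 0; for (int a = 0; a < G; ++a) mux += (a + 1) * px[a];
  double varx = 0; for (int a = 0; a < G; ++a) varx += (a + 1 - mux) * (a + 1 - mux) * px[a];
  double contrast = 0, dissim = 0, homog = 0, asm_ = 0, gent = 0, sij = 0,
         shade = 0, prom = 0, maxp = 0, idn = 0;
  std::vector<double> psum(2 * G + 1, 0.0), pdif(G, 0.0);
  for (int a = 0; a < G; ++a) for (int b = 0; b < G; ++b) {
    const double p = P[a + (size_t)G * b];
    const int ia = a + 1, jb = b + 1;
    const double dd = ia - jb, ss = ia + jb - 2 * mux;
    contrast += dd * dd * p;
    dissim += std::fabs(dd) * p;
    homog += p / (1.0 + dd * dd);
    asm_ += p * p;
    if (p > 0) gent -= p * std::log2(p);
    sij += (double)ia * jb * p;
    shade += ss * ss * ss * p;
    prom += ss * ss * ss * ss * p;
    if (p > maxp) maxp = p;
    idn += p / (1.0 + std::fabs(dd) / G);
    psum[ia + jb] += p;
    pdif[(int)std::fabs(dd)] += p;
  }
  double sumavg = 0, sument = 0, difent = 0;
  for (int k = 2; k <= 2 * G; ++k) {
    sumavg += k * psum[k];
    if (psum[k] > 0) sument -= psum[k] * std::log2(psum[k]);
  }
  for (int k = 0; k < G; ++k)
    if (pdif[k] > 0) difent -= pdif[k] * std::log2(pdif[k]);
  out[o++] = contrast;
  out[o++] = dissim;
  out[o++] = homog;
  out[o++] = asm_;
  out[o++] = gent;
  out[o++] = varx > 0 ? (sij - mux * mux) / varx : 1.0;  // correlation
  out[o++] = shade;
  out[o++] = prom;
  out[o++] = maxp;
  out[o++] = sumavg;
  out[o++] = sument;
  out[o++] = difent;
  out[o++] = idn;

  // ---- GLRLM (16), averaged over the 13 directions ----
  double acc[16] = {0};
  std::vector<std::vector<double>> rl(G);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIRS13[d][0], dy = DIRS13[d][1], dz = DIRS13[d][2];
    for (int g = 0; g < G; ++g) rl[g].clear();
    int maxRun = 1;
    for (int k = 0; k < n2; ++k) for (int j = 0; j < n1; ++j) for (int i = 0; i < n0; ++i) {
      const int a = levels[idx3(i, j, k, n0, n1)];
      if (a == 0) continue;
      const int pi = i - dx, pj = j - dy, pk = k - dz;
      if (pi >= 0 && pi < n0 && pj >= 0 && pj < n1 && pk >= 0 && pk < n2 &&
          levels[idx3(pi, pj, pk, n0, n1)] == a) continue;
      int len = 1, ci = i + dx, cj = j + dy, ck = k + dz;
      while (ci >= 0 && ci < n0 && cj >= 0 && cj < n1 && ck >= 0 && ck < n2 &&
             levels[idx3(ci, cj, ck, n0, n1)] == a) { ++len; ci += dx; cj += dy; ck += dz; }
      if (len > maxRun) maxRun = len;
      if ((int)rl[a - 1].size() < len) rl[a - 1].resize(len, 0.0);
      rl[a - 1][len - 1] += 1.0;
    }
    double Nr = 0;
    std::vector<double> rowS(G, 0.0), colS(maxRun, 0.0);
    for (int g = 0; g < G; ++g) for (size_t r = 0; r < rl[g].size(); ++r) {
      Nr += rl[g][r]; rowS[g] += rl[g][r]; colS[r] += rl[g][r];
    }
    double sre = 0, lre = 0, gln = 0, rln = 0, glvMu = 0, rvMu = 0, re = 0,
           lglre = 0, hglre = 0, srl = 0, srh = 0, lrl = 0, lrh = 0;
    for (int g = 0; g < G; ++g) {
      gln += rowS[g] * rowS[g];
      const double gi = g + 1;
      lglre += rowS[g] / (gi * gi);
      hglre += rowS[g] * gi * gi;
    }
    for (int r = 0; r < maxRun; ++r) {
      rln += colS[r] * colS[r];
      const double rj = r + 1;
      sre += colS[r] / (rj * rj);
      lre += colS[r] * rj * rj;
    }
    for (int g = 0; g < G; ++g) for (size_t r = 0; r < rl[g].size(); ++r) {
      const double c = rl[g][r];
      if (c == 0) continue;
      const double gi = g + 1, rj = (double)r + 1, p = c / Nr;
      glvMu += p * gi; rvMu += p * rj;
      re -= p * std::log2(p);
      srl += c / (gi * gi * rj * rj);
      srh += c * gi * gi / (rj * rj);
      lrl += c * rj * rj / (gi * gi);
      lrh += c * gi * gi * rj * rj;
    }
    double glv = 0, rv = 0;
    for (int g = 0; g < G; ++g) for (size_t r = 0; r < rl[g].size(); ++r) {
      const double p = rl[g][r] / Nr;
      if (p == 0) continue;
      glv += p * (g + 1 - glvMu) * (g + 1 - glvMu);
      rv += p * ((double)r + 1 - rvMu) * ((double)r + 1 - rvMu);
    }
    acc[0] += sre / Nr;  acc[1] += lre / Nr;
    acc[2] += gln / Nr;  acc[3] += gln / (Nr * Nr);
    acc[4] += rln / Nr;  acc[5] += rln / (Nr * Nr);
    acc[6] += Nr / n;    acc[7] += glv;  acc[8] += rv;  acc[9] += re;
    acc[10] += lglre / Nr; acc[11] += hglre / Nr;
    acc[12] += srl / Nr;  acc[13] += srh / Nr;
    acc[14] += lrl / Nr;  acc[15] += lrh / Nr;
  }
  for (int q = 0; q < 16; ++q) out[o++] = acc[q] / 13.0;

  // ---- GLSZM (16) ----
  {
    std::vector<char> seen(nTot, 0);
    std::vector<std::vector<double>> zs(G);
    std::vector<int> stack;
    int maxZone = 1;
    for (size_t s = 0; s < nTot; ++s) {
      const int lev = levels[s];
      if (lev == 0 || seen[s]) continue;
      int size = 0;
      stack.clear(); stack.push_back((int)s); seen[s] = 1;
      while (!stack.empty()) {
        const int cur = stack.back(); stack.pop_back();
        ++size;
        const int ci = cur % n0, cj = (cur / n0) % n1, ck = cur / (n0 * n1);
        for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          const int i2 = ci + dx, j2 = cj + dy, k2 = ck + dz;
          if (i2 < 0 || i2 >= n0 || j2 < 0 || j2 >= n1 || k2 < 0 || k2 >= n2) continue;
          const int t = idx3(i2, j2, k2, n0, n1);
          if (!seen[t] && levels[t] == lev) { seen[t] = 1; stack.push_back(t); }
        }
      }
      if (size > maxZone) maxZone = size;
      if ((int)zs[lev - 1].size() < size) zs[lev - 1].resize(size, 0.0);
      zs[lev - 1][size - 1] += 1.0;
    }
    double Nz = 0;
    std::vector<double> rowS(G, 0.0), colS(maxZone, 0.0);
    for (int g = 0; g < G; ++g) for (size_t z = 0; z < zs[g].size(); ++z) {
      Nz += zs[g][z]; rowS[g] += zs[g][z]; colS[z] += zs[g][z];
    }
    double sae = 0, lae = 0, gln = 0, szn = 0, muG = 0, muS = 0, ze = 0,
           lgl = 0, hgl = 0, sal = 0, sah = 0, lal = 0, lah = 0;
    for (int g = 0; g < G; ++g) {
      gln += rowS[g] * rowS[g];
      const double gi = g + 1;
      lgl += rowS[g] / (gi * gi);
      hgl += rowS[g] * gi * gi;
    }
    for (int z = 0; z < maxZone; ++z) {
      szn += colS[z] * colS[z];
      const double sj = z + 1;
      sae += colS[z] / (sj * sj);
      lae += colS[z] * sj * sj;
    }
    for (int g = 0; g < G; ++g) for (size_t z = 0; z < zs[g].size(); ++z) {
      const double c = zs[g][z];
      if (c == 0) continue;
      const double gi = g + 1, sj = (double)z + 1, p = c / Nz;
      muG += p * gi; muS += p * sj;
      ze -= p * std::log2(p);
      sal += c / (gi * gi * sj * sj);
      sah += c * gi * gi / (sj * sj);
      lal += c * sj * sj / (gi * gi);
      lah += c * gi * gi * sj * sj;
    }
    double glv = 0, zv = 0;
    for (int g = 0; g < G; ++g) for (size_t z = 0; z < zs[g].size(); ++z) {
      const double p = zs[g][z] / Nz;
      if (p == 0) continue;
      glv += p * (g + 1 - muG) * (g + 1 - muG);
      zv += p * ((double)z + 1 - muS) * ((double)z + 1 - muS);
    }
    out[o++] = sae / Nz;  out[o++] = lae / Nz;
    out[o++] = gln / Nz;  out[o++] = gln / (Nz * Nz);
    out[o++] = szn / Nz;  out[o++] = szn / (Nz * Nz);
    out[o++] = Nz / n;    out[o++] = glv;  out[o++] = zv;  out[o++] = ze;
    out[o++] = lgl / Nz;  out[o++] = hgl / Nz;
    out[o++] = sal / Nz;  out[o++] = sah / Nz;
    out[o++] = lal / Nz;  out[o++] = lah / Nz;
  }

  // ---- NGTDM (5), Amadasun-King with eps = 1e-6 guard ----
  {
    const double EPS = 1e-6;
    std::vector<double> ni(G, 0.0), si(G, 0.0);
    for (int k = 0; k < n2; ++k) for (int j = 0; j < n1; ++j) for (int i = 0; i < n0; ++i) {
      const int a = levels[idx3(i, j, k, n0, n1)];
      if (a == 0) continue;
      double sum = 0; int cnt = 0;
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int i2 = i + dx, j2 = j + dy, k2 = k + dz;
        if (i2 < 0 || i2 >= n0 || j2 < 0 || j2 >= n1 || k2 < 0 || k2 >= n2) continue;
        const int b = levels[idx3(i2, j2, k2, n0, n1)];
        if (b > 0) { sum += b; ++cnt; }
      }
      if (cnt == 0) continue;
      ni[a - 1] += 1.0;
      si[a - 1] += std::fabs((double)a - sum / cnt);
    }
    double Nv = 0; for (int g = 0; g < G; ++g) Nv += ni[g];
    std::vector<int> act;
    for (int g = 0; g < G; ++g) if (ni[g] > 0) act.push_back(g);
    const int Ngp = (int)act.size();
    double ps = 0, sSum = 0;
    for (int g : act) { ps += (ni[g] / Nv) * si[g]; sSum += si[g]; }
    double coarse = ps > EPS ? 1.0 / ps : 1.0 / EPS;
    double contr = 0, busyDen = 0, cmplx = 0, strength = 0;
    for (int ai = 0; ai < Ngp; ++ai) for (int bi = 0; bi < Ngp; ++bi) {
      const int ga = act[ai], gb = act[bi];
      const double pa = ni[ga] / Nv, pb = ni[gb] / Nv;
      const double dg = (ga + 1) - (gb + 1);
      contr += pa * pb * dg * dg;
      busyDen += std::fabs((ga + 1) * pa - (gb + 1) * pb);
      cmplx += std::fabs(dg) * (pa * si[ga] + pb * si[gb]) / (pa + pb);
      strength += (pa + pb) * dg * dg;
    }
    double contrast5 = Ngp > 1 ? (contr / (Ngp * (Ngp - 1))) * (sSum / Nv) : 0.0;
    double busy = busyDen > EPS ? ps / busyDen : 0.0;
    double cplx = Ngp > 1 ? cmplx / Nv : 0.0;
    double stren = sSum > EPS ? strength / sSum : 0.0;
    out[o++] = coarse; out[o++] = contrast5; out[o++] = busy;
    out[o++] = cplx;   out[o++] = stren;
  }
  return out;
}
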