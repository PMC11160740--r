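#include <Rcpp.h>
using namespace Rcpp;

// Trilinear sampling of a cubic grid at arbitrary fractional coordinates.
// vol: L*L*L array (column-major, first index fastest). coords: M x 3 matrix
// of grid coordinates in [0, L-1]; points outside the grid return `fill`.
// Used to slice gridded Hartley volumes along rotated central planes and to
// resample real-space volumes in the projection oracle.
// [[Rcpp::export(name = ".trilinear_cpp")]]
NumericVector trilinear_cpp(NumericVector vol, int L, NumericMatrix coords,
                            double fill = 0.0) {
  const int M = coords.nrow();
  NumericVector out(M);
  const double *v = vol.begin();
  const long LL = (long)L * L;
  for (int i = 0; i < M; ++i) {
    double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    if (x < 0 || y < 0 || z < 0 || x > L - 1 || y > L - 1 || z > L - 1) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == L - 1) x0--;
    if (y0 == L - 1) y0--;
    if (z0 == L - 1) z0--;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    const double *p = v + (long)x0 + (long)y0 * L + (long)z0 * LL;
    double c00 = p[0] * (1 - fx) + p[1] * fx;
    double c10 = p[L] * (1 - fx) + p[L + 1] * fx;
    double c01 = p[LL] * (1 - fx) + p[LL + 1] * fx;
    double c11 = p[LL + L] * (1 - fx) + p[LL + L + 1] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Squared reprojection errors over a rotation x translation candidate grid.
// A, B: R x K matrices (CTF-weighted slice values at k and at -k);
// I: length-K image Hartley coefficients; Ct, St: K x T cos/sin translation
// phase tables. Returns the R x T error matrix
//   E[r,t] = sum_k (I_k - (Ct[k,t] A[r,k] + St[k,t] B[r,k]))^2.
// [[Rcpp::export(name = ".pose_errors_cpp")]]
NumericMatrix pose_errors_cpp(NumericMatrix A, NumericMatrix B,
                              NumericVector I, NumericMatrix Ct,
                              NumericMatrix St) {
  const int R = A.nrow(), K = A.ncol(), T = Ct.ncol();
  NumericMatrix E(R, T);
  // loop order keeps the r-contiguous columns of A/B and E in cache
  for (int t = 0; t < T; ++t) {
    double *e = &E(0, t);
    for (int k = 0; k < K; ++k) {
      const double ct = Ct(k, t), st = St(k, t), ik = I[k];
      const double *a = &A(0, k), *b = &B(0, k);
      for (int r = 0; r < R; ++r) {
        double d = ik - ct * a[r] - st * b[r];
        e[r] += d * d;
      }
    }
  }
  return E;
}
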