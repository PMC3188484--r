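#include <Rcpp.h>
using namespace Rcpp;

// Half-sample symmetric reflection: pixel -1 maps to 0, pixel L maps to L-1.
// Matches the rasterizer's continuous-coordinate mirror rule at integer sites.
static inline int reflect_idx(int i, int L) {
  while (i < 0 || i >= L) {
    if (i < 0) i = -1 - i;
    else i = 2 * L - 1 - i;
  }
  return i;
}

// Cross-correlation (no kernel flip) of a single-channel image with a stack of
// centered square kernels, mirror-padded borders.
// image: L x L matrix; kernels: E x E x K array (E odd).
// [[Rcpp::export]]
NumericVector conv2_mirror_cpp(const NumericMatrix& image,
                               const NumericVector& kernels) {
  IntegerVector kd = kernels.attr("dim");
  if (kd.size() != 3) stop("kernels must be an E x E x K array");
  const int E = kd[0], K = kd[2];
  if (kd[1] != E || E % 2 == 0) stop("kernels must be square with odd extent");
  const int L = image.nrow();
  const int M = image.ncol();
  const int h = (E - 1) / 2;

  NumericVector out(static_cast<R_xlen_t>(L) * M * K);
  out.attr("dim") = IntegerVector::create(L, M, K);
  const double* img = REAL(image);
  const double* ker = REAL(kernels);
  double* o = REAL(out);

  std::vector<int> ry(L + 2 * h), rx(M + 2 * h);
  for (int i = 0; i < L + 2 * h; ++i) ry[i] = reflect_idx(i - h, L);
  for (int j = 0; j < M + 2 * h; ++j) rx[j] = reflect_idx(j - h, M);

  for (int k = 0; k < K; ++k) {
    const double* Kk = ker + static_cast<R_xlen_t>(k) * E * E;
    double* Ok = o + static_cast<R_xlen_t>(k) * L * M;
    for (int x = 0; x < M; ++x) {
      for (int y = 0; y < L; ++y) {
        double acc = 0.0;
        for (int v = 0; v < E; ++v) {
          const int xc = rx[x + v];
          const double* col = img + static_cast<R_xlen_t>(xc) * L;
          const double* kcol = Kk + v * E;
          for (int u = 0; u < E; ++u) acc += kcol[u] * col[ry[y + u]];
        }
        Ok[x * L + y] = acc;
      }
    }
  }
  return out;
}

// Same cross-correlation, but scattering from nonzero image pixels only —
// much faster for sparse binary line drawings. Mirror replicas of each
// source pixel reproduce the mirror-padded read exactly.
// [[Rcpp::export]]
NumericVector conv2_mirror_sparse_cpp(const NumericMatrix& image,
                                      const NumericVector& kernels) {
  IntegerVector kd = kernels.attr("dim");
  if (kd.size() != 3) stop("kernels must be an E x E x K array");
  const int E = kd[0], K = kd[2];
  if (kd[1] != E || E % 2 == 0) stop("kernels must be square with odd extent");
  const int L = image.nrow();
  const int M = image.ncol();
  const int h = (E - 1) / 2;

  NumericVector out(static_cast<R_xlen_t>(L) * M * K);
  out.attr("dim") = IntegerVector::create(L, M, K);
  const double* img = REAL(image);
  const double* ker = REAL(kernels);
  double* o = REAL(out);

  auto replicas = [h](int c, int n, int* buf) {
    int m = 0;
    buf[m++] = c;
    const int lo = -h, hi = n - 1 + h;
    int r1 = -1 - c;
    int r2 = 2 * n - 1 - c;
    if (r1 >= lo && r1 <= hi && r1 != c) buf[m++] = r1;
    if (r2 >= lo && r2 <= hi && r2 != c) buf[m++] = r2;
    return m;
  };

  int bx[3], by[3];
  for (int xs = 0; xs < M; ++xs) {
    for (int ys = 0; ys < L; ++ys) {
      const double a = img[xs * L + ys];
      if (a == 0.0) continue;
      const int nx = replicas(xs, M, bx);
      const int ny = replicas(ys, L, by);
      for (int rx = 0; rx < nx; ++rx) {
        const int px = bx[rx];
        const int x0 = std::max(0, px - h), x1 = std::min(M - 1, px + h);
        for (int ryi = 0; ryi < ny; ++ryi) {
          const int py = by[ryi];
          const int y0 = std::max(0, py - h), y1 = std::min(L - 1, py + h);
          for (int k = 0; k < K; ++k) {
            const double* Kk = ker + static_cast<R_xlen_t>(k) * E * E;
            double* Ok = o + static_cast<R_xlen_t>(k) * L * M;
            for (int x = x0; x <= x1; ++x) {
              const double* kcol = Kk + (px - x + h) * E;
              double* ocol = Ok + static_cast<R_xlen_t>(x) * L;
              for (int y = y0; y <= y1; ++y)
                ocol[y] += a * kcol[(py - y) + h];
            }
          }
        }
      }
    }
  }
  return out;
}

// Pairwise coactivation statistics of suprathreshold elements.
// field: L x L x T array (post-transfer activities; suprathreshold = > 0).
// Returns D x D x T x T counts, D = 2R+1, indexed [dy+R, dx+R, theta_rel,
// theta_center]; both orderings of each pair are accumulated; the exact
// self-pair is excluded; Euclidean cutoff |delta| <= R.
// weighted: add a_c * a_e instead of 1.
// [[Rcpp::export]]
NumericVector accumulate_pairs_cpp(const NumericVector& field, int R,
                                   bool weighted) {
  IntegerVector fd = field.attr("dim");
  if (fd.size() != 3) stop("field must be an L x L x T array");
  const int L = fd[0], M = fd[1], T = fd[2];
  const int D = 2 * R + 1;
  const double* f = REAL(field);

  // compact per-pixel lists of active orientations
  std::vector<int> start(static_cast<size_t>(L) * M + 1, 0);
  for (int t = 0; t < T; ++t) {
    const double* ft = f + static_cast<R_xlen_t>(t) * L * M;    for (int p = 0; p < L * M; ++p)
      if (ft[p] > 0.0) ++start[p + 1];
  }
  for (size_t p = 1; p < start.size(); ++p) start[p] += start[p - 1];
  const int n_active = start[static_cast<size_t>(L) * M];
  std::vector<int> ori(n_active);
  std::vector<double> act(n_active);
  {
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int t = 0; t < T; ++t) {
      const double* ft = f + static_cast<R_xlen_t>(t) * L * M;
      for (int p = 0; p < L * M; ++p)
        if (ft[p] > 0.0) { ori[fill[p]] = t; act[fill[p]] = ft[p]; ++fill[p]; }
    }
  }

  NumericVector counts(static_cast<R_xlen_t>(D) * D * T * T);
  counts.attr("dim") = IntegerVector::create(D, D, T, T);
  double* C = REAL(counts);
  const long long R2 = static_cast<long long>(R) * R;

  for (int xc = 0; xc < M; ++xc) {
    for (int yc = 0; yc < L; ++yc) {
      const int pc = xc * L + yc;
      if (start[pc] == start[pc + 1]) continue;
      const int xlo = std::max(0, xc - R), xhi = std::min(M - 1, xc + R);
      const int ylo = std::max(0, yc - R), yhi = std::min(L - 1, yc + R);
      for (int ic = start[pc]; ic < start[pc + 1]; ++ic) {
        const int tc = ori[ic];
        const double ac = act[ic];
        for (int xe = xlo; xe <= xhi; ++xe) {
          const int dx = xe - xc;
          for (int ye = ylo; ye <= yhi; ++ye) {
            const int dy = ye - yc;
            if (static_cast<long long>(dx) * dx +
                static_cast<long long>(dy) * dy > R2) continue;
            const int pe = xe * L + ye;
            for (int ie = start[pe]; ie < start[pe + 1]; ++ie) {
              if (ie == ic) continue;  // exact self-pair
              int trel = ori[ie] - tc; trel %= T; if (trel < 0) trel += T;
              const R_xlen_t idx = (dy + R) +
                static_cast<R_xlen_t>(D) * (dx + R) +
                static_cast<R_xlen_t>(D) * D * trel +
                static_cast<R_xlen_t>(D) * D * T * tc;
              C[idx] += weighted ? ac * act[ie] : 1.0;
            }
          }
        }
      }
    }
  }
  return counts;
}

// Raw lateral support C(x, theta_c) = sum_{delta, theta'} K_{theta_c}(delta,
// (theta'-theta_c) mod T) * A(x+delta, theta'), mirror-padded field, computed
// by scattering from active elements (fields are sparse after thresholding).
// kernels: D x D x T x T array [dy+R, dx+R, theta_rel, theta_center].
// [[Rcpp::export]]
NumericVector lateral_support_cpp(const NumericVector& field,
                                  const NumericVector& kernels) {
  IntegerVector fd = field.attr("dim");
  IntegerVector kd = kernels.attr("dim");
  if (fd.size() != 3) stop("field must be an L x L x T array");
  if (kd.size() != 4) stop("kernels must be a D x D x T x T array");
  const int L = fd[0], M = fd[1], T = fd[2];
  if (kd[2] != T || kd[3] != T)
    stop("kernel orientation count does not match field");
  const int D = kd[0];
  if (kd[1] != D || D % 2 == 0) stop("kernel table must be square, odd extent");
  const int R = (D - 1) / 2;

  NumericVector out(static_cast<R_xlen_t>(L) * M * T);
  out.attr("dim") = IntegerVector::create(L, M, T);
  const double* f = REAL(field);
  const double* K = REAL(kernels);
  double* o = REAL(out);

  // mirror replicas of a coordinate lying within the padded window [-R, L-1+R]
  auto replicas = [R](int c, int n, int* buf) {
    int m = 0;
    buf[m++] = c;
    const int lo = -R, hi = n - 1 + R;
    int r1 = -1 - c;            // reflection across low edge
    int r2 = 2 * n - 1 - c;     // reflection across high edge
    if (r1 >= lo && r1 <= hi && r1 != c) buf[m++] = r1;
    if (r2 >= lo && r2 <= hi && r2 != c) buf[m++] = r2;
    return m;
  };

  int bx[3], by[3];
  for (int t = 0; t < T; ++t) {
    const double* ft = f + static_cast<R_xlen_t>(t) * L * M;
    for (int xs = 0; xs < M; ++xs) {
      for (int ys = 0; ys < L; ++ys) {
        const double a = ft[xs * L + ys];
        if (a <= 0.0) continue;
        const int nx = replicas(xs, M, bx);
        const int ny = replicas(ys, L, by);
        for (int rx = 0; rx < nx; ++rx) {
          const int px = bx[rx];
          const int x0 = std::max(0, px - R), x1 = std::min(M - 1, px + R);
          for (int ryi = 0; ryi < ny; ++ryi) {
            const int py = by[ryi];
            const int y0 = std::max(0, py - R), y1 = std::min(L - 1, py + R);
            for (int tc = 0; tc < T; ++tc) {
              int trel = t - tc; trel %= T; if (trel < 0) trel += T;
              const double* Kt = K + static_cast<R_xlen_t>(D) * D *
                (trel + static_cast<R_xlen_t>(T) * tc);
              double* ot = o + static_cast<R_xlen_t>(tc) * L * M;
              // target position x = p - delta  =>  delta = p - x
              for (int x = x0; x <= x1; ++x) {
                const int dx = px - x;
                const double* kcol = Kt + static_cast<R_xlen_t>(D) * (dx + R);
                double* ocol = ot + static_cast<R_xlen_t>(x) * L;
                for (int y = y0; y <= y1; ++y)
                  ocol[y] += a * kcol[(py - y) + R];
              }
            }
          }
        }
      }
    }
  }
  return out;
}
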