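// Fused kernels for one multi-head attention layer. The R implementation
// of the same math (engine = "r" in gat_layer_forward/_backward) is the
// reference the test suite compares against; these kernels exist because
// the per-edge elementwise work on E x (K*Fo) matrices is allocation- and
// cache-bound in R. Internally everything is stored feature-major
// (features x nodes / features x edges) so per-node and per-edge inner
// loops touch contiguous memory; the heavy matrix products go through
// BLAS.
#include <Rcpp.h>
#define USE_FC_LEN_T
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {
inline double lrelu(double x, double s) { return x > 0 ? x : s * x; }
inline double dlrelu(double x, double s) { return x > 0 ? 1.0 : s; }

// C (m x n) = op(A) %*% op(B), column-major
void gemm(bool ta, bool tb, int m, int n, int k, const double* A, int lda,
          const double* B, int ldb, double* C, int ldc) {
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)(ta ? "T" : "N", tb ? "T" : "N", &m, &n, &k, &one, A, &lda,
                  B, &ldb, &zero, C, &ldc FCONE FCONE);
}
}

// [[Rcpp::export(name = ".gat_fwd")]]
List gat_fwd(NumericMatrix H, NumericMatrix Wall, NumericVector a_src,
             NumericVector a_dst, IntegerVector src, IntegerVector dst,
             int K, int fo, bool concat, double attn_slope,
             double act_slope) {
  const int n = H.nrow(), fin = H.ncol(), kfo = K * fo;
  const int E = src.size();
  if (Wall.nrow() != kfo || Wall.ncol() != fin)
    stop("stacked weight matrix has wrong shape");

  // Zt(j, i) = (W h_i)_j
  NumericMatrix Zt(kfo, n);
  gemm(false, true, kfo, n, fin, Wall.begin(), kfo, H.begin(), n,
       Zt.begin(), kfo);

  // attention scorer halves, per node: s_src(k, i), s_dst(k, i)
  NumericMatrix s_src(K, n), s_dst(K, n);
  for (int i = 0; i < n; ++i) {
    const double* z = &Zt(0, i);
    for (int k = 0; k < K; ++k) {
      double as = 0.0, ad = 0.0;
      const int off = k * fo;
      for (int f = 0; f < fo; ++f) {
        as += z[off + f] * a_src[off + f];
        ad += z[off + f] * a_dst[off + f];
      }
      s_src(k, i) = as;
      s_dst(k, i) = ad;
    }
  }

  NumericMatrix rawt(K, E), alphat(K, E);
  NumericMatrix mx(K, n), denom(K, n);
  std::fill(mx.begin(), mx.end(), -std::numeric_limits<double>::infinity());
  for (int e = 0; e < E; ++e) {
    const int i = src[e] - 1, h = dst[e] - 1;
    for (int k = 0; k < K; ++k) {
      const double r = s_src(k, i) + s_dst(k, h);
      rawt(k, e) = r;
      const double lg = lrelu(r, attn_slope);
      alphat(k, e) = lg;                     // holds the logit for now
      if (lg > mx(k, i)) mx(k, i) = lg;
    }
  }
  for (int e = 0; e < E; ++e) {
    const int i = src[e] - 1;
    for (int k = 0; k < K; ++k) {
      const double x = std::exp(alphat(k, e) - mx(k, i));
      alphat(k, e) = x;
      denom(k, i) += x;
    }
  }
  for (int e = 0; e < E; ++e) {
    const int i = src[e] - 1;
    for (int k = 0; k < K; ++k) alphat(k, e) /= denom(k, i);
  }

  // neighbourhood aggregation
  NumericMatrix Maggt(kfo, n);
  for (int e = 0; e < E; ++e) {
    const int i = src[e] - 1, h = dst[e] - 1;
    double* mcol = &Maggt(0, i);
    const double* zcol = &Zt(0, h);
    for (int k = 0; k < K; ++k) {
      const double a = alphat(k, e);
      const int off = k * fo;
      for (int f = 0; f < fo; ++f) mcol[off + f] += a * zcol[off + f];
    }
  }

  const int out = concat ? kfo : fo;
  NumericMatrix Ut(out, n), Hout(n, out);
  for (int i = 0; i < n; ++i) {
    if (concat) {
      for (int j = 0; j < kfo; ++j) Ut(j, i) = Maggt(j, i);
    } else {
      for (int f = 0; f < fo; ++f) {
        double acc = 0.0;
        for (int k = 0; k < K; ++k) acc += Maggt(k * fo + f, i);
        Ut(f, i) = acc / K;
      }
    }
    for (int j = 0; j < out; ++j) Hout(i, j) = lrelu(Ut(j, i), act_slope);
  }

  return List::create(_["H"] = Hout, _["Zt"] = Zt, _["rawt"] = rawt,
                      _["alphat"] = alphat, _["Ut"] = Ut);
}

// [[Rcpp::export(name = ".gat_bwd")]]
List gat_bwd(NumericMatrix dHout, NumericMatrix Hin, NumericMatrix Zt,
             NumericMatrix rawt, NumericMatrix alphat, NumericMatrix Ut,
             NumericMatrix Wall, NumericVector a_src, NumericVector a_dst,
             IntegerVector src, IntegerVector dst, int K, int fo,
             bool concat, double attn_slope, double act_slope) {
  const int n = Hin.nrow(), fin = Hin.ncol(), kfo = K * fo;
  const int E = src.size();

  NumericMatrix dMaggt(kfo, n);
  for (int i = 0; i < n; ++i) {
    if (concat) {
      for (int j = 0; j < kfo; ++j)
        dMaggt(j, i) = dHout(i, j) * dlrelu(Ut(j, i), act_slope);
    } else {
      for (int f = 0; f < fo; ++f) {
        const double du = dHout(i, f) * dlrelu(Ut(f, i), act_slope) / K;
        for (int k = 0; k < K; ++k) dMaggt(k * fo + f, i) = du;
      }
    }
  }

  // edge pass: attention gradient plus aggregation path into dZt
  NumericMatrix dalphat(K, E), dZt(kfo, n);
  for (int e = 0; e < E; ++e) {
    const int i = src[e] - 1, h = dst[e] - 1;
    const double* dm = &dMaggt(0, i);
    const double* z = &Zt(0, h);
    double* dz = &dZt(0, h);
    for (int k = 0; k < K; ++k) {
      const int off = k * fo;
      const double a = alphat(k, e);
      double da = 0.0;
      for (int f = 0; f < fo; ++f) {
        da += dm[off + f] * z[off + f];
        dz[off + f] += dm[off + f] * a;
      }
      dalphat(k, e) = da;
    }
  }

  NumericMatrix srow(K, n), ds_src(K, n), ds_dst(K, n);
  for (int e = 0; e < E; ++e) {
    const int i = src[e] - 1;
    for (int k = 0; k < K; ++k)
      srow(k, i) += alphat(k, e) * dalphat(k, e);
  }
  for (int e = 0; e < E; ++e) {
    const int i = src[e] - 1, h = dst[e] - 1;
    for (int k = 0; k < K; ++k) {
      const double de = alphat(k, e) * (dalphat(k, e) - srow(k, i));
      const double dl = de * dlrelu(rawt(k, e), attn_slope);
      ds_src(k, i) += dl;
      ds_dst(k, h) += dl;
    }
  }

  NumericVector da_src(kfo), da_dst(kfo);
  for (int i = 0; i < n; ++i) {
    const double* z = &Zt(0, i);
    double* dz = &dZt(0, i);
    for (int k = 0; k < K; ++k) {
      const int off = k * fo;
      const double gs = ds_src(k, i), gd = ds_dst(k, i);
      for (int f = 0; f < fo; ++f) {
        const int j = off + f;
        dz[j] += gs * a_src[j] + gd * a_dst[j];
        da_src[j] += z[j] * gs;
        da_dst[j] += z[j] * gd;
      }
    }
  }

  NumericMatrix dWall(kfo, fin), dH(n, fin);
  gemm(false, false, kfo, fin, n, dZt.begin(), kfo, Hin.begin(), n,
       dWall.begin(), kfo);
  gemm(true, false, n, fin, kfo, dZt.begin(), kfo, Wall.begin(), kfo,
       dH.begin(), n);

  return List::create(_["dWall"] = dWall, _["da_src"] = da_src,
                      _["da_dst"] = da_dst, _["dH"] = dH);
}
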