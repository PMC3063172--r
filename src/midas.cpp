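#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3D connected-component labelling on a flat 0/1 mask.
// dims = c(nx, ny, nz); connectivity 6 (faces) or 26 (faces+edges+corners).
// Returns integer labels (0 = background), components numbered from 1 in
// first-encounter (column-major scan) order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  // neighbour offsets in ijk
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  const int nn = (int)di.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int k = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v - (R_xlen_t)k * nx * ny);
      int j = rem / nx;
      int i = rem - j * nx;
      for (int m = 0; m < nn; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
        if (mask[w] != 0 && labels[w] == 0) {
          labels[w] = next_label;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}

// One E-step of the prior-weighted mixture, fused with the accumulation of
// the sufficient statistics used by the M-step.
//
// y        : bias-corrected intensities at the active voxels (length n)
// logprior : n x K matrix of per-class log prior probabilities
// cls      : 0-based class index of each Gaussian component (length J)
// logw     : log within-class mixing weight per component
// mu, s2   : component means / variances
// want_post: also return the n x K class posterior matrix
// want_tlog: also return sum_j r_j * log(mu_j) per voxel (bias-field
//            target) and the Gauss-Newton precision weight
//            sum_j r_j * mu_j^2 / s2_j for the log-domain bias fit
//
// Returns loglik (sum over voxels of log-sum-exp), N/Sy/Syy per component.
// [[Rcpp::export]]
List em_step_cpp(NumericVector y, NumericMatrix logprior, IntegerVector cls,
                 NumericVector logw, NumericVector mu, NumericVector s2,
                 bool want_post, bool want_tlog) {
  const R_xlen_t n = y.size();
  const int J = (int)cls.size();
  const int K = logprior.ncol();
  if (logprior.nrow() != n) stop("logprior rows must match length(y)");

  std::vector<double> cst(J), inv2(J), lmu(J), prec(J);
  const double l2pi = std::log(2.0 * M_PI);
  for (int j = 0; j < J; ++j) {
    cst[j] = logw[j] - 0.5 * (l2pi + std::log(s2[j]));
    inv2[j] = 0.5 / s2[j];
    lmu[j] = std::log(std::max(mu[j], 1e-12));
    prec[j] = mu[j] * mu[j] / s2[j];
  }

  NumericVector N(J), Sy(J), Syy(J);
  NumericMatrix post;
  NumericVector tlog, wprec;
  if (want_post) post = NumericMatrix(n, K);
  if (want_tlog) { tlog = NumericVector(n); wprec = NumericVector(n); }

  // responsibilities below exp(-40) are dropped (far below the numerical
  // noise of the accumulators); skipping their exp() calls dominates the
  // kernel's speed
  const double CUT = 40.0;
  double ll = 0.0;
  std::vector<double> lj(J);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double yi = y[i];
    double m = R_NegInf;
    for (int j = 0; j < J; ++j) {
      double d = yi - mu[j];
      double v = logprior(i, cls[j]) + cst[j] - d * d * inv2[j];
      lj[j] = v;
      if (v > m) m = v;
    }
    double se = 0.0;
    for (int j = 0; j < J; ++j)
      if (lj[j] > m - CUT) se += std::exp(lj[j] - m);
    double lli = m + std::log(se);
    ll += lli;
    double tl = 0.0, wp = 0.0;
    for (int j = 0; j < J; ++j) {
      if (lj[j] <= lli - CUT) continue;
      double r = std::exp(lj[j] - lli);
      N[j] += r;
      Sy[j] += r * yi;
      Syy[j] += r * yi * yi;
      if (want_post) post(i, cls[j]) += r;
      if (want_tlog) { tl += r * lmu[j]; wp += r * prec[j]; }
    }
    if (want_tlog) { tlog[i] = tl; wprec[i] = wp; }
  }

  List out = List::create(_["loglik"] = ll, _["N"] = N, _["Sy"] = Sy,
                          _["Syy"] = Syy);
  if (want_post) out["post"] = post;
  if (want_tlog) { out["tlogmu"] = tlog; out["wprec"] = wprec; }
  return out;
}
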