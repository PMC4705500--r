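// Compiled kernels for the two hot preprocessing loops: the banded
// (pentadiagonal) Whittaker solve inside airPLS, and the COW dynamic
// program.  Both are O(m) / O(segments * slack^2 * seglen) and dominate
// the preprocessing cost when run over whole fingerprint matrices.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Solve (diag(w) + lam * t(D2) %*% D2) z = w * x for the second-difference
// operator D2, via banded (bandwidth-2) Cholesky.  The system matrix is
// positive definite whenever lam > 0 and at least the two endpoint weights
// are positive (the penalty nullspace is the linear functions).
// [[Rcpp::export(name = ".whittaker_solve")]]
NumericVector whittaker_solve(NumericVector x, NumericVector w,
                              double lam) {
  const int m = x.size();
  if (w.size() != m) stop("w and x lengths differ");
  if (m < 3) stop("need length >= 3");

  // bands of A = diag(w) + lam * crossprod(D2); D2 rows: [1 -2 1]
  std::vector<double> a0(m), a1(m, 0.0), a2(m, 0.0);
  for (int i = 0; i < m; ++i) a0[i] = w[i];
  for (int k = 0; k + 2 < m; ++k) {
    a0[k]     += lam * 1.0;
    a0[k + 1] += lam * 4.0;
    a0[k + 2] += lam * 1.0;
    a1[k + 1] += lam * (-2.0);   // A[k+1, k]
    a1[k + 2] += lam * (-2.0);   // A[k+2, k+1]
    a2[k + 2] += lam * 1.0;      // A[k+2, k]
  }

  // banded Cholesky A = L L^T, L lower with bandwidth 2
  std::vector<double> l0(m), l1(m, 0.0), l2(m, 0.0);
  for (int i = 0; i < m; ++i) {
    if (i >= 2) l2[i] = a2[i] / l0[i - 2];
    if (i >= 1) {
      double s = a1[i];
      if (i >= 2) s -= l2[i] * l1[i - 1];
      l1[i] = s / l0[i - 1];
    }
    double s = a0[i];
    if (i >= 1) s -= l1[i] * l1[i];
    if (i >= 2) s -= l2[i] * l2[i];
    if (s <= 0) stop("banded Cholesky failed: system not positive definite");
    l0[i] = std::sqrt(s);
  }

  // forward then backward substitution on b = w * x
  std::vector<double> u(m);
  for (int i = 0; i < m; ++i) {
    double s = w[i] * x[i];
    if (i >= 1) s -= l1[i] * u[i - 1];
    if (i >= 2) s -= l2[i] * u[i - 2];
    u[i] = s / l0[i];
  }
  NumericVector z(m);
  for (int i = m - 1; i >= 0; --i) {
    double s = u[i];
    if (i + 1 < m) s -= l1[i + 1] * z[i + 1];
    if (i + 2 < m) s -= l2[i + 2] * z[i + 2];
    z[i] = s / l0[i];
  }
  return z;
}

static inline double interp_at(const NumericVector& y, double pos) {
  // linear interpolation on the 1-based index grid, clamped to the ends
  const int m = y.size();
  if (pos <= 1.0) return y[0];
  if (pos >= (double)m) return y[m - 1];
  int i0 = (int)std::floor(pos);
  double f = pos - i0;
  if (f == 0.0) return y[i0 - 1];
  return y[i0 - 1] * (1.0 - f) + y[i0] * f;
}

// Pearson correlation of an interpolated sample stretch against a
// reference segment; constant stretches count as uninformative (0).
static double seg_score(const NumericVector& sample,
                        const NumericVector& reference,
                        int ref_from, int ref_to,
                        double smp_from, double smp_to) {
  const int L = ref_to - ref_from + 1;
  const double step = (smp_to - smp_from) / (L - 1);
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  for (int i = 0; i < L; ++i) {
    double xv = interp_at(sample, smp_from + step * i);
    double yv = reference[ref_from - 1 + i];
    sx += xv; sy += yv; sxx += xv * xv; syy += yv * yv; sxy += xv * yv;
  }
  double vx = sxx - sx * sx / L, vy = syy - sy * sy / L;
  if (vx <= 0 || vy <= 0) return 0.0;
  // multiply square roots, not the product: vx * vy can underflow for
  // near-constant (detector-floor) segments and blow the ratio up to Inf
  double r = (sxy - sx * sy / L) / (std::sqrt(vx) * std::sqrt(vy));
  if (!std::isfinite(r)) return 0.0;
  if (r > 1.0) r = 1.0; else if (r < -1.0) r = -1.0;
  return r;
}

// COW dynamic program: boundary shifts in [-slack, slack] (endpoints
// pinned), score = summed per-segment Pearson correlation, ties broken
// toward the smaller absolute shift by candidate ordering plus strict
// improvement.  Returns the warped sample on the reference grid.
// [[Rcpp::export(name = ".cow_warp")]]
NumericVector cow_warp(NumericVector sample, NumericVector reference,
                       IntegerVector bounds, int slack) {
  const int m = reference.size();
  const int nb = bounds.size();          // n_seg + 1 boundary positions
  if (nb < 2) stop("need at least one segment");

  // candidate shifts ordered 0, -1, 1, -2, 2, ... for tie-breaking
  std::vector<int> cand;
  cand.push_back(0);
  for (int s = 1; s <= slack; ++s) { cand.push_back(-s); cand.push_back(s); }
  const int nc = cand.size();
  std::vector<int> pos_of(2 * slack + 1);        // shift -> index in cand
  for (int c = 0; c < nc; ++c) pos_of[cand[c] + slack] = c;

  const double NEG = -1e300;
  std::vector<std::vector<double>> score(nb, std::vector<double>(nc, NEG));
  std::vector<std::vector<int>> back(nb, std::vector<int>(nc, 0));
  score[0][pos_of[slack]] = 0.0;                 // left endpoint, shift 0

  for (int b = 1; b < nb; ++b) {
    const bool last = (b == nb - 1);
    for (int ci = 0; ci < nc; ++ci) {
      int u_cur = cand[ci];
      if (last && u_cur != 0) continue;          // right endpoint pinned
      for (int cj = 0; cj < nc; ++cj) {
        int u_prev = cand[cj];
        if (b == 1 && u_prev != 0) continue;     // left endpoint pinned
        double prev = score[b - 1][cj];
        if (prev <= NEG) continue;
        double sc = prev + seg_score(sample, reference,
                                     bounds[b - 1], bounds[b],
                                     bounds[b - 1] + u_prev,
                                     bounds[b] + u_cur);
        if (sc > score[b][ci] + 1e-12) {
          score[b][ci] = sc;
          back[b][ci] = cj;
        }
      }
    }
  }

  // trace back from the pinned right endpoint
  std::vector<int> path(nb);
  if (score[nb - 1][pos_of[slack]] <= NEG) stop("no admissible warping path");
  std::vector<int> idx(nb);
  idx[nb - 1] = pos_of[slack];
  for (int b = nb - 1; b >= 1; --b) idx[b - 1] = back[b][idx[b]];
  for (int b = 0; b < nb; ++b) path[b] = cand[idx[b]];

  NumericVector out(m);
  for (int b = 1; b < nb; ++b) {
    int from = bounds[b - 1], to = bounds[b];
    int L = to - from + 1;
    double s_from = from + path[b - 1], s_to = to + path[b];
    double step = (s_to - s_from) / (L - 1);
    for (int i = 0; i < L; ++i)
      out[from - 1 + i] = interp_at(sample, s_from + step * i);
  }
  return out;
}
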