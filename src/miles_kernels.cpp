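#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Column-wise minimum of (v[i] - 2*A[i][j]) over rows i.
// Used to reduce a bag's instance-to-concept distance block to per-
// concept minima: with A = Z_bag %*% t(C) and v = rowSums(Z_bag^2), the
// result plus colSums(C^2) is the per-concept minimum squared distance.
// [[Rcpp::export]]
NumericVector colmin_shift(NumericMatrix A, NumericVector v) {
  int n = A.nrow(), p = A.ncol();
  NumericVector out(p);
  for (int j = 0; j < p; ++j) {
    double m = std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; ++i) {
      double d = v[i] - 2.0 * A(i, j);
      if (d < m) m = d;
    }
    out[j] = m;
  }
  return out;
}

// L1-regularized linear SVM (1-norm SVM) via revised simplex on the
// exact LP:
//   minimize (1/n) sum_i xi_i + lambda * ||w||_1
//   s.t.     y_i (w . x_i + b) >= 1 - xi_i,  xi_i >= 0.
// Variables (all >= 0): u(p), v(p) with w = u - v; bp, bm with
// b = bp - bm; xi(n); surplus s(n). Column indexing:
//   0..p-1: u, p..2p-1: v, 2p: bp, 2p+1: bm,
//   2p+2..2p+1+n: xi, 2p+2+n..2p+1+2n: s.
// The all-xi basis (xi_i = 1) is feasible, so no phase 1 is needed.
// Dantzig pricing with a Bland fallback for stalling; optional warm
// start from a previous basis.
// [[Rcpp::export]]
List lp_hinge_l1(NumericMatrix X, NumericVector y, double lambda,
                 Nullable<IntegerVector> basis0 = R_NilValue,
                 double tol = 1e-9, int max_iter = -1) {
  int n = X.nrow(), p = X.ncol();
  int ncol_tot = 2 * p + 2 + 2 * n;
  double ninv = 1.0 / n;
  if (max_iter < 0) max_iter = 400 + 60 * n;

  // cost of column j
  auto cost = [&](int j) -> double {
    if (j < 2 * p) return lambda;
    if (j < 2 * p + 2) return 0.0;
    if (j < 2 * p + 2 + n) return ninv;
    return 0.0;
  };
  // column j of the constraint matrix into buffer a
  auto fill_col = [&](int j, std::vector<double>& a) {
    std::fill(a.begin(), a.end(), 0.0);
    if (j < p) {
      for (int i = 0; i < n; ++i) a[i] = y[i] * X(i, j);
    } else if (j < 2 * p) {
      int k = j - p;
      for (int i = 0; i < n; ++i) a[i] = -y[i] * X(i, k);
    } else if (j == 2 * p) {
      for (int i = 0; i < n; ++i) a[i] = y[i];
    } else if (j == 2 * p + 1) {
      for (int i = 0; i < n; ++i) a[i] = -y[i];
    } else if (j < 2 * p + 2 + n) {
      a[j - 2 * p - 2] = 1.0;
    } else {
      a[j - 2 * p - 2 - n] = -1.0;
    }
  };

  std::vector<int> basis(n);
  std::vector<double> Binv((size_t)n * n, 0.0);
  std::vector<double> xB(n, 1.0);

  bool warm = false;
  if (basis0.isNotNull()) {
    IntegerVector b0(basis0);
    if (b0.size() == n) {
      warm = true;
      for (int i = 0; i < n; ++i) basis[i] = b0[i];
      // Build B and invert by Gauss-Jordan; fall back to cold start on
      // singularity.
      std::vector<double> B((size_t)n * n, 0.0), col(n);
      for (int jj = 0; jj < n; ++jj) {
        fill_col(basis[jj], col);
        for (int i = 0; i < n; ++i) B[(size_t)i * n + jj] = col[i];
      }
      for (int i = 0; i < n; ++i) Binv[(size_t)i * n + i] = 1.0;
      for (int cidx = 0; cidx < n && warm; ++cidx) {
        int piv = -1; double best = 1e-10;
        for (int r = cidx; r < n; ++r) {
          double v = std::fabs(B[(size_t)r * n + cidx]);
          if (v > best) { best = v; piv = r; }
        }
        if (piv < 0) { warm = false; break; }
        if (piv != cidx) {
          for (int k = 0; k < n; ++k) {
            std::swap(B[(size_t)piv * n + k], B[(size_t)cidx * n + k]);
            std::swap(Binv[(size_t)piv * n + k], Binv[(size_t)cidx * n + k]);
          }
        }
        double d = B[(size_t)cidx * n + cidx];
        for (int k = 0; k < n; ++k) {
          B[(size_t)cidx * n + k] /= d;
          Binv[(size_t)cidx * n + k] /= d;
        }
        for (int r = 0; r < n; ++r) {
          if (r == cidx) continue;
          double f = B[(size_t)r * n + cidx];
          if (f != 0.0) {
            for (int k = 0; k < n; ++k) {
              B[(size_t)r * n + k] -= f * B[(size_t)cidx * n + k];
              Binv[(size_t)r * n + k] -= f * Binv[(size_t)cidx * n + k];
            }
          }
        }
      }
      if (warm) {
        // xB = Binv * b  (b = ones)
        bool feas = true;
        for (int i = 0; i < n; ++i) {
          double s = 0;
          for (int k = 0; k < n; ++k) s += Binv[(size_t)i * n + k];
          xB[i] = s;
          if (s < -1e-9) feas = false;
        }
        if (!feas) warm = false;
      }
    }
  }
  if (!warm) {
    for (int i = 0; i < n; ++i) {
      basis[i] = 2 * p + 2 + i;               // xi_i
      for (int k = 0; k < n; ++k) Binv[(size_t)i * n + k] = (i == k) ? 1.0 : 0.0;
      xB[i] = 1.0;
    }
  }

  std::vector<double> pi(n), acol(n), d(n), yx(n);
  int iter = 0, stall = 0;
  bool bland = false;

  for (iter = 0; iter < max_iter; ++iter) {
    // pi = Binv' * c_B
    for (int k = 0; k < n; ++k) {
      double s = 0;
      for (int i = 0; i < n; ++i) s += Binv[(size_t)i * n + k] * cost(basis[i]);
      pi[k] = s;
    }
    for (int i = 0; i < n; ++i) yx[i] = pi[i] * y[i];

    // pricing
    int enter = -1; double best = -tol;
    double sy = 0; for (int i = 0; i < n; ++i) sy += yx[i];
    if (!bland) {
      for (int j = 0; j < p; ++j) {
        double dot = 0;
        for (int i = 0; i < n; ++i) dot += yx[i] * X(i, j);
        double rc_u = lambda - dot, rc_v = lambda + dot;
        if (rc_u < best) { best = rc_u; enter = j; }
        if (rc_v < best) { best = rc_v; enter = p + j; }
      }
      if (-sy < best) { best = -sy; enter = 2 * p; }
      if (sy < best) { best = sy; enter = 2 * p + 1; }
      for (int i = 0; i < n; ++i) {
        double rc_xi = ninv - pi[i];
        double rc_s = pi[i];
        if (rc_xi < best) { best = rc_xi; enter = 2 * p + 2 + i; }
        if (rc_s < best) { best = rc_s; enter = 2 * p + 2 + n + i; }
      }
    } else {
      // Bland: first improving column by index
      for (int j = 0; j < ncol_tot && enter < 0; ++j) {
        double rc;
        if (j < p) {
          double dot = 0; for (int i = 0; i < n; ++i) dot += yx[i] * X(i, j);
          rc = lambda - dot;
        } else if (j < 2 * p) {
          double dot = 0; for (int i = 0; i < n; ++i) dot += yx[i] * X(i, j - p);
          rc = lambda + dot;
        } else if (j == 2 * p) rc = -sy;
        else if (j == 2 * p + 1) rc = sy;
        else if (j < 2 * p + 2 + n) rc = ninv - pi[j - 2 * p - 2];
        else rc = pi[j - 2 * p - 2 - n];
        if (rc < -tol) enter = j;
      }
    }
    if (enter < 0) break;                     // optimal

    fill_col(enter, acol);
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (int k = 0; k < n; ++k) s += Binv[(size_t)i * n + k] * acol[k];
      d[i] = s;
    }
    int leave = -1; double theta = std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; ++i) {
      if (d[i] > 1e-10) {
        double t = xB[i] / d[i];
        if (t < theta - 1e-12 ||
            (t < theta + 1e-12 && leave >= 0 &&
             (bland ? basis[i] < basis[leave] : std::fabs(d[i]) > std::fabs(d[leave])))) {
          theta = t; leave = i;
        }
      }
    }
    if (leave < 0) {
      return List::create(_["status"] = "unbounded");
    }
    if (theta < 1e-12) { if (++stall > 2 * n) bland = true; } else stall = 0;

    // pivot update
    double piv = d[leave];
    for (int k = 0; k < n; ++k) Binv[(size_t)leave * n + k] /= piv;
    for (int i = 0; i < n; ++i) {
      if (i == leave) continue;
      double f = d[i];
      if (f != 0.0) {
        for (int k = 0; k < n; ++k)
          Binv[(size_t)i * n + k] -= f * Binv[(size_t)leave * n + k];
      }
    }
    for (int i = 0; i < n; ++i) xB[i] -= theta * d[i];
    xB[leave] = theta;
    basis[leave] = enter;
  }

  // extract solution
  NumericVector w(p);
  double b = 0, xisum = 0, l1 = 0;
  for (int i = 0; i < n; ++i) {
    int j = basis[i]; double v = xB[i];
    if (j < p) { w[j] += v; l1 += v; }
    else if (j < 2 * p) { w[j - p] -= v; l1 += v; }
    else if (j == 2 * p) b += v;
    else if (j == 2 * p + 1) b -= v;
    else if (j < 2 * p + 2 + n) xisum += v;
  }
  double obj = ninv * xisum + lambda * l1;
  IntegerVector basis_out(n);
  for (int i = 0; i < n; ++i) basis_out[i] = basis[i];
  return List::create(_["weights"] = w, _["intercept"] = b,
                      _["objective"] = obj, _["iterations"] = iter,
                      _["basis"] = basis_out,
                      _["status"] = iter < max_iter ? "optimal" : "iteration_limit");
}
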