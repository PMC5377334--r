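#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Dense two-phase primal simplex with Bland's anti-cycling rule.
//
// Maximises c'x subject to A x (sense) b, x >= 0, where sense codes
// 0 = "<=", 1 = "=", 2 = ">=".  The caller must normalise rows so that
// b >= 0 (flip signs of "=" rows; convert negative-rhs inequalities to
// the opposite sense).  Problem sizes here are small (toy genome-scale
// models, tens of reactions), so a dense tableau is adequate and keeps
// the pivoting exact and deterministic.
//
// Status codes: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit.

static const double TOL = 1e-9;      // reduced-cost / pivot tolerance
static const double FEAS_TOL = 1e-7; // phase-1 residual tolerance

struct Tableau {
  int m, ncol;                 // rows, columns (excluding rhs)
  std::vector<double> T;       // m x (ncol+1), row-major
  std::vector<double> obj;     // objective row, length ncol+1 (z_j - c_j, rhs = z)
  std::vector<int> basis;      // basic variable per row
  std::vector<bool> banned;    // columns never allowed to enter

  double &at(int i, int j) { return T[i * (ncol + 1) + j]; }

  void pivot(int prow, int pcol) {
    const double piv = at(prow, pcol);
    const int w = ncol + 1;
    double *pr = &T[prow * w];
    for (int j = 0; j < w; ++j) pr[j] /= piv;
    for (int i = 0; i < m; ++i) {
      if (i == prow) continue;
      double f = at(i, pcol);
      if (f == 0.0) continue;
      double *ri = &T[i * w];
      for (int j = 0; j < w; ++j) ri[j] -= f * pr[j];
      ri[pcol] = 0.0;
    }
    double f = obj[pcol];
    if (f != 0.0) {
      for (int j = 0; j < w; ++j) obj[j] -= f * pr[j];
      obj[pcol] = 0.0;
    }
    basis[prow] = pcol;
  }

  // Simplex iteration: Dantzig pricing (most negative reduced cost,
  // smallest index on ties) with a switch to Bland's rule after
  // `blandAfter` iterations to guarantee termination on degenerate
  // problems.  Returns 0 optimal, 2 unbounded, 3 maxit.
  int iterate(int maxit, int blandAfter = 2000) {
    for (int it = 0; it < maxit; ++it) {
      int enter = -1;
      if (it < blandAfter) {
        double most = -TOL;
        for (int j = 0; j < ncol; ++j) {
          if (!banned[j] && obj[j] < most) { most = obj[j]; enter = j; }
        }
      } else {
        for (int j = 0; j < ncol; ++j) {
          if (!banned[j] && obj[j] < -TOL) { enter = j; break; }
        }
      }
      if (enter < 0) return 0;
      int leave = -1;
      double best = 0.0;
      for (int i = 0; i < m; ++i) {
        double a = at(i, enter);
        if (a > TOL) {
          double ratio = at(i, ncol) / a;
          if (leave < 0 || ratio < best - TOL ||
              (ratio < best + TOL && basis[i] < basis[leave])) {
            leave = i;
            best = ratio;
          }
        }
      }
      if (leave < 0) return 2;
      pivot(leave, enter);
    }
    return 3;
  }
};

// [[Rcpp::export]]
List cpp_simplex(NumericMatrix A, NumericVector b, IntegerVector sense,
                 NumericVector cobj, int maxit = 100000) {
  const int m = A.nrow(), n = A.ncol();
  int nSlack = 0, nArt = 0;
  for (int i = 0; i < m; ++i) {
    if (sense[i] == 0) nSlack += 1;
    else if (sense[i] == 2) { nSlack += 1; nArt += 1; }
    else nArt += 1;
  }
  Tableau tb;
  tb.m = m;
  tb.ncol = n + nSlack + nArt;
  tb.T.assign((size_t)m * (tb.ncol + 1), 0.0);
  tb.obj.assign(tb.ncol + 1, 0.0);
  tb.basis.assign(m, -1);
  tb.banned.assign(tb.ncol, false);

  const int artStart = n + nSlack;
  int sl = n, ar = artStart;
  for (int i = 0; i < m; ++i) {
    if (b[i] < -FEAS_TOL) stop("internal: negative rhs reached the simplex core");
    for (int j = 0; j < n; ++j) tb.at(i, j) = A(i, j);
    tb.at(i, tb.ncol) = b[i] < 0 ? 0.0 : b[i];
    if (sense[i] == 0) {
      tb.at(i, sl) = 1.0; tb.basis[i] = sl; ++sl;
    } else if (sense[i] == 2) {
      tb.at(i, sl) = -1.0; ++sl;
      tb.at(i, ar) = 1.0; tb.basis[i] = ar; ++ar;
    } else {
      tb.at(i, ar) = 1.0; tb.basis[i] = ar; ++ar;
    }
  }

  // Phase 1: maximise -(sum of artificials).
  if (nArt > 0) {
    for (int j = artStart; j < tb.ncol; ++j) tb.obj[j] = 1.0; // z_j - c_j with c_j = -1
    // make objective row consistent with the starting basis
    for (int i = 0; i < m; ++i) {
      if (tb.basis[i] >= artStart) {
        const int w = tb.ncol + 1;
        for (int j = 0; j < w; ++j) tb.obj[j] -= tb.T[i * w + j];
      }
    }
    int st = tb.iterate(maxit);
    if (st == 3) return List::create(_["status"] = 3);
    if (st == 2) stop("internal: phase-1 unbounded");
    if (tb.obj[tb.ncol] < -FEAS_TOL) // max of -(sum art) below 0 => infeasible
      return List::create(_["status"] = 1);
    // drive basic artificials out where possible; leftover rows are
    // redundant (all-zero in structural columns) and stay inert because
    // artificial columns are banned from entering below
    for (int i = 0; i < m; ++i) {
      if (tb.basis[i] >= artStart) {
        int pcol = -1;
        double best = 0.0;
        for (int j = 0; j < artStart; ++j) {
          double a = std::fabs(tb.at(i, j));
          if (a > 1e-7 && a > best) { best = a; pcol = j; }
        }
        if (pcol >= 0) tb.pivot(i, pcol);
      }
    }
  }
  for (int j = artStart; j < tb.ncol; ++j) tb.banned[j] = true;

  // Phase 2: maximise c'x.
  std::fill(tb.obj.begin(), tb.obj.end(), 0.0);
  for (int j = 0; j < n; ++j) tb.obj[j] = -cobj[j];
  for (int i = 0; i < m; ++i) {
    int bj = tb.basis[i];
    if (bj < n && cobj[bj] != 0.0) {
      const int w = tb.ncol + 1;
      for (int j = 0; j < w; ++j) tb.obj[j] += cobj[bj] * tb.T[i * w + j];
      tb.obj[bj] = 0.0;
    }
  }
  int st = tb.iterate(maxit);
  if (st == 2) return List::create(_["status"] = 2);
  if (st == 3) return List::create(_["status"] = 3);

  NumericVector x(n);
  for (int i = 0; i < m; ++i)
    if (tb.basis[i] < n) x[tb.basis[i]] = tb.at(i, tb.ncol);
  return List::create(_["status"] = 0,
                      _["objective"] = tb.obj[tb.ncol],
                      _["x"] = x);
}
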