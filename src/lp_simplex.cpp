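// Bounded-variable two-phase primal simplex.
//
// Solves   min / max  c'z   s.t.  A z = b,  lb <= z <= ub
// with all structural bounds finite (the bound-contraction polytope is a
// box intersected with a linear subspace, so this always holds here).
// Dense tableau with explicit basis-inverse updates; problem sizes in this
// package are at most a few hundred columns, where a dense tableau is both
// fast and numerically well behaved.
//
// Phase 1 starts from an all-artificial basis and minimises the sum of
// artificial variables; phase 2 fixes artificials to zero and optimises the
// real objective. Dantzig pricing with a Bland's-rule fallback guards
// against cycling on degenerate vertices.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = 1e30;
const double DTOL = 1e-9;   // reduced-cost tolerance
const double PTOL = 1e-9;   // pivot tolerance
const double FTOL = 1e-7;   // phase-1 feasibility tolerance

struct SimplexState {
  int nrow;                  // constraints
  int ncol;                  // structural + artificial columns
  int nstruct;
  std::vector<double> T;     // tableau: B^{-1} A, row-major nrow x ncol
  std::vector<double> xB;    // basic variable values
  std::vector<int> basis;    // column index basic in each row
  std::vector<int> state;    // -1 at lb, +1 at ub, 0 basic
  std::vector<double> lb, ub;

  double &t(int i, int j) { return T[(size_t)i * ncol + j]; }
};

// current value of column j
double varValue(const SimplexState &S, int j) {
  if (S.state[j] == -1) return S.lb[j];
  if (S.state[j] == +1) return S.ub[j];
  for (int i = 0; i < S.nrow; ++i)
    if (S.basis[i] == j) return S.xB[i];
  return 0.0; // unreachable
}

// one simplex run on the current basis for objective c (minimisation).
// returns 0 optimal, 1 iteration limit, 2 numerical failure
int runSimplex(SimplexState &S, const std::vector<double> &c, int maxit) {
  int n = S.ncol, m = S.nrow;
  std::vector<double> d(n);            // reduced costs
  std::vector<int> basicpos(n, -1);
  int stall = 0;
  double lastobj = std::numeric_limits<double>::max();

  for (int iter = 0; iter < maxit; ++iter) {
    for (int j = 0; j < n; ++j) basicpos[j] = -1;
    for (int i = 0; i < m; ++i) basicpos[S.basis[i]] = i;

    // reduced costs d = c - c_B' T
    for (int j = 0; j < n; ++j) d[j] = c[j];
    for (int i = 0; i < m; ++i) {
      double cb = c[S.basis[i]];
      if (cb != 0.0) {
        const double *row = &S.T[(size_t)i * n];
        for (int j = 0; j < n; ++j) d[j] -= cb * row[j];
      }
    }

    // objective value for stall detection
    double obj = 0.0;
    for (int j = 0; j < n; ++j)
      if (S.state[j] != 0) obj += c[j] * (S.state[j] == -1 ? S.lb[j] : S.ub[j]);
    for (int i = 0; i < m; ++i) obj += c[S.basis[i]] * S.xB[i];
    if (obj < lastobj - 1e-12) { stall = 0; lastobj = obj; } else ++stall;
    bool bland = stall > 2 * (n + m);

    // pricing: nonbasic at lb wants d_j < 0 (increase), at ub wants d_j > 0
    int enter = -1, dir = 0;
    double best = -DTOL;
    for (int j = 0; j < n; ++j) {
      if (S.state[j] == 0) continue;
      if (S.ub[j] - S.lb[j] < 1e-15 && basicpos[j] == -1) continue; // fixed
      double viol = (S.state[j] == -1) ? d[j] : -d[j];
      if (viol < (bland ? -DTOL : best)) {
        enter = j; dir = (S.state[j] == -1) ? +1 : -1;
        if (bland) break;
        best = viol;
      }
    }
    if (enter < 0) return 0; // optimal

    // ratio test: entering moves by t >= 0 in direction dir
    double tmax = S.ub[enter] - S.lb[enter]; // bound flip limit
    int leave = -1;   // row index of leaving basic variable
    int leaveTo = 0;  // bound the leaving variable exits to
    for (int i = 0; i < m; ++i) {
      double a = dir * S.t(i, enter);
      if (a > PTOL) { // basic decreases toward its lb
        double lim = (S.xB[i] - S.lb[S.basis[i]]) / a;
        if (lim < tmax - 1e-12 || (lim < tmax + 1e-12 && leave >= 0 &&
            (bland ? S.basis[i] < S.basis[leave] : std::fabs(S.t(i, enter)) > std::fabs(S.t(leave, enter))))) {
          tmax = std::max(lim, 0.0); leave = i; leaveTo = -1;
        }
      } else if (a < -PTOL) { // basic increases toward its ub
        if (S.ub[S.basis[i]] >= INF) continue;
        double lim = (S.ub[S.basis[i]] - S.xB[i]) / (-a);
        if (lim < tmax - 1e-12 || (lim < tmax + 1e-12 && leave >= 0 &&
            (bland ? S.basis[i] < S.basis[leave] : std::fabs(S.t(i, enter)) > std::fabs(S.t(leave, enter))))) {
          tmax = std::max(lim, 0.0); leave = i; leaveTo = +1;
        }
      }
    }
    if (tmax >= INF) return 2; // unbounded: impossible with finite boxes

    // update basic values
    for (int i = 0; i < m; ++i) S.xB[i] -= dir * tmax * S.t(i, enter);

    if (leave < 0) { // bound flip, no basis change
      S.state[enter] = -S.state[enter];
      continue;
    }

    // pivot: entering becomes basic in row `leave`
    double enterVal = (S.state[enter] == -1 ? S.lb[enter] : S.ub[enter]) + dir * tmax;
    int leavingCol = S.basis[leave];
    double piv = S.t(leave, enter);
    if (std::fabs(piv) < PTOL) return 2;

    double *prow = &S.T[(size_t)leave * n];
    double inv = 1.0 / piv;
    for (int j = 0; j < n; ++j) prow[j] *= inv;
    for (int i = 0; i < m; ++i) {
      if (i == leave) continue;
      double f = S.t(i, enter);
      if (f != 0.0) {
        double *row = &S.T[(size_t)i * n];
        for (int j = 0; j < n; ++j) row[j] -= f * prow[j];
        row[enter] = 0.0; // exact zero in pivot column
      }
    }
    prow[enter] = 1.0;

    S.basis[leave] = enter;
    S.xB[leave] = enterVal;
    S.state[enter] = 0;
    S.state[leavingCol] = (leaveTo == -1) ? -1 : +1;
    // snap leaving variable's neighbours: nothing to store; its value is a bound
  }
  return 1;
}

// Set up phase-1 state for A z = b with z starting at the bound nearest zero.
SimplexState initState(const NumericMatrix &A, const NumericVector &b,
                       const NumericVector &lb, const NumericVector &ub) {
  int m = A.nrow(), ns = A.ncol();
  SimplexState S;
  S.nrow = m; S.nstruct = ns; S.ncol = ns + m;
  S.T.assign((size_t)m * S.ncol, 0.0);
  S.lb.resize(S.ncol); S.ub.resize(S.ncol);
  S.state.assign(S.ncol, -1);
  S.basis.resize(m); S.xB.resize(m);

  std::vector<double> z0(ns);
  for (int j = 0; j < ns; ++j) {
    S.lb[j] = lb[j]; S.ub[j] = ub[j];
    if (std::fabs(lb[j]) <= std::fabs(ub[j])) { z0[j] = lb[j]; S.state[j] = -1; }
    else { z0[j] = ub[j]; S.state[j] = +1; }
  }
  for (int i = 0; i < m; ++i) {
    double r = b[i];
    for (int j = 0; j < ns; ++j) r -= A(i, j) * z0[j];
    double s = (r >= 0.0) ? 1.0 : -1.0;
    // artificial column i: coefficient s in row i
    int aj = ns + i;
    S.lb[aj] = 0.0; S.ub[aj] = INF;
    S.basis[i] = aj; S.xB[i] = std::fabs(r);
    S.state[aj] = 0;
    // tableau = B^{-1} [A | D], B = diag(s)
    for (int j = 0; j < ns; ++j) S.t(i, j) = s * A(i, j);
    S.t(i, aj) = 1.0;
  }
  return S;
}

// returns: status 0 ok, 2 infeasible, 3 numerical trouble
int phase1(SimplexState &S, int maxit) {
  std::vector<double> c(S.ncol, 0.0);
  for (int j = S.nstruct; j < S.ncol; ++j) c[j] = 1.0;
  int st = runSimplex(S, c, maxit);
  if (st != 0) return 3;
  double infeas = 0.0;
  for (int i = 0; i < S.nrow; ++i)
    if (S.basis[i] >= S.nstruct) infeas += S.xB[i];
  if (infeas > FTOL) return 2;
  // pin artificials to zero for phase 2
  for (int j = S.nstruct; j < S.ncol; ++j) { S.lb[j] = 0.0; S.ub[j] = 0.0; }
  for (int i = 0; i < S.nrow; ++i)
    if (S.basis[i] >= S.nstruct && S.xB[i] > 0.0) S.xB[i] = 0.0;
  return 0;
}

double objectiveValue(const SimplexState &S, const std::vector<double> &c) {
  double obj = 0.0;
  for (int j = 0; j < S.nstruct; ++j)
    if (S.state[j] != 0) obj += c[j] * (S.state[j] == -1 ? S.lb[j] : S.ub[j]);
  for (int i = 0; i < S.nrow; ++i)
    if (S.basis[i] < S.nstruct) obj += c[S.basis[i]] * S.xB[i];
  return obj;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".lp_solve_cpp")]]
List lp_solve_cpp(NumericMatrix A, NumericVector b, NumericVector lb,
                  NumericVector ub, NumericVector cvec, bool maximize,
                  int maxit = 20000) {
  int ns = A.ncol();
  SimplexState S = initState(A, b, lb, ub);
  int st = phase1(S, maxit);
  if (st == 2) return List::create(_["status"] = "infeasible");
  if (st != 0) return List::create(_["status"] = "numerical");

  std::vector<double> c(S.ncol, 0.0);
  for (int j = 0; j < ns; ++j) c[j] = maximize ? -cvec[j] : cvec[j];
  int st2 = runSimplex(S, c, maxit);
  if (st2 != 0) return List::create(_["status"] = "numerical");

  NumericVector x(ns);
  for (int j = 0; j < ns; ++j) x[j] = varValue(S, j);
  double val = objectiveValue(S, c);
  return List::create(_["status"] = "optimal",
                      _["value"] = maximize ? -val : val,
                      _["x"] = x);
}

//' @noRd
// [[Rcpp::export(name = ".lp_contract_cpp")]]
List lp_contract_cpp(NumericMatrix A, NumericVector b, NumericVector lb,
                     NumericVector ub, int maxit = 20000) {
  int ns = A.ncol();
  // shared phase-1 feasibility decision
  {
    SimplexState S0 = initState(A, b, lb, ub);
    int st = phase1(S0, maxit);
    if (st == 2)
      return List::create(_["feasible"] = false);
    if (st != 0) stop("LP solver failed during feasibility phase");
  }
  NumericVector lo(ns), hi(ns);
  std::vector<double> c(ns + A.nrow(), 0.0);
  for (int j = 0; j < ns; ++j) {
    for (int sense = 0; sense < 2; ++sense) {
      SimplexState S = initState(A, b, lb, ub);
      int st = phase1(S, maxit);
      if (st != 0) stop("LP solver lost feasibility on variable %d", j + 1);
      std::fill(c.begin(), c.end(), 0.0);
      c[j] = (sense == 0) ? 1.0 : -1.0; // minimise, then maximise
      int st2 = runSimplex(S, c, maxit);
      if (st2 != 0) stop("LP solver failed on variable %d", j + 1);
      double v = objectiveValue(S, c);
      if (sense == 0) lo[j] = v; else hi[j] = -v;
    }
  }
  return List::create(_["feasible"] = true, _["lo"] = lo, _["hi"] = hi,
                      _["lp_count"] = 2 * ns);
}
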