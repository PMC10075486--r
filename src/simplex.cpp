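// Exact rational feasibility solver for systems  G z >= g  with z free,
// G integer (m x d).  Used for the strict-separating-hyperplane decision,
// the conservativity test and the siphon witness problems.
//
// By Farkas duality, G z >= g is infeasible iff there is y >= 0 with
// G^T y = 0 and g^T y > 0.  We run an exact phase-1 simplex on the dual
// system [G^T; g^T] y = e_{d+1}: optimum 0 means the dual system is feasible
// (primal infeasible); a strictly positive optimum yields simplex multipliers
// pi = (u, t) with t > 0 and u.G_j + t g_j <= 0 for all rows j, so that
// z = -u / t satisfies the primal system exactly.
//
// All tableau arithmetic is in reduced rationals over 64-bit integers with
// 128-bit intermediates; overflow aborts rather than rounds.

#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

typedef long long ll;
typedef __int128 lll;

static const lll RBOUND = ((lll)1) << 62;

static ll gcdll(ll a, ll b) {
  if (a < 0) a = -a;
  if (b < 0) b = -b;
  while (b) { ll t = a % b; a = b; b = t; }
  return a;
}

struct Rat {
  ll n, d; // d > 0, reduced
  Rat() : n(0), d(1) {}
  Rat(ll nn) : n(nn), d(1) {}
  Rat(ll nn, ll dd) : n(nn), d(dd) {}
};

static inline Rat make(lll n, lll d) {
  if (d == 0) stop("zero denominator in exact simplex");
  if (d < 0) { n = -n; d = -d; }
  if (n == 0) return Rat(0, 1);
  lll a = n < 0 ? -n : n, b = d;
  while (b) { lll t = a % b; a = b; b = t; }
  n /= a; d /= a;
  if (n >= RBOUND || n <= -RBOUND || d >= RBOUND) stop("exact arithmetic overflow in simplex");
  return Rat((ll)n, (ll)d);
}

static inline Rat add(const Rat& a, const Rat& b) {
  return make((lll)a.n * b.d + (lll)b.n * a.d, (lll)a.d * b.d);
}
static inline Rat sub(const Rat& a, const Rat& b) {
  return make((lll)a.n * b.d - (lll)b.n * a.d, (lll)a.d * b.d);
}
static inline Rat mul(const Rat& a, const Rat& b) {
  return make((lll)a.n * b.n, (lll)a.d * b.d);
}
static inline Rat divr(const Rat& a, const Rat& b) {
  if (b.n == 0) stop("division by zero in exact simplex");
  return make((lll)a.n * b.d, (lll)a.d * b.n);
}
static inline int cmp(const Rat& a, const Rat& b) {
  lll lhs = (lll)a.n * b.d, rhs = (lll)b.n * a.d;
  return lhs < rhs ? -1 : (lhs > rhs ? 1 : 0);
}
static inline bool is_zero(const Rat& a) { return a.n == 0; }
static inline bool is_neg(const Rat& a) { return a.n < 0; }
static inline bool is_pos(const Rat& a) { return a.n > 0; }

// [[Rcpp::export]]
List cpp_lp_feasible(NumericMatrix Gmat, NumericVector gvec, double max_iter) {
  int m = Gmat.nrow(), d = Gmat.ncol();
  int rows = d + 1;                 // dual equality constraints
  int ncols = m + rows;             // y columns + artificial columns
  // dual constraint matrix columns: A_j = (G_j, g_j) for j < m; artificials after
  // tableau: rows x (ncols + 1); last col = rhs; plus objective row
  std::vector< std::vector<Rat> > T(rows + 1, std::vector<Rat>(ncols + 1));
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < d; ++i) {
      double v = Gmat(j, i);
      if (v != std::floor(v) || std::abs(v) >= 9e15) stop("constraint matrix must be integer-valued");
      T[i][j] = Rat((ll)v);
    }
    double v = gvec[j];
    if (v != std::floor(v) || std::abs(v) >= 9e15) stop("rhs must be integer-valued");
    T[d][j] = Rat((ll)v);
  }
  // dual rhs b = e_{d+1}; ensure nonnegative rows (already: b_i in {0,1})
  for (int i = 0; i < rows; ++i) {
    T[i][m + i] = Rat(1);            // artificial
    T[i][ncols] = Rat(i == d ? 1 : 0);
  }
  // objective row: minimize sum of artificials; reduced costs with basis =
  // artificials: cbar_j = 0 - sum_i A_ij for y columns, 0 for artificials;
  // objective value = -sum b_i (stored negated in T[rows][ncols])
  for (int j = 0; j < m; ++j) {
    Rat ssum(0);
    for (int i = 0; i < rows; ++i) ssum = add(ssum, T[i][j]);
    T[rows][j] = sub(Rat(0), ssum);
  }
  Rat obj(0);
  for (int i = 0; i < rows; ++i) obj = add(obj, T[i][ncols]);
  T[rows][ncols] = sub(Rat(0), obj); // = -(sum b) ; objective value = -T[rows][ncols]

  std::vector<int> basis(rows);
  for (int i = 0; i < rows; ++i) basis[i] = m + i;

  long long iter = 0, bland_after = 2000;
  bool bland = false;
  while (true) {
    if (++iter > (long long)max_iter) stop("exact simplex iteration limit reached");
    if (iter > bland_after) bland = true;
    // entering column
    int enter = -1;
    if (bland) {
      for (int j = 0; j < ncols; ++j) if (is_neg(T[rows][j])) { enter = j; break; }
    } else {
      Rat best(0);
      for (int j = 0; j < ncols; ++j)
        if (is_neg(T[rows][j]) && (enter < 0 || cmp(T[rows][j], best) < 0)) { enter = j; best = T[rows][j]; }
    }
    if (enter < 0) break; // optimal
    // ratio test
    int leave = -1;
    Rat bestratio(0);
    for (int i = 0; i < rows; ++i) {
      if (!is_pos(T[i][enter])) continue;
      Rat ratio = divr(T[i][ncols], T[i][enter]);
      if (leave < 0 || cmp(ratio, bestratio) < 0 ||
          (cmp(ratio, bestratio) == 0 && basis[i] < basis[leave])) {
        leave = i; bestratio = ratio;
      }
    }
    if (leave < 0) stop("phase-1 objective unbounded; internal error");
    // pivot
    Rat piv = T[leave][enter];
    for (int j = 0; j <= ncols; ++j)
      if (!is_zero(T[leave][j])) T[leave][j] = divr(T[leave][j], piv);
    for (int i = 0; i <= rows; ++i) {
      if (i == leave || is_zero(T[i][enter])) continue;
      Rat f = T[i][enter];
      for (int j = 0; j <= ncols; ++j) {
        if (is_zero(T[leave][j])) continue;
        T[i][j] = sub(T[i][j], mul(f, T[leave][j]));
      }
    }
    basis[leave] = enter;
  }

  Rat optval = sub(Rat(0), T[rows][ncols]); // minimized sum of artificials
  if (is_zero(optval)) {
    // dual system feasible -> primal infeasible
    return List::create(_["feasible"] = false);
  }
  // multipliers: pi_i = c_art_i - cbar_art_i = 1 - T[rows][m+i]
  std::vector<Rat> pi(rows);
  for (int i = 0; i < rows; ++i) pi[i] = sub(Rat(1), T[rows][m + i]);
  Rat t = pi[d];
  if (!is_pos(t)) stop("internal error: nonpositive homogenization multiplier");
  NumericVector zn(d), zd(d);
  for (int i = 0; i < d; ++i) {
    Rat z = divr(sub(Rat(0), pi[i]), t);
    if (std::abs((double)z.n) >= 9e15 || std::abs((double)z.d) >= 9e15)
      stop("certificate entries exceed exact double range");
    zn[i] = (double)z.n; zd[i] = (double)z.d;
  }
  return List::create(_["feasible"] = true, _["num"] = zn, _["den"] = zd);
}
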