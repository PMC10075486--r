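// Exact expansion of the critical polynomial
//   (-1)^s det Mtilde(h, lambda),
// where Mtilde is N diag(E lambda) A^T diag(h) with the pivot rows replaced by
// the rows of (an integer-scaled) W.
//
// The determinant is expanded by a generalized Laplace expansion along the
// block of W rows: for every column subset C of size n-s,
//   det M = sum_C  (-1)^{sigma(pivots)+sigma(C)} det W[,C] * det Q[J, C^c] * prod_{j in C^c} h_j,
// where Q[i][j] = sum_m N_im (E lambda)_m A_jm is linear in lambda.  The inner
// lambda-determinants are computed by row expansion memoized on the column
// bitmask, which is shared across subsets C.  All coefficients are 64-bit
// integers with 128-bit overflow checks; a term budget converts combinatorial
// blow-up into a clean error.

#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

typedef long long ll;
typedef __int128 lll;

static const ll LLBOUND = (1LL << 62);

static inline ll chk_mul(ll a, ll b) {
  lll r = (lll)a * (lll)b;
  if (r >= LLBOUND || r <= -LLBOUND) stop("integer overflow in critical polynomial expansion");
  return (ll)r;
}
static inline ll chk_add(ll a, ll b) {
  lll r = (lll)a + (lll)b;
  if (r >= LLBOUND || r <= -LLBOUND) stop("integer overflow in critical polynomial expansion");
  return (ll)r;
}

// polynomial in lambda: packed exponent key -> coefficient
typedef std::map<uint64_t, ll> Poly;

static const int BITS = 5;          // bits per lambda exponent
static const uint64_t EMASK = 31;   // 2^BITS - 1

struct Expander {
  int n, s, l;
  std::vector< std::vector< std::vector<ll> > > Q; // [depth][col][k]
  std::unordered_map<uint32_t, Poly> memo;
  long long budget;
  long long stored;

  void charge(size_t k) {
    stored += (long long)k;
    if (stored > budget) stop("term budget exceeded while expanding the critical polynomial; raise term_budget or reduce the network first");
  }

  const Poly& minor_poly(int depth, uint32_t mask) {
    auto it = memo.find(mask);
    if (it != memo.end()) return it->second;
    Poly res;
    if (depth == s) {
      res[0] = 1;
    } else {
      int pos = 0;
      for (int j = 0; j < n; ++j) {
        uint32_t bit = 1u << j;
        if (!(mask & bit)) continue;
        const std::vector<ll>& lin = Q[depth][j];
        bool nz = false;
        for (int k = 0; k < l; ++k) if (lin[k] != 0) { nz = true; break; }
        if (nz) {
          const Poly& child = minor_poly(depth + 1, mask & ~bit);
          int sgn = (pos % 2 == 0) ? 1 : -1;
          for (const auto& term : child) {
            for (int k = 0; k < l; ++k) {
              if (lin[k] == 0) continue;
              uint64_t e = (term.first >> (BITS * k)) & EMASK;
              if (e + 1 > EMASK) stop("lambda exponent exceeds packing range");
              uint64_t key = term.first + ((uint64_t)1 << (BITS * k));
              ll add = chk_mul(sgn * lin[k], term.second);
              ll& slot = res[key];
              slot = chk_add(slot, add);
              if (slot == 0) res.erase(key);
            }
          }
        }
        ++pos;
      }
    }
    charge(res.size());
    auto ins = memo.emplace(mask, std::move(res));
    return ins.first->second;
  }
};

// exact integer determinant of a small matrix (Bareiss)
static ll int_det(std::vector< std::vector<ll> > M) {
  int k = (int)M.size();
  if (k == 0) return 1;
  ll denom = 1;
  int sign = 1;
  for (int c = 0; c < k - 1; ++c) {
    int p = -1;
    for (int i = c; i < k; ++i) if (M[i][c] != 0) { p = i; break; }
    if (p < 0) return 0;
    if (p != c) { std::swap(M[p], M[c]); sign = -sign; }
    for (int i = c + 1; i < k; ++i) {
      for (int j = c + 1; j < k; ++j) {
        lll v = (lll)M[i][j] * M[c][c] - (lll)M[i][c] * M[c][j];
        v /= denom;
        if (v >= LLBOUND || v <= -LLBOUND) stop("integer overflow in W-minor determinant");
        M[i][j] = (ll)v;
      }
      M[i][c] = 0;
    }
    denom = M[c][c];
  }
  return sign * M[k - 1][k - 1];
}

// [[Rcpp::export]]
List cpp_critical_polynomial(IntegerMatrix N, IntegerMatrix A, IntegerMatrix E,
                             IntegerMatrix Wint, IntegerVector pivots,
                             double term_budget) {
  int n = N.nrow(), r = N.ncol(), l = E.ncol();
  int w = Wint.nrow();
  int s = n - w;
  if (l < 1) stop("flux cone has no extreme rays (l = 0)");
  if (n > 31) stop("networks with more than 31 species are not supported by the symbolic expansion");
  if (l > 12) stop("more than 12 extreme rays exceed the exponent packing; reduce the network first");
  if (s < 1) stop("stoichiometric matrix has rank 0");

  // nonpivot rows, ascending
  std::vector<bool> ispiv(n, false);
  for (int i = 0; i < w; ++i) ispiv[pivots[i] - 1] = true;
  std::vector<int> J;
  for (int i = 0; i < n; ++i) if (!ispiv[i]) J.push_back(i);
  if ((int)J.size() != s) stop("pivot bookkeeping error");

  Expander ex;
  ex.n = n; ex.s = s; ex.l = l;
  ex.budget = (long long)term_budget;
  ex.stored = 0;
  ex.Q.assign(s, std::vector< std::vector<ll> >(n, std::vector<ll>(l, 0)));
  for (int d = 0; d < s; ++d) {
    int i = J[d];
    for (int m = 0; m < r; ++m) {
      if (N(i, m) == 0) continue;
      for (int j = 0; j < n; ++j) {
        if (A(j, m) == 0) continue;
        ll c = chk_mul((ll)N(i, m), (ll)A(j, m));
        for (int k = 0; k < l; ++k) {
          if (E(m, k) == 0) continue;
          ex.Q[d][j][k] = chk_add(ex.Q[d][j][k], chk_mul(c, (ll)E(m, k)));
        }
      }
    }
  }

  int pivsum = 0;
  for (int i = 0; i < w; ++i) pivsum += pivots[i]; // 1-based

  // global accumulator: (hmask, lambda key) -> coefficient
  std::map< std::pair<uint32_t, uint64_t>, ll> acc;

  // iterate over column subsets C (for the W block) of size w
  std::vector<int> comb(w);
  for (int i = 0; i < w; ++i) comb[i] = i;
  bool more = (w <= n);
  if (w == 0) {
    // single empty combination handled by the loop body below once
  }
  while (true) {
    // det W[, comb]
    ll dW;
    {
      std::vector< std::vector<ll> > M(w, std::vector<ll>(w));
      for (int i = 0; i < w; ++i)
        for (int j = 0; j < w; ++j)
          M[i][j] = Wint(i, comb[j]);
      dW = int_det(M);
    }
    if (dW != 0) {
      uint32_t cmask = 0;
      int csum = 0;
      for (int j = 0; j < w; ++j) { cmask |= (1u << comb[j]); csum += comb[j] + 1; }
      uint32_t smask = (n == 31 ? 0x7fffffffu : ((1u << n) - 1u)) & ~cmask;
      int sgn = ((pivsum + csum) % 2 == 0) ? 1 : -1;
      ll f = chk_mul((ll)sgn, dW);
      const Poly& p = ex.minor_poly(0, smask);
      for (const auto& term : p) {
        std::pair<uint32_t, uint64_t> key(smask, term.first);
        ll& slot = acc[key];
        slot = chk_add(slot, chk_mul(f, term.second));
        if (slot == 0) acc.erase(key);
      }
      ex.charge(0); // no-op, budget already charged in minor_poly
      if ((long long)acc.size() > ex.budget)
        stop("term budget exceeded while expanding the critical polynomial; raise term_budget or reduce the network first");
    }
    // next combination
    if (w == 0) break;
    int i = w - 1;
    while (i >= 0 && comb[i] == n - w + i) --i;
    if (i < 0) break;
    ++comb[i];
    for (int j = i + 1; j < w; ++j) comb[j] = comb[j - 1] + 1;
  }
  (void)more;

  // overall factor (-1)^s
  int osgn = (s % 2 == 0) ? 1 : -1;

  int m = (int)acc.size();
  IntegerMatrix expo(m, n + l);
  NumericVector coef(m);
  int row = 0;
  for (const auto& term : acc) {
    uint32_t hmask = term.first.first;
    uint64_t lkey = term.first.second;
    for (int j = 0; j < n; ++j) expo(row, j) = (hmask >> j) & 1u;
    for (int k = 0; k < l; ++k) expo(row, n + k) = (int)((lkey >> (BITS * k)) & EMASK);
    ll c = osgn * term.second;
    if (c >= (ll)1 << 53 || c <= -((ll)1 << 53))
      stop("coefficient exceeds exact double range");
    coef[row] = (double)c;
    ++row;
  }
  return List::create(_["exponents"] = expo, _["coef"] = coef);
}
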