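#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <string>
#include <vector>

using namespace Rcpp;

// Levenshtein distance bounded by tau via a banded DP.  Returns the distance
// when it is <= tau and -1 otherwise.  Cost is O(tau * min(la, lb)): only the
// diagonal band of half-width tau is filled, and a row whose band minimum
// already exceeds tau aborts the whole computation.
static int banded_lev(const char *a, int la, const char *b, int lb, int tau) {
  if (tau < 0) return -1;
  if (la > lb) {
    std::swap(a, b);
    std::swap(la, lb);
  }
  if (lb - la > tau) return -1;
  if (la == 0) return (lb <= tau) ? lb : -1;
  const int INF = tau + 1;
  std::vector<int> prev(lb + 2), cur(lb + 2);
  for (int j = 0; j <= lb; ++j) prev[j] = (j <= tau) ? j : INF;
  for (int i = 1; i <= la; ++i) {
    int lo = i - tau;
    if (lo < 1) lo = 1;
    int hi = i + tau;
    if (hi > lb) hi = lb;
    cur[lo - 1] = (lo - 1 == 0) ? ((i <= tau) ? i : INF) : INF;
    int best = INF;
    for (int j = lo; j <= hi; ++j) {
      int v = prev[j] + 1;                                   // delete from a
      int e = cur[j - 1] + 1;                                // insert into a
      int f = prev[j - 1] + ((a[i - 1] == b[j - 1]) ? 0 : 1);  // substitute
      if (e < v) v = e;
      if (f < v) v = f;
      if (v > INF) v = INF;
      cur[j] = v;
      if (v < best) best = v;
    }
    // guard cell so the next row reads INF just outside this row's band
    if (hi + 1 <= lb) cur[hi + 1] = INF;
    if (best >= INF) return -1;
    prev.swap(cur);
  }
  return (prev[lb] <= tau) ? prev[lb] : -1;
}

// method: 0 = plain edit, 1 = reversal (min over both orientations of a),
// 2 = truncation (longer string truncated, free of charge, to the shorter
// length before the edit computation).
static int bounded_method(const std::string &a, const std::string &b, int tau,
                          int method) {
  if (method == 0)
    return banded_lev(a.c_str(), (int)a.size(), b.c_str(), (int)b.size(), tau);
  if (method == 1) {
    int d1 = banded_lev(a.c_str(), (int)a.size(), b.c_str(), (int)b.size(), tau);
    std::string ar(a.rbegin(), a.rend());
    int d2 = banded_lev(ar.c_str(), (int)ar.size(), b.c_str(), (int)b.size(), tau);
    if (d1 < 0) return d2;
    if (d2 < 0) return d1;
    return std::min(d1, d2);
  }
  int l = (int)std::min(a.size(), b.size());
  return banded_lev(a.c_str(), l, b.c_str(), l, tau);
}

// [[Rcpp::export]]
IntegerVector cpp_bounded_dist(CharacterVector a, CharacterVector b,
                               IntegerVector tau, int method) {
  R_xlen_t n = std::max(a.size(), b.size());
  if (a.size() != n && a.size() != 1)
    stop("lengths of 'a' and 'b' must match (or be 1)");
  if (b.size() != n && b.size() != 1)
    stop("lengths of 'a' and 'b' must match (or be 1)");
  if (tau.size() != n && tau.size() != 1)
    stop("'tau' must have length 1 or length of the string vectors");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP sa = a[a.size() == 1 ? 0 : i];
    SEXP sb = b[b.size() == 1 ? 0 : i];
    int t = tau[tau.size() == 1 ? 0 : i];
    if (sa == NA_STRING || sb == NA_STRING || t == NA_INTEGER) {
      out[i] = NA_INTEGER;
      continue;
    }
    std::string va = CHAR(sa), vb = CHAR(sb);
    out[i] = bounded_method(va, vb, t, method);
  }
  return out;
}

// Summed per-attribute bounded distance between record pairs.  cols_a and
// cols_b hold one character vector per comparison attribute, aligned over
// pairs; NA marks an attribute absent from a record's dataset schema.
// Returns the sum when <= the pair budget, -1 when it exceeds it, and -2
// when the pair shares no comparison attribute.
// [[Rcpp::export]]
IntegerVector cpp_record_distance(List cols_a, List cols_b, int tau,
                                  int method, bool proportional, double rho) {
  int natt = cols_a.size();
  if (natt == 0) stop("no comparison attributes");
  CharacterVector first = cols_a[0];
  R_xlen_t np = first.size();
  std::vector<CharacterVector> ca(natt), cb(natt);
  for (int j = 0; j < natt; ++j) {
    ca[j] = as<CharacterVector>(cols_a[j]);
    cb[j] = as<CharacterVector>(cols_b[j]);
    if (ca[j].size() != np || cb[j].size() != np)
      stop("all attribute columns must have the same length");
  }
  IntegerVector out(np);
  for (R_xlen_t i = 0; i < np; ++i) {
    int budget = tau;
    bool shared = false;
    if (proportional) {
      int la = 0, lb = 0;
      for (int j = 0; j < natt; ++j) {
        SEXP sa = ca[j][i], sb = cb[j][i];
        if (sa == NA_STRING || sb == NA_STRING) continue;
        shared = true;
        la += (int)std::strlen(CHAR(sa));
        lb += (int)std::strlen(CHAR(sb));
      }
      if (!shared) {
        out[i] = -2;
        continue;
      }
      budget = (int)std::ceil(rho * (double)std::min(la, lb));
      shared = false;
    }
    int sum = 0;
    bool exceeded = false;
    for (int j = 0; j < natt; ++j) {
      SEXP sa = ca[j][i], sb = cb[j][i];
      if (sa == NA_STRING || sb == NA_STRING) continue;
      shared = true;
      std::string va = CHAR(sa), vb = CHAR(sb);
      int d = bounded_method(va, vb, budget - sum, method);
      if (d < 0) {
        exceeded = true;
        break;
      }
      sum += d;
    }
    out[i] = shared ? (exceeded ? -1 : sum) : -2;
  }
  return out;
}

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];  // path halving
      x = parent[x];
    }
    return x;
  }
  void unite(int x, int y) {
    int rx = find(x), ry = find(y);
    if (rx != ry) parent[std::max(rx, ry)] = std::min(rx, ry);
  }
};

// Connected components over nodes 1..n given an edge list (1-based).
// Labels are 1-based, assigned in order of each component's smallest member.
// [[Rcpp::export]]
IntegerVector cpp_components(int n, IntegerVector u, IntegerVector v) {
  if (u.size() != v.size()) stop("edge endpoint vectors differ in length");
  UnionFind uf(n);
  for (R_xlen_t e = 0; e < u.size(); ++e) {
    int a = u[e], b = v[e];
    if (a < 1 || a > n || b < 1 || b > n) stop("edge endpoint out of range");
    uf.unite(a - 1, b - 1);
  }
  IntegerVector lab(n);
  std::vector<int> label_of_root(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    if (label_of_root[r] == 0) label_of_root[r] = ++next;
    lab[i] = label_of_root[r];
  }
  return lab;
}
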