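#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving double-edge-swap rewiring for binary networks.
// Moves are attempted `nswaps` times; proposals creating self-loops or
// parallel edges are rejected, so node degrees are invariants of the chain.
// With `preserve_triangles` a proposal is additionally rejected unless the
// global triangle count is unchanged (Metropolis-style zero-tolerance move).
//
// Edge endpoints are 0-based. R's RNG is used (Rcpp attributes wrap the
// call in an RNGScope), so set.seed() governs reproducibility.

static inline int runif_int(int n) {
  int k = (int)(R::unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// common neighbours of a and b in adjacency A (n x n, row-major)
static inline int common_nbrs(const std::vector<unsigned char>& A, int n,
                              int a, int b) {
  const unsigned char* ra = &A[(size_t)a * n];
  const unsigned char* rb = &A[(size_t)b * n];
  int c = 0;
  for (int v = 0; v < n; ++v) c += ra[v] & rb[v];
  return c;
}

// [[Rcpp::export]]
IntegerMatrix cpp_rewire_undirected(const IntegerMatrix& edges, int n,
                                    int nswaps, bool preserve_triangles) {
  int m = edges.nrow();
  if (m < 2) return edges;
  std::vector<int> ea(m), eb(m);
  std::vector<unsigned char> A((size_t)n * n, 0);
  for (int e = 0; e < m; ++e) {
    ea[e] = edges(e, 0);
    eb[e] = edges(e, 1);
    A[(size_t)ea[e] * n + eb[e]] = 1;
    A[(size_t)eb[e] * n + ea[e]] = 1;
  }
#define HAS(i, j) A[(size_t)(i) * n + (j)]
#define SET(i, j, v)                     \
  {                                      \
    A[(size_t)(i) * n + (j)] = (v);      \
    A[(size_t)(j) * n + (i)] = (v);      \
  }
  for (int it = 0; it < nswaps; ++it) {
    int e1 = runif_int(m), e2 = runif_int(m);
    if (e1 == e2) continue;
    int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
    if (R::unif_rand() < 0.5) std::swap(c, d);
    // propose (a,b),(c,d) -> (a,d),(c,b)
    if (a == d || c == b || a == c || b == d) continue;
    if (HAS(a, d) || HAS(c, b)) continue;
    if (preserve_triangles) {
      int t_old = common_nbrs(A, n, a, b) + common_nbrs(A, n, c, d);
      SET(a, b, 0);
      SET(c, d, 0);
      int t_new = common_nbrs(A, n, a, d) + common_nbrs(A, n, c, b);
      if (t_new != t_old) {  // reject: restore
        SET(a, b, 1);
        SET(c, d, 1);
        continue;
      }
      SET(a, d, 1);
      SET(c, b, 1);
    } else {
      SET(a, b, 0);
      SET(c, d, 0);
      SET(a, d, 1);
      SET(c, b, 1);
    }
    ea[e1] = a; eb[e1] = d;
    ea[e2] = c; eb[e2] = b;
  }
#undef HAS
#undef SET
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = ea[e];
    out(e, 1) = eb[e];
  }
  return out;
}

// Directed rewiring preserving in-degree, out-degree, and each node's
// counts of unidirectional and bidirectional connections: unidirectional
// arcs and mutual pairs form disjoint pools, and swaps act within a pool.
// A proposal is rejected if it would connect a pair that is already
// connected in either direction (which would merge the pools).
// `asym` holds arcs a->b with no reciprocal; `mut` holds mutual pairs.

// [[Rcpp::export]]
List cpp_rewire_directed(const IntegerMatrix& asym, const IntegerMatrix& mut,
                         int n, int nswaps_asym, int nswaps_mut) {
  int ma = asym.nrow(), mm = mut.nrow();
  std::vector<int> aa(ma), ab(ma), ua(mm), ub(mm);
  std::vector<unsigned char> C((size_t)n * n, 0);  // connected either way
  for (int e = 0; e < ma; ++e) {
    aa[e] = asym(e, 0);
    ab[e] = asym(e, 1);
    C[(size_t)aa[e] * n + ab[e]] = 1;
    C[(size_t)ab[e] * n + aa[e]] = 1;
  }
  for (int e = 0; e < mm; ++e) {
    ua[e] = mut(e, 0);
    ub[e] = mut(e, 1);
    C[(size_t)ua[e] * n + ub[e]] = 1;
    C[(size_t)ub[e] * n + ua[e]] = 1;
  }
#define CON(i, j) C[(size_t)(i) * n + (j)]
#define SETC(i, j, v)                    \
  {                                      \
    C[(size_t)(i) * n + (j)] = (v);      \
    C[(size_t)(j) * n + (i)] = (v);      \
  }
  if (ma >= 2) {
    for (int it = 0; it < nswaps_asym; ++it) {
      int e1 = runif_int(ma), e2 = runif_int(ma);
      if (e1 == e2) continue;
      int a = aa[e1], b = ab[e1], c = aa[e2], d = ab[e2];
      // propose a->b, c->d  ->  a->d, c->b (keeps out- and in-stubs)
      if (a == d || c == b || a == c || b == d) continue;
      if (CON(a, d) || CON(c, b)) continue;
      SETC(a, b, 0);
      SETC(c, d, 0);
      SETC(a, d, 1);
      SETC(c, b, 1);
      ab[e1] = d;
      ab[e2] = b;
    }
  }
  if (mm >= 2) {
    for (int it = 0; it < nswaps_mut; ++it) {
      int e1 = runif_int(mm), e2 = runif_int(mm);
      if (e1 == e2) continue;
      int a = ua[e1], b = ub[e1], c = ua[e2], d = ub[e2];
      if (R::unif_rand() < 0.5) std::swap(c, d);
      if (a == d || c == b || a == c || b == d) continue;
      if (CON(a, d) || CON(c, b)) continue;
      SETC(a, b, 0);
      SETC(c, d, 0);
      SETC(a, d, 1);
      SETC(c, b, 1);
      ua[e1] = a; ub[e1] = d;
      ua[e2] = c; ub[e2] = b;
    }
  }
#undef CON
#undef SETC
  IntegerMatrix oa(ma, 2), om(mm, 2);
  for (int e = 0; e < ma; ++e) {
    oa(e, 0) = aa[e];
    oa(e, 1) = ab[e];
  }
  for (int e = 0; e < mm; ++e) {
    om(e, 0) = ua[e];
    om(e, 1) = ub[e];
  }
  return List::create(_["asym"] = oa, _["mutual"] = om);
}
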