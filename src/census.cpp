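#include <Rcpp.h>
using namespace Rcpp;

// Induced-subgraph census by exhaustive subset enumeration.
//
// The subset {v1 < v2 < ... < vk} is encoded as a bit pattern over its
// vertex pairs taken in lexicographic order (v1,v2),(v1,v3),...,(v2,v3),...
// Undirected: one bit per pair. Directed: two bits per pair, low bit for
// the a->b arc (a < b), high bit for b->a. `classmap` (computed in R by
// enumerating all labelled graphs and grouping by isomorphism) maps each
// pattern to a 1-based isomorphism-class index.
//
// Counts are returned as doubles: C(n,4) overflows 32-bit ints near n ~ 400.

// [[Rcpp::export]]
NumericVector cpp_census(const IntegerMatrix& adj, int size, bool directed,
                         const IntegerVector& classmap, int nclass) {
  const int n = adj.nrow();
  NumericVector counts(nclass);
  std::vector<unsigned char> A((size_t)n * n, 0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      A[(size_t)i * n + j] = adj(i, j) != 0 ? 1 : 0;
#define EDGE(i, j) A[(size_t)(i) * n + (j)]

  if (size == 2) {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        int code = directed ? (EDGE(i, j) | (EDGE(j, i) << 1)) : EDGE(i, j);
        counts[classmap[code] - 1] += 1;
      }
  } else if (size == 3) {
    for (int i = 0; i < n - 2; ++i) {
      for (int j = i + 1; j < n - 1; ++j) {
        int cij = directed ? (EDGE(i, j) | (EDGE(j, i) << 1)) : EDGE(i, j);
        for (int k = j + 1; k < n; ++k) {
          int code;
          if (directed) {
            code = cij | ((EDGE(i, k) | (EDGE(k, i) << 1)) << 2) |
                   ((EDGE(j, k) | (EDGE(k, j) << 1)) << 4);
          } else {
            code = cij | (EDGE(i, k) << 1) | (EDGE(j, k) << 2);
          }
          counts[classmap[code] - 1] += 1;
        }
      }
    }
  } else if (size == 4 && !directed) {
    for (int i = 0; i < n - 3; ++i) {
      for (int j = i + 1; j < n - 2; ++j) {
        int cij = EDGE(i, j);
        for (int k = j + 1; k < n - 1; ++k) {
          int cijk = cij | (EDGE(i, k) << 1) | (EDGE(j, k) << 3);
          for (int l = k + 1; l < n; ++l) {
            int code = cijk | (EDGE(i, l) << 2) | (EDGE(j, l) << 4) |
                       (EDGE(k, l) << 5);
            counts[classmap[code] - 1] += 1;
          }
        }
      }
    }
  } else {
    stop("unsupported census size/directedness combination");
  }
#undef EDGE
  return counts;
}
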