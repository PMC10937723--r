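#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// UPGMA agglomeration with a deterministic tie-break: among pairs at the
// minimal distance, merge the pair whose (sorted) representative labels are
// lexicographically smallest, a cluster's representative being its smallest
// member label. Output follows the stats::hclust merge/height convention.
// [[Rcpp::export(name = ".upgma_cpp")]]
List upgma_cpp(NumericMatrix d, CharacterVector labels) {
  const int n = d.nrow();
  if (n < 2) stop("need at least 2 leaves");
  std::vector<std::vector<double> > dist(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double v = d(i, j);
      if (ISNAN(v)) stop("NaN entry in dissimilarity matrix");
      dist[i][j] = v;
    }
  std::vector<bool> active(n, true);
  std::vector<int> size(n, 1);
  std::vector<int> node(n);          // hclust id: -(leaf+1) or merge step
  std::vector<std::string> rep(n);   // lexicographic representative label
  for (int i = 0; i < n; ++i) {
    node[i] = -(i + 1);
    rep[i] = as<std::string>(labels[i]);
  }
  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1);

  std::vector<int> alive(n);
  for (int i = 0; i < n; ++i) alive[i] = i;

  for (int step = 0; step < n - 1; ++step) {
    const int m = (int)alive.size();
    double dmin = R_PosInf;
    int bi = -1, bj = -1;
    std::string b1, b2;
    for (int ii = 0; ii < m; ++ii) {
      const int i = alive[ii];
      const double *row = &dist[i][0];
      for (int jj = ii + 1; jj < m; ++jj) {
        const int j = alive[jj];
        const double v = row[j];
        if (v > dmin) continue;
        if (v < dmin) {
          dmin = v;
          bi = i; bj = j;
          b1 = rep[i] < rep[j] ? rep[i] : rep[j];
          b2 = rep[i] < rep[j] ? rep[j] : rep[i];
        } else {
          std::string p1 = rep[i], p2 = rep[j];
          if (p2 < p1) std::swap(p1, p2);
          if (p1 < b1 || (p1 == b1 && p2 < b2)) {
            bi = i; bj = j; b1 = p1; b2 = p2;
          }
        }
      }
    }
    // hclust convention: singletons (negative) before merges, else by step
    int a = node[bi], b = node[bj];
    if ((a < 0 && b < 0 && a > b) || (a > 0 && b > 0 && a > b) ||
        (a > 0 && b < 0)) std::swap(a, b);
    merge(step, 0) = a;
    merge(step, 1) = b;
    height[step] = dmin;
    // size-weighted average linkage update into slot bi
    for (int kk = 0; kk < m; ++kk) {
      const int k = alive[kk];
      if (k == bi || k == bj) continue;
      double v = (size[bi] * dist[bi][k] + size[bj] * dist[bj][k]) /
                 (size[bi] + size[bj]);
      dist[bi][k] = v;
      dist[k][bi] = v;
    }
    size[bi] += size[bj];
    active[bj] = false;
    alive.erase(std::find(alive.begin(), alive.end(), bj));
    node[bi] = step + 1;
    if (rep[bj] < rep[bi]) rep[bi] = rep[bj];
  }
  return List::create(_["merge"] = merge, _["height"] = height);
}
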