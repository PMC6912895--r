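#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stored-matrix agglomerative clustering driven by the Lance-Williams update:
// after merging clusters i and j into m,
//   d(m,h) = ai*d(i,h) + aj*d(j,h) + beta*d(i,j) + gamma*|d(i,h) - d(j,h)|
// with (single: ai=aj=1/2, beta=0, gamma=-1/2), (complete: gamma=+1/2),
// (average: ai=ni/(ni+nj), aj=nj/(ni+nj), beta=gamma=0),
// (flexible_beta: ai=aj=(1-beta)/2, gamma=0).
// At each step the pair with the minimal current dissimilarity is merged;
// ties are broken by the lexicographically smallest pair of slot indices
// (a merged cluster keeps the smaller slot of its parents). O(n^3) worst
// case, adequate for the n <= ~1000 problem sizes this package targets.
//
// Returns the merge sequence in hclust layout: negative entries are leaves,
// positive entries refer to earlier merge steps.
// [[Rcpp::export(name = ".lw_agglomerate")]]
List lw_agglomerate(NumericMatrix D0, std::string method, double beta) {
  int n = D0.nrow();
  if (n < 2) stop("need at least two objects to agglomerate");

  int mcode;
  if (method == "single") mcode = 0;
  else if (method == "complete") mcode = 1;
  else if (method == "average") mcode = 2;
  else if (method == "flexible_beta") mcode = 3;
  else stop("unknown linkage method: %s", method.c_str());

  NumericMatrix d = clone(D0);
  std::vector<bool> active(n, true);
  std::vector<int> node(n);  // hclust id of the cluster occupying each slot
  std::vector<double> size(n, 1.0);
  for (int i = 0; i < n; ++i) node[i] = -(i + 1);

  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1);

  // Per-row nearest-neighbor cache over the active slots j > i; the merged
  // pair chosen from it is identical (including tie-breaks) to a full scan
  // of the stored matrix, found in amortized O(n) per step instead of O(n^2).
  std::vector<double> nnd(n, R_PosInf);
  std::vector<int> nn(n, -1);
  auto rescan_row = [&](int i) {
    nnd[i] = R_PosInf;
    nn[i] = -1;
    for (int j = i + 1; j < n; ++j) {
      if (!active[j]) continue;
      if (d(i, j) < nnd[i]) { nnd[i] = d(i, j); nn[i] = j; }
    }
  };
  for (int i = 0; i < n - 1; ++i) rescan_row(i);

  for (int step = 0; step < n - 1; ++step) {
    double best = R_PosInf;
    int bi = -1;
    for (int i = 0; i < n; ++i) {
      if (!active[i] || nn[i] < 0) continue;
      if (nnd[i] < best) { best = nnd[i]; bi = i; }
    }
    int bj = nn[bi];

    int a = node[bi], b = node[bj];
    // hclust row layout: leaves before internal nodes, each pair ascending
    bool swap;
    if (a < 0 && b < 0) swap = (-a) > (-b);
    else if (a > 0 && b > 0) swap = a > b;
    else swap = (a > 0);  // put the leaf first
    merge(step, 0) = swap ? b : a;
    merge(step, 1) = swap ? a : b;
    height[step] = best;

    double ni = size[bi], nj = size[bj], dij = d(bi, bj);
    double ai, aj, bpar, gam;
    switch (mcode) {
      case 0: ai = aj = 0.5; bpar = 0.0; gam = -0.5; break;
      case 1: ai = aj = 0.5; bpar = 0.0; gam = 0.5; break;
      case 2: ai = ni / (ni + nj); aj = nj / (ni + nj); bpar = 0.0; gam = 0.0; break;
      default: ai = aj = (1.0 - beta) / 2.0; bpar = beta; gam = 0.0; break;
    }

    for (int h = 0; h < n; ++h) {
      if (!active[h] || h == bi || h == bj) continue;
      double dh = ai * d(bi, h) + aj * d(bj, h) + bpar * dij +
                  gam * std::fabs(d(bi, h) - d(bj, h));
      d(bi, h) = dh;
      d(h, bi) = dh;
    }

    active[bj] = false;
    size[bi] = ni + nj;
    node[bi] = step + 1;

    // refresh the nearest-neighbor cache
    rescan_row(bi);
    for (int h = 0; h < bj; ++h) {
      if (!active[h] || h == bi) continue;
      if (nn[h] == bj) { rescan_row(h); continue; }
      if (h < bi) {
        double dv = d(h, bi);
        if (dv < nnd[h] || (dv == nnd[h] && bi < nn[h])) {
          nnd[h] = dv;
          nn[h] = bi;
        } else if (nn[h] == bi && dv > nnd[h]) {
          rescan_row(h);
        }
      }
    }
  }

  return List::create(_["merge"] = merge, _["height"] = height);
}
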