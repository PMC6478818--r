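#include <Rcpp.h>
using namespace Rcpp;

// Triplets of the full-state Moran transition matrix.
//
// States are mutant-configuration bitmasks 0 .. 2^n - 1 (state index =
// mask + 1, 1-based for R). For each non-absorbing mask, a reproducer u is
// chosen with probability f(u)/F (f = r for mutants, 1 for residents,
// F = sum of fitness) and its offspring lands on v with probability
// W(u, v); the target adopts the reproducer's type. Same-type replacements
// (including self-loops) leave the configuration unchanged and are kept as
// explicit self-transitions so that times count every Moran step.
// [[Rcpp::export]]
List moran_transition_triplets(NumericMatrix W, double r) {
  const int n = W.nrow();
  if (n > 30) stop("state space 2^n too large");
  const long nstates = 1L << n;

  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve(nstates * n);
  tj.reserve(nstates * n);
  tx.reserve(nstates * n);

  for (long mask = 1; mask < nstates - 1; ++mask) {
    int k = 0;
    for (int u = 0; u < n; ++u) if (mask >> u & 1L) ++k;
    const double F = n + (r - 1.0) * k;
    double hold = 0.0;
    for (int u = 0; u < n; ++u) {
      const bool umut = mask >> u & 1L;
      const double pu = (umut ? r : 1.0) / F;
      for (int v = 0; v < n; ++v) {
        const double w = W(u, v);
        if (w <= 0.0) continue;
        const double p = pu * w;
        long nxt = umut ? (mask | (1L << v)) : (mask & ~(1L << v));
        if (nxt == mask) {
          hold += p;
        } else {
          ti.push_back((int)(mask + 1));
          tj.push_back((int)(nxt + 1));
          tx.push_back(p);
        }
      }
    }
    if (hold > 0.0) {
      ti.push_back((int)(mask + 1));
      tj.push_back((int)(mask + 1));
      tx.push_back(hold);
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx), _["nstates"] = (double)nstates);
}
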