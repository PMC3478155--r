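#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Restricted single-hairpin minimum free energy dynamic program.
//
// Structures considered: pseudoknot-free, exactly one hairpin loop, no
// multiloops -- i.e. the base pairs form a single nested chain
// (i1,j1) > (i2,j2) > ... > (ik,jk) with the innermost loop >= 3 nt.
// Interior extensions (bulges / internal loops) are capped at `w` unpaired
// nucleotides per side. Exterior unpaired bases are free.
//
// seq: 0=A, 1=C, 2=G, 3=U. stack: 6x6 (outer pair row, inner pair col),
// pair index 1..6 = AU,UA,CG,GC,GU,UG. hairpinPen[k-1] = penalty of a
// hairpin loop of size k; bulgePen / internalPen likewise by size.

static inline int pair_index(int a, int b) {
  if (a == 0 && b == 3) return 1; // AU
  if (a == 3 && b == 0) return 2; // UA
  if (a == 1 && b == 2) return 3; // CG
  if (a == 2 && b == 1) return 4; // GC
  if (a == 2 && b == 3) return 5; // GU
  if (a == 3 && b == 2) return 6; // UG
  return 0;
}

// [[Rcpp::export]]
List fold_hairpin_cpp(IntegerVector seq, NumericMatrix stack,
                      NumericVector hairpinPen, NumericVector bulgePen,
                      NumericVector internalPen, int w) {
  const int n = seq.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> V((size_t)n * n, INF);
  auto idx = [n](int i, int j) { return (size_t)i * n + j; };

  // increasing span; i, j are 0-based, pair requires j - i - 1 >= 3
  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pt = pair_index(seq[i], seq[j]);
      if (pt == 0) continue;
      int loop = j - i - 1;
      double best = (loop <= (int)hairpinPen.size()) ? hairpinPen[loop - 1] : INF;
      int kmax = std::min(i + 1 + w, j - 1);
      for (int k = i + 1; k <= kmax; ++k) {
        int s1 = k - i - 1;
        int lmin = std::max(k + 4, j - 1 - w);
        for (int l = j - 1; l >= lmin; --l) {
          double sub = V[idx(k, l)];
          if (sub == INF) continue;
          int s2 = j - l - 1;
          double cost;
          if (s1 == 0 && s2 == 0) {
            cost = stack(pt - 1, pair_index(seq[k], seq[l]) - 1);
          } else if (s1 == 0 || s2 == 0) {
            cost = bulgePen[s1 + s2 - 1];
          } else {
            cost = internalPen[s1 + s2 - 1];
          }
          if (cost + sub < best) best = cost + sub;
        }
      }
      V[idx(i, j)] = best;
    }
  }

  // outermost pair: 5'-most, then longest span among strict improvements
  double mfe = 0.0;
  int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i)
    for (int j = n - 1; j > i; --j)
      if (V[idx(i, j)] < mfe) { mfe = V[idx(i, j)]; bi = i; bj = j; }

  std::string db(n, '.');
  if (bi >= 0) {
    int i = bi, j = bj;
    while (true) {
      db[i] = '('; db[j] = ')';
      int pt = pair_index(seq[i], seq[j]);
      int loop = j - i - 1;
      double here = V[idx(i, j)];
      double hp = (loop <= (int)hairpinPen.size()) ? hairpinPen[loop - 1] : INF;
      if (here == hp) break; // hairpin loop closes the chain
      bool found = false;
      int kmax = std::min(i + 1 + w, j - 1);
      for (int k = i + 1; k <= kmax && !found; ++k) {
        int s1 = k - i - 1;
        int lmin = std::max(k + 4, j - 1 - w);
        for (int l = j - 1; l >= lmin; --l) {
          double sub = V[idx(k, l)];
          if (sub == INF) continue;
          int s2 = j - l - 1;
          double cost;
          if (s1 == 0 && s2 == 0) {
            cost = stack(pt - 1, pair_index(seq[k], seq[l]) - 1);
          } else if (s1 == 0 || s2 == 0) {
            cost = bulgePen[s1 + s2 - 1];
          } else {
            cost = internalPen[s1 + s2 - 1];
          }
          if (cost + sub == here) { i = k; j = l; found = true; break; }
        }
      }
      if (!found) stop("traceback failed (internal error)");
    }
  }
  return List::create(_["structure"] = db, _["dG"] = (bi >= 0) ? mfe : 0.0);
}
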