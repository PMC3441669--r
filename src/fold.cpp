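#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pair energies (kcal/mol) of the simple stacking-free model: GC -3, AU -2,
// GU -1; anything else cannot pair. Sequence must be upper-case RNA (ACGU).
static inline double pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 1.0; // sentinel: not pairable
}

// Minimum-energy nested folding by interval dynamic programming with a
// minimum hairpin loop of `min_loop` unpaired bases. Ties are broken
// deterministically: pairing the 5'-most open position beats leaving it
// unpaired, and among equal-energy partners the 3'-most partner wins
// (keeps helices contiguous in stem-loops instead of pairing into the
// hairpin loop).
// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  if (n == 0) return List::create(_["structure"] = "", _["mfe"] = 0.0);

  std::vector<double> E((size_t) n * n, 0.0);
  // choice: -1 => i unpaired; k >= 0 => i paired with k
  std::vector<int> C((size_t) n * n, -1);
  #define IDX(i, j) ((size_t)(i) * n + (j))

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double best = R_PosInf;
      int choice = -1;
      // pairing options first so that, on ties, pairing i wins; descending
      // k so that, among equal-energy partners, the 3'-most wins
      for (int k = j; k >= i + min_loop + 1; --k) {
        double pe = pair_energy(seq[i], seq[k]);
        if (pe > 0) continue;
        double e = pe + E[IDX(i + 1, k - 1)];
        if (k + 1 <= j) e += E[IDX(k + 1, j)];
        if (e < best) { best = e; choice = k; }
      }
      double skip = E[IDX(i + 1, j)];
      if (skip < best) { best = skip; choice = -1; }
      if (best == R_PosInf) { best = 0.0; choice = -1; }
      E[IDX(i, j)] = best;
      C[IDX(i, j)] = choice;
    }
  }

  std::string db(n, '.');
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    int k = C[IDX(i, j)];
    if (k < 0) {
      stack.push_back(std::make_pair(i + 1, j));
    } else {
      db[i] = '(';
      db[k] = ')';
      stack.push_back(std::make_pair(i + 1, k - 1));
      if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
    }
  }

  double mfe = (n > min_loop + 1) ? E[IDX(0, n - 1)] : 0.0;
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}
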