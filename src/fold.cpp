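#include <Rcpp.h>
#include <string>
#include <vector>
#include <utility>

using namespace Rcpp;

// Fixed per-pair stacking-free energies (kcal/mol). 'N' never pairs.
static inline double pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 0.0;
}

static inline bool can_pair(char a, char b) {
  return pair_energy(a, b) < 0.0;
}

// Maximum-pairing (Nussinov) folding recast as energy minimization:
// E(i,j) = min( E(i+1,j), E(i,j-1), E(i+1,j-1) + e(i,j) [if pairable,
// loop >= min_loop], min_k E(i,k) + E(k+1,j) ).  Returns the minimum
// energy and one optimal structure in dot-bracket notation.
// [[Rcpp::export(name = ".fold_min_energy")]]
List fold_min_energy(std::string seq, int min_loop = 3) {
  const int n = static_cast<int>(seq.size());
  std::string db(n, '.');
  if (n < 2) return List::create(_["mfe"] = 0.0, _["structure"] = db);

  std::vector<std::vector<double> > E(n, std::vector<double>(n, 0.0));
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      double best = E[i + 1][j];
      if (E[i][j - 1] < best) best = E[i][j - 1];
      if (j - i - 1 >= min_loop && can_pair(seq[i], seq[j])) {
        const double v = E[i + 1][j - 1] + pair_energy(seq[i], seq[j]);
        if (v < best) best = v;
      }
      for (int k = i + 1; k <= j - 2; ++k) {
        const double v = E[i][k] + E[k + 1][j];
        if (v < best) best = v;
      }
      E[i][j] = best;
    }
  }

  // Traceback mirrors the recursion order exactly.
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    const int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    const double e = E[i][j];
    if (e == E[i + 1][j]) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    if (e == E[i][j - 1]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    if (j - i - 1 >= min_loop && can_pair(seq[i], seq[j]) &&
        e == E[i + 1][j - 1] + pair_energy(seq[i], seq[j])) {
      db[i] = '(';
      db[j] = ')';
      stack.push_back(std::make_pair(i + 1, j - 1));
      continue;
    }
    for (int k = i + 1; k <= j - 2; ++k) {
      if (e == E[i][k] + E[k + 1][j]) {
        stack.push_back(std::make_pair(i, k));
        stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }

  return List::create(_["mfe"] = E[0][n - 1], _["structure"] = db);
}
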