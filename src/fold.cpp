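#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Weighted base-pair maximization (Nussinov-style) over GC/AU/GU pairs
// with a minimum hairpin-loop constraint. Deterministic traceback:
// position i is left unpaired only when no pairing partner achieves the
// optimum; among tying partners the smallest k is chosen.

static double pair_weight(char a, char b, double wGC, double wAU,
                          double wGU) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return wGC;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return wAU;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return wGU;
  return -1.0; // disallowed
}

// [[Rcpp::export(name = ".fold_maxpair_cpp")]]
List fold_maxpair_cpp(std::string seq, int min_loop, double wGC,
                      double wAU, double wGU) {
  int n = seq.size();
  std::vector<std::vector<double> > M(n + 2,
                                      std::vector<double>(n + 2, 0.0));
  // choice[i][j]: 0 = i unpaired, k>0 = i pairs with k (1-based)
  std::vector<std::vector<int> > choice(n + 2, std::vector<int>(n + 2, 0));

  for (int span = 2; span <= n; ++span) {
    for (int i = 1; i + span - 1 <= n; ++i) {
      int j = i + span - 1;
      double best = M[i + 1][j];
      int ch = 0;
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double w = pair_weight(seq[i - 1], seq[k - 1], wGC, wAU, wGU);
        if (w < 0) continue;
        double inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0.0;
        double outer = (k + 1 <= j) ? M[k + 1][j] : 0.0;
        double s = w + inner + outer;
        // pairing preferred over leaving i unpaired; smallest k on ties
        if (s > best + 1e-9 || (ch == 0 && s > best - 1e-9)) {
          best = s;
          ch = k;
        }
      }
      M[i][j] = best;
      choice[i][j] = ch;
    }
  }

  std::string structure(n, '.');
  // iterative traceback over interval stack
  std::vector<std::pair<int, int> > stack;
  if (n >= 2) stack.push_back(std::make_pair(1, n));
  while (!stack.empty()) {
    std::pair<int, int> iv = stack.back();
    stack.pop_back();
    int i = iv.first, j = iv.second;
    if (i >= j) continue;
    int k = choice[i][j];
    if (k == 0) {
      stack.push_back(std::make_pair(i + 1, j));
    } else {
      structure[i - 1] = '(';
      structure[k - 1] = ')';
      if (k - 1 > i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
      if (j > k + 1) stack.push_back(std::make_pair(k + 1, j));
    }
  }

  return List::create(_["structure"] = structure,
                      _["pair_score"] = (n >= 2) ? M[1][n] : 0.0);
}
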