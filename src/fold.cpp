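#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Nussinov-style maximum base-pairing dynamic program over {AU,UA,GC,CG,GU,UG}
// with a minimum hairpin loop of 3 unpaired bases. Surrogate energy is
// -(pair count); traceback is deterministic (outermost pair at the smallest i,
// closing partner at the smallest admissible j).

static const int MIN_LOOP = 3;

static inline bool can_pair(char a, char b) {
  switch (a) {
    case 'A': return b == 'U';
    case 'U': return b == 'A' || b == 'G';
    case 'G': return b == 'C' || b == 'U';
    case 'C': return b == 'G';
  }
  return false;
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int forbid_i = -1, int forbid_j = -1) {
  const int n = (int) seq.size();
  // forbid_i/forbid_j come in 1-based from R; -1 means no constraint
  const int fi = forbid_i - 1, fj = forbid_j - 1;
  if (n == 0) stop("empty sequence");
  std::vector<int> N((size_t) n * n, 0);
#define NN(i, j) N[(size_t) (i) * n + (j)]
  for (int span = MIN_LOOP + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = NN(i + 1, j); // i unpaired
      const char si = seq[i];
      for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
        if (!can_pair(si, seq[k])) continue;
        if (i == fi && k == fj) continue;
        int v = 1 + (k > i + 1 ? NN(i + 1, k - 1) : 0)
                  + (k < j ? NN(k + 1, j) : 0);
        if (v > best) best = v;
      }
      NN(i, j) = best;
    }
  }
  std::string db(n, '.');
  // iterative traceback over a stack of (i, j) regions
  std::vector<std::pair<int, int> > todo;
  if (n > MIN_LOOP + 1) todo.push_back(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.back().first, j = todo.back().second;
    todo.pop_back();
    while (i < j) {
      if (j - i <= MIN_LOOP) break;
      int target = NN(i, j);
      if (target == 0) break;
      bool paired = false;
      for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        if (i == fi && k == fj) continue;
        int v = 1 + (k > i + 1 ? NN(i + 1, k - 1) : 0)
                  + (k < j ? NN(k + 1, j) : 0);
        if (v == target) {
          db[i] = '(';
          db[k] = ')';
          if (k < j) todo.push_back(std::make_pair(k + 1, j));
          i = i + 1;
          j = k - 1;
          paired = true;
          break;
        }
      }
      if (!paired) i = i + 1; // position i is unpaired in the optimum
    }
  }
  int pairs = (n > MIN_LOOP + 1) ? NN(0, n - 1) : 0;
#undef NN
  return List::create(_["structure"] = db, _["n_pairs"] = pairs);
}
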