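#include <Rcpp.h>
#include <string>
#include <vector>
#include <stack>
using namespace Rcpp;

// AU, GC and GU wobble pairs over the RNA alphabet
static inline bool pairable(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum base-pair count fold (Nussinov) with a minimum hairpin loop of
// `min_loop` unpaired nt. Returns the dot-bracket string of one maximising
// structure and the pair count.
// [[Rcpp::export]]
List nussinov_cpp(std::string seq, int min_loop = 3) {
  int n = seq.size();
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!pairable(seq[k], seq[j])) continue;
        int left = (k > i) ? M[i][k - 1] : 0;
        int right = (k + 1 <= j - 1) ? M[k + 1][j - 1] : 0;
        int cand = left + right + 1;
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }

  std::string db(n, '.');
  std::stack<std::pair<int, int> > todo;
  if (n > min_loop + 1) todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.top().first, j = todo.top().second;
    todo.pop();
    if (j - i <= min_loop) continue;
    if (M[i][j] == M[i][j - 1]) {
      todo.push(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (!pairable(seq[k], seq[j])) continue;
      int left = (k > i) ? M[i][k - 1] : 0;
      int right = M[k + 1][j - 1];
      if (M[i][j] == left + right + 1) {
        db[k] = '(';
        db[j] = ')';
        if (k > i) todo.push(std::make_pair(i, k - 1));
        todo.push(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }

  int n_pairs = (n > 0) ? M[0][n - 1] : 0;
  return List::create(_["structure"] = db, _["n_pairs"] = n_pairs);
}
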