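#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// Weighted base-pair maximization (Nussinov-style) over pseudoknot-free
// structures with a minimum hairpin loop. Returns the maximum total pair
// score and one optimal structure; ties in traceback pair position i with
// the smallest admissible partner.

static double pair_score(char a, char b, double gc, double au, double gu) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return gc;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return au;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return gu;
  return -1.0; // not pairable
}

// [[Rcpp::export]]
List nussinov_fold(std::string seq, double score_gc, double score_au,
                   double score_gu, int min_loop) {
  int n = seq.size();
  std::string db(n, '.');
  if (n == 0)
    return List::create(_["score"] = 0.0, _["structure"] = db);

  std::vector<std::vector<double>> N(n, std::vector<double>(n, 0.0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = N[i + 1][j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double s = pair_score(seq[i], seq[k], score_gc, score_au, score_gu);
        if (s < 0) continue;
        double cand = s + (k - i >= 2 ? N[i + 1][k - 1] : 0.0) +
                      (k < j ? N[k + 1][j] : 0.0);
        if (cand > best) best = cand;
      }
      N[i][j] = best;
    }
  }

  // traceback: prefer pairing i with the smallest admissible partner
  std::stack<std::pair<int, int>> todo;
  todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.top().first, j = todo.top().second;
    todo.pop();
    if (j - i < min_loop + 1) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      double s = pair_score(seq[i], seq[k], score_gc, score_au, score_gu);
      if (s < 0) continue;
      double cand = s + (k - i >= 2 ? N[i + 1][k - 1] : 0.0) +
                    (k < j ? N[k + 1][j] : 0.0);
      if (cand == N[i][j]) {
        db[i] = '(';
        db[k] = ')';
        if (k - i >= 2) todo.push(std::make_pair(i + 1, k - 1));
        if (k < j) todo.push(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) todo.push(std::make_pair(i + 1, j));
  }

  return List::create(_["score"] = N[0][n - 1], _["structure"] = db);
}
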