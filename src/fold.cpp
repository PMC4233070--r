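#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Additive base-pair energy proxy (kcal/mol): GC = -3, AU = -2, GU = -1.
// Input is expected in DNA alphabet (U already mapped to T by the caller).
static inline double pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return -1.0;
  return 0.0; // not pairable
}

static const double INF = std::numeric_limits<double>::infinity();
static const int MINLOOP = 3;

// Minimum-energy nested structure with no isolated (lonely) base pairs:
// every pair must be stacked on a neighbouring pair. Three-state interval
// dynamic programming:
//   W(i,j)  : best energy of any admissible structure on [i,j]
//   P1(i,j) : (i,j) paired with inner support ((i+1,j-1) also paired) —
//             usable as the outermost pair of a helix
//   P2(i,j) : (i,j) paired given outer support ((i-1,j+1) is paired)
// Recursions:
//   P2(i,j) = e(i,j) + min(W(i+1,j-1), P2(i+1,j-1))
//   P1(i,j) = e(i,j) + P2(i+1,j-1)
//   W(i,j)  = min(W(i+1,j), min_k P1(i,k) + W(k+1,j))
// with pairing allowed only when pairable and j-i-1 >= MINLOOP.
// [[Rcpp::export(name = ".fold_nussinov")]]
List fold_nussinov(std::string seq) {
  const int n = (int) seq.size();
  if (n == 0) return List::create(_["structure"] = "", _["mfe"] = 0.0);

  auto can = [&](int i, int j) {
    return j - i - 1 >= MINLOOP && pair_energy(seq[i], seq[j]) < 0.0;
  };

  std::vector<std::vector<double>> W(n, std::vector<double>(n, 0.0));
  std::vector<std::vector<double>> P1(n, std::vector<double>(n, INF));
  std::vector<std::vector<double>> P2(n, std::vector<double>(n, INF));
  // W trace: -1 = i unpaired, k >= 0 = helix P1(i,k) then W(k+1,j)
  std::vector<std::vector<int>> trW(n, std::vector<int>(n, -1));
  // P2 trace: 1 = stack continues (P2 inside), 0 = interior is W
  std::vector<std::vector<char>> trP2(n, std::vector<char>(n, 0));

  for (int span = MINLOOP + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (can(i, j)) {
        double e = pair_energy(seq[i], seq[j]);
        double inner_w = W[i + 1][j - 1];
        double inner_p2 = can(i + 1, j - 1) ? P2[i + 1][j - 1] : INF;
        if (inner_p2 < inner_w) {
          P2[i][j] = e + inner_p2;
          trP2[i][j] = 1;
        } else {
          P2[i][j] = e + inner_w;
          trP2[i][j] = 0;
        }
        if (inner_p2 < INF) P1[i][j] = e + inner_p2;
      }
      double best = W[i + 1][j];
      int arg = -1;
      for (int k = i + MINLOOP + 2; k <= j; ++k) {
        if (P1[i][k] == INF) continue;
        double cand = P1[i][k] + (k + 1 <= j ? W[k + 1][j] : 0.0);
        if (cand < best - 1e-12) { best = cand; arg = k; }
      }
      W[i][j] = best;
      trW[i][j] = arg;
    }
  }

  // Traceback to dot-bracket.
  std::string db(n, '.');
  // stack entries: (state, i, j); state 0 = W, 1 = helix rooted at (i,j)
  struct Frame { int state, i, j; };
  std::vector<Frame> stack;
  stack.push_back({0, 0, n - 1});
  while (!stack.empty()) {
    Frame f = stack.back();
    stack.pop_back();
    int i = f.i, j = f.j;
    if (i >= j) continue;
    if (f.state == 0) {
      int k = trW[i][j];
      if (k < 0) {
        stack.push_back({0, i + 1, j});
      } else {
        // helix: pairs (i,k) and (i+1,k-1), then follow P2 inward
        db[i] = '('; db[k] = ')';
        stack.push_back({1, i + 1, k - 1});
        if (k + 1 < j + 1) stack.push_back({0, k + 1, j});
      }
    } else {
      // P2 state: (i,j) is paired
      db[i] = '('; db[j] = ')';
      if (trP2[i][j] == 1) {
        stack.push_back({1, i + 1, j - 1});
      } else {
        stack.push_back({0, i + 1, j - 1});
      }
    }
  }

  return List::create(_["structure"] = db, _["mfe"] = W[0][n - 1]);
}
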