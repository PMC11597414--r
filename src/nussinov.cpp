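#include <Rcpp.h>
#include <vector>
#include <stack>
#include <cstring>
using namespace Rcpp;

// Watson-Crick + GU wobble pairing on DNA alphabet (T plays U's role).
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': case 'U': return 3;
    default: return 4;
  }
}

static const bool PAIR_OK[5][5] = {
  //        A      C      G      T      N
  /*A*/ {false, false, false, true,  false},
  /*C*/ {false, false, true,  false, false},
  /*G*/ {false, true,  false, true,  false},
  /*T*/ {true,  false, true,  false, false},
  /*N*/ {false, false, false, false, false}
};

// Nussinov base-pair maximization with a minimum hairpin loop of min_loop
// unpaired nucleotides. D is kept twice (row-major and transposed) so the
// inner maximization walks contiguous memory. Returns the optimal pair
// count and one optimal set of pairs (0-based positions).
// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string s, int min_loop = 3) {
  const int n = (int) s.size();
  if (n == 0)
    return List::create(_["max_pairs"] = 0,
                        _["pairs"] = IntegerMatrix(0, 2));
  std::vector<int> b(n);
  for (int i = 0; i < n; ++i) b[i] = base_code(s[i]);

  typedef short cell;
  std::vector<cell> D((size_t) n * n, 0);   // D[i*n+j]
  std::vector<cell> T((size_t) n * n, 0);   // T[j*n+i] = D[i][j]
  #define DD(i, j) D[(size_t)(i) * n + (j)]
  #define TT(i, j) T[(size_t)(j) * n + (i)]

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      int best = DD(i + 1, j);                     // i unpaired
      const cell *rowi1 = &D[(size_t)(i + 1) * n]; // D[i+1][.]
      const cell *colj  = &T[(size_t) j * n];      // D[.][j]
      const int bi = b[i];
      // k = j (pair closes at the end): no right part
      if (PAIR_OK[bi][b[j]]) {
        int v = 1 + rowi1[j - 1];
        if (v > best) best = v;
      }
      for (int k = i + min_loop + 1; k < j; ++k) {
        if (!PAIR_OK[bi][b[k]]) continue;
        int v = 1 + rowi1[k - 1] + colj[k + 1];
        if (v > best) best = v;
      }
      DD(i, j) = (cell) best;
      TT(i, j) = (cell) best;
    }
  }

  // traceback (iterative)
  std::vector<std::pair<int, int> > pairs;
  std::stack<std::pair<int, int> > st;
  st.push(std::make_pair(0, n - 1));
  while (!st.empty()) {
    std::pair<int, int> ij = st.top(); st.pop();
    int i = ij.first, j = ij.second;
    if (i >= j || j - i < min_loop + 1) continue;
    // prefer closing a pair at i over leaving i unpaired, so that optimal
    // helices are traced as contiguous stems
    bool done = false;
    for (int k = j; k >= i + min_loop + 1 && !done; --k) {
      if (!PAIR_OK[b[i]][b[k]]) continue;
      int v = 1 + (k - 1 >= i + 1 ? DD(i + 1, k - 1) : 0) +
              (k + 1 <= j ? DD(k + 1, j) : 0);
      if (v == DD(i, j)) {
        pairs.push_back(std::make_pair(i, k));
        if (k - 1 > i + 1) st.push(std::make_pair(i + 1, k - 1));
        if (k + 1 < j) st.push(std::make_pair(k + 1, j));
        done = true;
      }
    }
    if (!done) st.push(std::make_pair(i + 1, j));
  }
  IntegerMatrix pm((int) pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first;
    pm(r, 1) = pairs[r].second;
  }
  int mp = DD(0, n - 1);
  #undef DD
  #undef TT
  return List::create(_["max_pairs"] = mp, _["pairs"] = pm);
}
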