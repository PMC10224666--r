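#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Pairing energy for RNA bases (0 = no pair). U and T are equivalent.
static inline int pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1;
  return 0;
}

// Nussinov-style minimum-energy folding: E(i,j) is the minimal total energy
// of any nested secondary structure on s[i..j] with pair energies
// GC = -3, AU = -2, GU = -1 and a minimum hairpin loop of 3 unpaired bases
// (i pairs j only when j - i > 3). Recurrence considers i unpaired, j
// unpaired, i.j paired, and all bifurcations. All energies are integers, so
// the DP runs in int; a column-major mirror of the table keeps the
// bifurcation scan over two contiguous arrays.
// [[Rcpp::export(name = ".rna_mfe_nussinov")]]
double rna_mfe_nussinov(std::string seq) {
  int n = seq.size();
  if (n < 2) return 0.0;
  std::string s(seq);
  for (int i = 0; i < n; ++i) {
    char c = toupper(s[i]);
    if (c == 'T') c = 'U';
    s[i] = c;
  }
  std::vector<int> Erow((size_t)n * n, 0);  // Erow[i*n + j] = E(i,j)
  std::vector<int> Ecol((size_t)n * n, 0);  // Ecol[j*n + i] = E(i,j)
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = Erow[(size_t)(i + 1) * n + j];            // i unpaired
      int ej = Erow[(size_t)i * n + (j - 1)];              // j unpaired
      if (ej < best) best = ej;
      if (j - i > 3) {
        int e = pair_energy(s[i], s[j]);
        if (e < 0) {
          int inner = Erow[(size_t)(i + 1) * n + (j - 1)] + e;
          if (inner < best) best = inner;
        }
      }
      const int *row_i = &Erow[(size_t)i * n];      // E(i, k), k = i..j-1
      const int *col_j = &Ecol[(size_t)j * n];      // E(k+1, j)
      for (int k = i; k < j; ++k) {
        int split = row_i[k] + col_j[k + 1];
        if (split < best) best = split;
      }
      Erow[(size_t)i * n + j] = best;
      Ecol[(size_t)j * n + i] = best;
    }
  }
  return (double)Erow[(size_t)0 * n + (n - 1)];
}
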