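#include <Rcpp.h>
using namespace Rcpp;

// Global Needleman-Wunsch alignment with linear gap penalties against a
// converted reference. Reference positions flagged in `wildcard` (CpG
// cytosines) score as a match for either C or T in the read. Traceback
// tie-break: diagonal, then gap in the read (consume reference), then gap in
// the reference (consume read).
//
// Returns list(score, ref = 0-based reference offsets (-1 = gap),
//              read = 0-based read offsets (-1 = gap)).
// [[Rcpp::export]]
List nw_align_cpp(std::string ref, std::string read, LogicalVector wildcard,
                  double match, double mismatch, double gap) {
  const int n = ref.size(), m = read.size();
  std::vector<double> H((n + 1) * (m + 1));
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  for (int j = 0; j <= m; ++j) H[at(0, j)] = j * gap;
  for (int i = 0; i <= n; ++i) H[at(i, 0)] = i * gap;

  auto sub = [&](int i, int j) {  // 1-based i over ref, j over read
    char a = ref[i - 1], b = read[j - 1];
    if (a == b) return match;
    if (wildcard[i - 1] && (b == 'C' || b == 'T')) return match;
    return mismatch;
  };

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = H[at(i - 1, j - 1)] + sub(i, j);
      double u = H[at(i - 1, j)] + gap;
      double l = H[at(i, j - 1)] + gap;
      double best = d;
      if (u > best) best = u;
      if (l > best) best = l;
      H[at(i, j)] = best;
    }
  }

  // traceback
  std::vector<int> ref_pos, read_pos;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && H[at(i, j)] == H[at(i - 1, j - 1)] + sub(i, j)) {
      ref_pos.push_back(i - 1); read_pos.push_back(j - 1); --i; --j;
    } else if (i > 0 && H[at(i, j)] == H[at(i - 1, j)] + gap) {
      ref_pos.push_back(i - 1); read_pos.push_back(-1); --i;
    } else {
      ref_pos.push_back(-1); read_pos.push_back(j - 1); --j;
    }
  }
  std::reverse(ref_pos.begin(), ref_pos.end());
  std::reverse(read_pos.begin(), read_pos.end());

  return List::create(_["score"] = H[at(n, m)],
                      _["ref"] = IntegerVector(ref_pos.begin(), ref_pos.end()),
                      _["read"] = IntegerVector(read_pos.begin(), read_pos.end()));
}
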