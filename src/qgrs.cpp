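#include <Rcpp.h>
using namespace Rcpp;

// Enumerate QGRS-style quadruplex candidates: four equal-length G-tracts
// of size g >= min_g separated by loops of length loop_min..loop_max,
// total span <= max_len. Returns one row per candidate:
// start (0-based), g, loop1, loop2, loop3, total length.
// [[Rcpp::export(name = ".qgrs_candidates_cpp")]]
IntegerMatrix qgrs_candidates_cpp(std::string seq, int min_g,
                                  int loop_min, int loop_max, int max_len) {
  const int n = seq.size();
  std::vector<int> grun(n + 1, 0);  // length of G-run starting at i
  for (int i = n - 1; i >= 0; --i) {
    char c = seq[i];
    grun[i] = (c == 'G' || c == 'g') ? grun[i + 1] + 1 : 0;
  }
  std::vector<int> rows;
  const int max_g = max_len / 4;
  for (int g = min_g; g <= max_g; ++g) {
    for (int p1 = 0; p1 + 4 * g <= n; ++p1) {
      if (grun[p1] < g) continue;
      const int lim = p1 + max_len;  // exclusive end bound
      int hi2 = std::min(p1 + g + loop_max, lim - 3 * g);
      for (int p2 = p1 + g + loop_min; p2 <= hi2; ++p2) {
        if (p2 + 3 * g > n || grun[p2] < g) continue;
        int hi3 = std::min(p2 + g + loop_max, lim - 2 * g);
        for (int p3 = p2 + g + loop_min; p3 <= hi3; ++p3) {
          if (p3 + 2 * g > n || grun[p3] < g) continue;
          int hi4 = std::min(p3 + g + loop_max, lim - g);
          for (int p4 = p3 + g + loop_min; p4 <= hi4; ++p4) {
            if (p4 + g > n || grun[p4] < g) continue;
            rows.push_back(p1);
            rows.push_back(g);
            rows.push_back(p2 - p1 - g);
            rows.push_back(p3 - p2 - g);
            rows.push_back(p4 - p3 - g);
            rows.push_back(p4 + g - p1);
          }
        }
      }
    }
  }
  const int k = rows.size() / 6;
  IntegerMatrix out(k, 6);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < 6; ++j) out(i, j) = rows[6 * i + j];
  colnames(out) = CharacterVector::create("start0", "g", "loop1", "loop2",
                                          "loop3", "len");
  return out;
}
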