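#include <Rcpp.h>
using namespace Rcpp;

// Hamming mismatch count between flank and the window of seq starting at pos.
// Any character difference (including N vs base) counts as a mismatch; the
// scan aborts early once the budget is exceeded.
static inline int window_mismatches(const char* seq, int pos, const char* flank,
                                    int flen, int budget) {
  int mm = 0;
  for (int j = 0; j < flen; ++j) {
    if (seq[pos + j] != flank[j]) {
      if (++mm > budget) return mm;
    }
  }
  return mm;
}

struct Candidate {
  int pos;
  int mm;
};

// All window positions where flank matches seq within max_mm mismatches,
// in left-to-right order.
static std::vector<Candidate> scan_flank(const std::string& seq,
                                         const std::string& flank,
                                         int max_mm) {
  std::vector<Candidate> out;
  const int n = (int)seq.size(), f = (int)flank.size();
  for (int i = 0; i + f <= n; ++i) {
    int mm = window_mismatches(seq.c_str(), i, flank.c_str(), f, max_mm);
    if (mm <= max_mm) out.push_back({i, mm});
  }
  return out;
}

// Locate flank_up and flank_down in each sequence, each within max_mm
// Hamming mismatches, with flank_up ending at or before flank_down's start.
// Among admissible placements the pair minimising up_mm + down_mm is chosen;
// ties resolve to the leftmost upstream window, then the leftmost downstream
// window. Returns an n x 5 integer matrix with columns
// (bc_start, bc_end, up_mm, down_mm, found), 0-based half-open interval.
// [[Rcpp::export]]
IntegerMatrix cpp_find_flanks(CharacterVector seqs, std::string flank_up,
                              std::string flank_down, int max_mm) {
  const int n = seqs.size();
  const int fu = (int)flank_up.size(), fd = (int)flank_down.size();
  IntegerMatrix res(n, 5);
  for (int r = 0; r < n; ++r) {
    res(r, 0) = res(r, 1) = res(r, 2) = res(r, 3) = -1;
    res(r, 4) = 0;
    if (seqs[r] == NA_STRING) continue;
    std::string s = as<std::string>(seqs[r]);
    if ((int)s.size() < fu + fd) continue;
    std::vector<Candidate> ups = scan_flank(s, flank_up, max_mm);
    if (ups.empty()) continue;
    std::vector<Candidate> downs = scan_flank(s, flank_down, max_mm);
    if (downs.empty()) continue;
    int best_total = max_mm * 2 + 1, bu = -1, bd = -1;
    for (size_t i = 0; i < ups.size(); ++i) {
      const int up_end = ups[i].pos + fu;
      for (size_t j = 0; j < downs.size(); ++j) {
        if (downs[j].pos < up_end) continue;
        const int tot = ups[i].mm + downs[j].mm;
        if (tot < best_total) {  // strict: ties keep the leftmost up, then down
          best_total = tot;
          bu = (int)i;
          bd = (int)j;
        }
      }
    }
    if (bu < 0) continue;
    res(r, 0) = ups[bu].pos + fu;
    res(r, 1) = downs[bd].pos;
    res(r, 2) = ups[bu].mm;
    res(r, 3) = downs[bd].mm;
    res(r, 4) = 1;
  }
  return res;
}
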