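#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive Hamming scan of short reads against reference targets.
// Reports every ungapped placement with <= max_mm mismatches; any base pair
// involving a character outside A/C/G/T counts as a mismatch (N never
// matches, even against N). Coordinates are 0-based half-open on the target
// forward strand; minus-strand hits are placements of the reverse complement.

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static inline bool base_match(char a, char b) {
  if (a != b) return false;
  return a == 'A' || a == 'C' || a == 'G' || a == 'T';
}

// [[Rcpp::export]]
DataFrame cpp_hamming_scan(CharacterVector reads,
                           CharacterVector targets,
                           int max_mm,
                           LogicalVector target_both_strands,
                           bool first_hit_only) {
  const int n_reads = reads.size();
  const int n_targets = targets.size();
  std::vector<std::string> tgt(n_targets);
  for (int t = 0; t < n_targets; ++t) tgt[t] = as<std::string>(targets[t]);

  std::vector<int> out_read, out_target, out_start, out_mm;
  std::vector<char> out_strand;

  for (int r = 0; r < n_reads; ++r) {
    const std::string fwd = as<std::string>(reads[r]);
    const int L = (int) fwd.size();
    if (L == 0) continue;
    std::string rev(L, 'N');
    for (int i = 0; i < L; ++i) rev[L - 1 - i] = comp_base(fwd[i]);
    bool done = false;

    for (int t = 0; t < n_targets && !done; ++t) {
      const std::string &s = tgt[t];
      const int TL = (int) s.size();
      if (L > TL) continue;
      const int n_strands = target_both_strands[t] ? 2 : 1;
      for (int k = 0; k < n_strands && !done; ++k) {
        const std::string &q = (k == 0) ? fwd : rev;
        for (int pos = 0; pos + L <= TL; ++pos) {
          int mm = 0;
          for (int i = 0; i < L; ++i) {
            if (!base_match(q[i], s[pos + i])) {
              if (++mm > max_mm) break;
            }
          }
          if (mm <= max_mm) {
            out_read.push_back(r + 1);
            out_target.push_back(t + 1);
            out_start.push_back(pos);
            out_strand.push_back(k == 0 ? '+' : '-');
            out_mm.push_back(mm);
            if (first_hit_only) { done = true; break; }
          }
        }
      }
    }
  }

  const int n = (int) out_read.size();
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) strand[i] = std::string(1, out_strand[i]);
  return DataFrame::create(
    _["read_idx"] = wrap(out_read),
    _["target_idx"] = wrap(out_target),
    _["start"] = wrap(out_start),
    _["strand"] = strand,
    _["mismatches"] = wrap(out_mm),
    _["stringsAsFactors"] = false);
}
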