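#include <Rcpp.h>
using namespace Rcpp;

// Candidate mirror-repeat enumeration. For every spacer placement (c = spacer
// start, g = spacer length) arms grow outward symmetrically: pair k compares
// seq[c-1-k] with seq[c+g+k]. Both arm bases of every pair must belong to one
// purity class (A/G purine or C/T pyrimidine; N belongs to neither), and the
// cumulative count of unequal same-class pairs (symmetry mismatches) must stay
// within the budget, which is 0 below `mismatch_arm_threshold` and
// `max_mismatches` at or above it -- the gate is applied on the final arm
// length. The longest admissible arm per (c, g) with arm >= min_arm is
// reported; containment suppression happens in R.
//
// Coordinates in/out are 0-based half-open.
// [[Rcpp::export]]
DataFrame mirror_scan_cpp(std::string seq, int min_arm, int min_spacer,
                          int max_spacer, int mismatch_arm_threshold,
                          int max_mismatches, bool require_pure_spacer) {
  const int L = (int)seq.size();
  std::vector<signed char> cls(L, 0);
  for (int i = 0; i < L; ++i) {
    char b = seq[i];
    if (b == 'A' || b == 'G') cls[i] = 1;
    else if (b == 'C' || b == 'T') cls[i] = 2;
  }
  std::vector<int> hs, ha, hg, hm;
  std::vector<signed char> hc;
  for (int c = 1; c < L; ++c) {
    for (int g = min_spacer; g <= max_spacer; ++g) {
      if (c + g >= L) break;  // need at least one base for arm2
      signed char cl = 0;
      int mm = 0, best_a = 0, best_mm = 0;
      const int kmax = std::min(c, L - (c + g));
      for (int k = 0; k < kmax; ++k) {
        const int l = c - 1 - k, r = c + g + k;
        const signed char c1 = cls[l], c2 = cls[r];
        if (c1 == 0 || c2 == 0 || c1 != c2) break;
        if (k == 0) cl = c1; else if (c1 != cl) break;
        if (seq[l] != seq[r]) {
          ++mm;
          if (mm > max_mismatches) break;
        }
        const int a = k + 1;
        const int allowed = (a >= mismatch_arm_threshold) ? max_mismatches : 0;
        if (a >= min_arm && mm <= allowed) { best_a = a; best_mm = mm; }
      }
      if (best_a >= min_arm) {
        if (require_pure_spacer) {
          bool pure = true;
          for (int j = c; j < c + g; ++j)
            if (cls[j] != cl) { pure = false; break; }
          if (!pure) continue;
        }
        hs.push_back(c - best_a);
        ha.push_back(best_a);
        hg.push_back(g);
        hm.push_back(best_mm);
        hc.push_back(cl);
      }
    }
  }
  const int n = (int)hs.size();
  IntegerVector start(n), arm(n), spacer(n), mism(n), klass(n);
  for (int i = 0; i < n; ++i) {
    start[i] = hs[i]; arm[i] = ha[i]; spacer[i] = hg[i];
    mism[i] = hm[i]; klass[i] = hc[i];
  }
  return DataFrame::create(_["start"] = start, _["arm_len"] = arm,
                           _["spacer_len"] = spacer, _["mismatches"] = mism,
                           _["class"] = klass);
}
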