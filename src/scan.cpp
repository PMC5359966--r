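#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Exhaustive sense-strand Hamming scan of each query against one subject
// string. A position where the subject holds a non-ACGT character (the
// reference delimiter 'N') voids the whole placement; a non-ACGT character in
// the query (an ambiguous base call) is an unconditional mismatch. Returns
// all placements with at most max_mm mismatches; 1-based starts.
// [[Rcpp::export]]
DataFrame hamming_scan_cpp(std::string subject, CharacterVector queries, int max_mm) {
  std::vector<int> out_q, out_s, out_mm;
  const char* sub = subject.c_str();
  const int slen = (int) subject.size();
  for (int qi = 0; qi < queries.size(); ++qi) {
    const char* q = CHAR(STRING_ELT(queries, qi));
    const int qlen = (int) std::strlen(q);
    if (qlen == 0 || qlen > slen) continue;
    for (int p = 0; p + qlen <= slen; ++p) {
      int mm = 0;
      bool blocked = false;
      for (int j = 0; j < qlen; ++j) {
        const char s = sub[p + j];
        if (!is_acgt(s)) { blocked = true; break; }   // delimiter safety
        const char c = q[j];
        if (c != s || !is_acgt(c)) {
          if (++mm > max_mm) break;
        }
      }
      if (!blocked && mm <= max_mm) {
        out_q.push_back(qi + 1);
        out_s.push_back(p + 1);
        out_mm.push_back(mm);
      }
    }
  }
  return DataFrame::create(_["query"] = out_q, _["start"] = out_s,
                           _["mismatches"] = out_mm);
}

// Leftmost 3'-anchored adapter match per read. At each candidate start p the
// compared window is the adapter prefix of length k = min(|adapter|, L-p+1);
// the window matches when its Hamming mismatch count is <= floor(rate * k)
// and k >= min_overlap. Returns the 1-based start of the match (0 = none).
// [[Rcpp::export]]
IntegerVector adapter_trim_cpp(CharacterVector reads, std::string adapter,
                               double max_error_rate, int min_overlap) {
  const char* ad = adapter.c_str();
  const int alen = (int) adapter.size();
  IntegerVector pos(reads.size());
  for (int ri = 0; ri < reads.size(); ++ri) {
    const char* r = CHAR(STRING_ELT(reads, ri));
    const int L = (int) std::strlen(r);
    int hit = 0;
    for (int p = 0; p <= L - min_overlap; ++p) {
      const int k = std::min(alen, L - p);
      const int budget = (int) (max_error_rate * k + 1e-9);
      int mm = 0;
      for (int j = 0; j < k; ++j) {
        if (r[p + j] != ad[j] && ++mm > budget) break;
      }
      if (mm <= budget) { hit = p + 1; break; }
    }
    pos[ri] = hit;
  }
  return pos;
}

// True where the query occurs verbatim (exact, 0 mismatches) in any of the
// subject strings. Callers pass both strands of a genome explicitly.
// [[Rcpp::export]]
LogicalVector exact_occurs_cpp(CharacterVector queries, CharacterVector subjects) {
  std::vector<std::string> subs(subjects.size());
  for (int i = 0; i < subjects.size(); ++i) subs[i] = as<std::string>(subjects[i]);
  LogicalVector out(queries.size());
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    bool found = false;
    for (size_t si = 0; si < subs.size() && !found; ++si) {
      if (subs[si].find(q) != std::string::npos) found = true;
    }
    out[qi] = found;
  }
  return out;
}
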