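#include <Rcpp.h>
using namespace Rcpp;

// Leftmost 3' adaptor occurrence per read, cutadapt-style semantics:
// at 0-based read position p the first min(alen, len - p) bases of the
// adaptor are compared; accepted when overlap >= min_overlap and
// mismatches <= floor(error_rate * overlap). Returns the insert length
// (number of bases kept before the adaptor) or -1 when no acceptable
// occurrence exists.
// [[Rcpp::export]]
IntegerVector adaptor_positions_cpp(CharacterVector reads, std::string adaptor,
                                    int min_overlap, double error_rate) {
  const int n = reads.size();
  const int alen = (int) adaptor.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (reads[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const std::string s = as<std::string>(reads[i]);
    const int len = (int) s.size();
    int hit = -1;
    for (int p = 0; p + min_overlap <= len; ++p) {
      const int m = std::min(alen, len - p);
      const int allowed = (int) std::floor(error_rate * m);
      int mm = 0;
      bool ok = true;
      for (int j = 0; j < m; ++j) {
        if (s[p + j] != adaptor[j]) {
          if (++mm > allowed) { ok = false; break; }
        }
      }
      if (ok) { hit = p; break; }
    }
    out[i] = hit;
  }
  return out;
}

// Fraction of bases per quality string with Phred score strictly above
// `threshold`, given the ASCII `offset` (33 or 64). Empty strings -> NaN.
// [[Rcpp::export]]
NumericVector qual_frac_above_cpp(CharacterVector quals, int offset, int threshold) {
  const int n = quals.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (quals[i] == NA_STRING) { out[i] = NA_REAL; continue; }
    const std::string q = as<std::string>(quals[i]);
    const int len = (int) q.size();
    if (len == 0) { out[i] = R_NaN; continue; }
    int above = 0;
    for (int j = 0; j < len; ++j) {
      if ((int) q[j] - offset > threshold) ++above;
    }
    out[i] = (double) above / (double) len;
  }
  return out;
}
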