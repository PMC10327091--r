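// poly-A tail trimming: remove a trailing A-run of total length >= 10,
// allowing one embedded non-A interruption inside the run.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".trim_polya_cpp")]]
CharacterVector trim_polya_cpp(CharacterVector seqs, int min_run) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int a = 0; a < n; ++a) {
    std::string s = as<std::string>(seqs[a]);
    int len = (int)s.size();
    int i = len - 1, k1 = 0;
    while (i >= 0 && s[i] == 'A') { ++k1; --i; }
    int total = k1;
    if (k1 > 0 && i >= 1 && s[i] != 'A') {  // one embedded non-A
      int j = i - 1, k2 = 0;
      while (j >= 0 && s[j] == 'A') { ++k2; --j; }
      if (k2 > 0) total = k1 + 1 + k2;
    }
    if (total >= min_run) s.resize(len - total);
    out[a] = s;
  }
  return out;
}
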