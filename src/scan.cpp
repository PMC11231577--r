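#include <Rcpp.h>
using namespace Rcpp;

// Quantized PWM score at every start position of an integer-coded
// sequence (codes 1..4 = A,C,G,T; 5 = N/other). score5 is a 5 x W integer
// matrix whose fifth row holds a large negative sentinel so that any
// window containing N falls below every attainable score.
// [[Rcpp::export(name = ".scan_scores_int")]]
IntegerVector scan_scores_int(IntegerVector codes, IntegerMatrix score5) {
  const int W = score5.ncol();
  const int n = codes.size() - W + 1;
  if (n < 1) return IntegerVector(0);
  IntegerVector S(n);
  const int* cd = codes.begin();
  const int* sc = score5.begin();  // column-major, 5 rows
  for (int i = 0; i < n; ++i) {
    int s = 0;
    for (int k = 0; k < W; ++k) {
      s += sc[5 * k + (cd[i + k] - 1)];
    }
    S[i] = s;
  }
  return S;
}
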