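#include <Rcpp.h>
using namespace Rcpp;

// Log block-size PMF of the hotspot model for n = 1..nMax:
//   P(n) = sigma (T.U)^{n-1} (T.C) 1
// with . the Hadamard product. Propagated as successive row-vector x 2x2
// matrix products (one step per block size, so the whole vector costs
// O(nMax)); the running vector is rescaled and the log of the scale
// accumulated so that long blocks do not underflow.
// [[Rcpp::export]]
NumericVector hotspot_log_pmf_cpp(NumericVector sigma, NumericMatrix M,
                                  NumericVector cutRowSums, int nMax) {
  NumericVector out(nMax);
  double vH = sigma[0], vC = sigma[1];
  double logScale = 0.0;
  for (int n = 1; n <= nMax; ++n) {
    double p = vH * cutRowSums[0] + vC * cutRowSums[1];
    out[n - 1] = (p > 0.0) ? std::log(p) + logScale : R_NegInf;
    double nextH = vH * M(0, 0) + vC * M(1, 0);
    double nextC = vH * M(0, 1) + vC * M(1, 1);
    vH = nextH;
    vC = nextC;
    double s = vH + vC;
    if (s > 0.0 && s < 1e-280) {
      vH /= s;
      vC /= s;
      logScale += std::log(s);
    }
  }
  return out;
}
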