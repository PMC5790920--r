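#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Local profile-HMM alignment score in bits (log2-odds against a uniform
// residue background). Model: match states M_1..M_M with emission log-odds
// in `matlod` (M x 20), insert states I_1..I_{M-1} emitting background
// (log-odds 0), delete states D_2..D_M. Entry into any match state costs
// log2(1/M); exit from any match state is free. `forward = false` gives
// the Viterbi (best path) score, `forward = true` the summed (forward)
// score over all local paths; forward >= viterbi always.
//
// seq holds 0-based residue indices; negative entries are wildcards that
// emit background in both model and null (log-odds 0).

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double hi = a > b ? a : b;
  double lo = a > b ? b : a;
  return hi + std::log2(1.0 + std::exp2(lo - hi));
}

// [[Rcpp::export]]
double hmm_dp_bits(IntegerVector seq, NumericMatrix matlod,
                   NumericVector tMM, NumericVector tMI, NumericVector tMD,
                   NumericVector tIM, NumericVector tII,
                   NumericVector tDM, NumericVector tDD,
                   bool forward) {
  const int L = seq.size();
  const int M = matlod.nrow();
  if (L < 1 || M < 1) return R_NegInf;
  const double entry = -std::log2((double) M);
  const double NEG = R_NegInf;

  std::vector<double> VMp(M + 1, NEG), VIp(M + 1, NEG), VDp(M + 1, NEG);
  std::vector<double> VMc(M + 1, NEG), VIc(M + 1, NEG), VDc(M + 1, NEG);
  double result = NEG;

  for (int i = 1; i <= L; ++i) {
    int a = seq[i - 1];
    for (int j = 1; j <= M; ++j) {
      double e = (a < 0) ? 0.0 : matlod(j - 1, a);
      double best = entry;  // enter the model at M_j with residue i
      if (j > 1) {
        double c1 = VMp[j - 1] + tMM[j - 2];
        double c2 = (j - 1 <= M - 1) ? VIp[j - 1] + tIM[j - 2] : NEG;
        double c3 = VDp[j - 1] + tDM[j - 2];
        if (forward) {
          best = lse2(lse2(best, c1), lse2(c2, c3));
        } else {
          if (c1 > best) best = c1;
          if (c2 > best) best = c2;
          if (c3 > best) best = c3;
        }
      }
      VMc[j] = e + best;
    }
    // insert states (emit residue i from background, log-odds 0)
    for (int j = 1; j <= M - 1; ++j) {
      double c1 = VMp[j] + tMI[j - 1];
      double c2 = VIp[j] + tII[j - 1];
      VIc[j] = forward ? lse2(c1, c2) : (c1 > c2 ? c1 : c2);
    }
    // delete states (consume no residue; same row, left to right)
    VDc[1] = NEG;
    for (int j = 2; j <= M; ++j) {
      double c1 = VMc[j - 1] + tMD[j - 2];
      double c2 = VDc[j - 1] + tDD[j - 2];
      VDc[j] = forward ? lse2(c1, c2) : (c1 > c2 ? c1 : c2);
    }
    // free exit from any match state
    for (int j = 1; j <= M; ++j) {
      result = forward ? lse2(result, VMc[j])
                       : (VMc[j] > result ? VMc[j] : result);
    }
    std::swap(VMp, VMc); std::swap(VIp, VIc); std::swap(VDp, VDc);
    std::fill(VMc.begin(), VMc.end(), NEG);
    std::fill(VIc.begin(), VIc.end(), NEG);
    std::fill(VDc.begin(), VDc.end(), NEG);
  }
  return result;
}

// Batch variant: scores many encoded sequences against one model.
// [[Rcpp::export]]
NumericVector hmm_dp_bits_many(List seqs, NumericMatrix matlod,
                               NumericVector tMM, NumericVector tMI,
                               NumericVector tMD, NumericVector tIM,
                               NumericVector tII, NumericVector tDM,
                               NumericVector tDD, bool forward) {
  const int n = seqs.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    IntegerVector s = seqs[k];
    out[k] = hmm_dp_bits(s, matlod, tMM, tMI, tMD, tIM, tII, tDM, tDD, forward);
  }
  return out;
}
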