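#include <Rcpp.h>
using namespace Rcpp;

// Accumulate the PLI over channel pairs from stacked phase matrices.
// sinp/cosp: (epoch*time) x channel, rows grouped by epoch with n_t rows
// each. degenerate: n_ep x channel flags; epochs flagged for a channel are
// skipped for pairs involving it. pool=true pools all samples instead of
// averaging per-epoch PLIs.
// [[Rcpp::export(name = ".pli_accumulate")]]
NumericMatrix pli_accumulate(NumericMatrix sinp, NumericMatrix cosp,
                             int n_ep, int n_t, LogicalMatrix degenerate,
                             bool pool) {
  const int n_ch = sinp.ncol();
  NumericMatrix out(n_ch, n_ch);
  for (int i = 0; i < n_ch - 1; ++i) {
    const double *si = &sinp(0, i), *ci = &cosp(0, i);
    for (int j = i + 1; j < n_ch; ++j) {
      const double *sj = &sinp(0, j), *cj = &cosp(0, j);
      double acc = 0.0;
      long pooled = 0;
      int n_used = 0;
      for (int e = 0; e < n_ep; ++e) {
        const int r0 = e * n_t;
        if (!pool && (degenerate(e, i) || degenerate(e, j))) continue;
        long s = 0;
        for (int r = r0; r < r0 + n_t; ++r) {
          double v = si[r] * cj[r] - ci[r] * sj[r];
          s += (v > 0.0) - (v < 0.0);
        }
        if (pool) {
          pooled += s;
        } else {
          acc += std::abs((double)s) / n_t;
          ++n_used;
        }
      }
      double pli = pool ? std::abs((double)pooled) / ((double)n_ep * n_t)
                        : (n_used > 0 ? acc / n_used : 0.0);
      out(i, j) = pli;
      out(j, i) = pli;
    }
  }
  return out;
}
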