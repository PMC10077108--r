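#include <Rcpp.h>
using namespace Rcpp;

// Pairwise concordance counts between observed and predicted values.
// Over all pairs (i, j) with obs_i != obs_j:
//   concordant : (pred_i - pred_j) has the same sign as (obs_i - obs_j)
//   tied       : pred_i == pred_j
// Returns c(concordant, tied, comparable).
// [[Rcpp::export]]
NumericVector concordance_counts(NumericVector obs, NumericVector pred) {
  const R_xlen_t n = obs.size();
  if (pred.size() != n) stop("obs and pred must have equal length");
  double conc = 0.0, tied = 0.0, comp = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j) {
      const double dobs = obs[i] - obs[j];
      if (dobs == 0.0) continue;
      comp += 1.0;
      const double dpred = pred[i] - pred[j];
      if (dpred == 0.0) {
        tied += 1.0;
      } else if ((dobs > 0.0) == (dpred > 0.0)) {
        conc += 1.0;
      }
    }
  }
  return NumericVector::create(conc, tied, comp);
}
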