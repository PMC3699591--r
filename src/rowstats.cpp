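// Row-wise medians of the Monte-Carlo draw matrices. These run once per
// summary statistic per fit over (genes x n_mc) matrices, which makes them
// the hot loop of the whole pipeline: transpose once for contiguous access,
// then selection (nth_element) instead of a full sort per row.
#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::NumericVector row_medians_cpp(const arma::mat& x) {
  const arma::uword n = x.n_cols, m = x.n_rows;
  arma::mat xt = x.t();
  Rcpp::NumericVector out(m);
  std::vector<double> buf(n);
  const arma::uword h = n / 2;
  for (arma::uword j = 0; j < m; ++j) {
    const double* col = xt.colptr(j);
    std::copy(col, col + n, buf.begin());
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double upper = buf[h];
    if (n % 2 == 1) {
      out[j] = upper;
    } else {
      double lower = *std::max_element(buf.begin(), buf.begin() + h);
      out[j] = (lower + upper) / 2.0;
    }
  }
  return out;
}
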