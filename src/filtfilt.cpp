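#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// direct-form IIR filter along each row of X (all channels advance together)
static mat filt_rows(const vec& b, const vec& a, const mat& X) {
  const uword nb = b.n_elem, na = a.n_elem, n = X.n_cols, ch = X.n_rows;
  mat Y(ch, n, fill::zeros);
  for (uword t = 0; t < n; ++t) {
    vec acc(ch, fill::zeros);
    for (uword k = 0; k < nb && k <= t; ++k)
      acc += b[k] * X.col(t - k);
    for (uword k = 1; k < na && k <= t; ++k)
      acc -= a[k] * Y.col(t - k);
    Y.col(t) = acc / a[0];
  }
  return Y;
}

// zero-phase (forward-backward) IIR filtering of a channels x samples
// matrix with reflective edge padding, as in the classic filtfilt scheme
// [[Rcpp::export(name = ".filtfilt_mat")]]
arma::mat filtfilt_mat(const arma::vec& b, const arma::vec& a,
                       const arma::mat& X) {
  const uword n = X.n_cols;
  const uword npad = 3 * (std::max(a.n_elem, b.n_elem) - 1);
  if (n <= npad + 1)
    Rcpp::stop("signal too short for the requested filter order");
  mat P(X.n_rows, n + 2 * npad);
  // reflect about the end points: 2*x0 - x[k]
  for (uword k = 0; k < npad; ++k) {
    P.col(k) = 2 * X.col(0) - X.col(npad - k);
    P.col(npad + n + k) = 2 * X.col(n - 1) - X.col(n - 2 - k);
  }
  P.cols(npad, npad + n - 1) = X;
  mat Y = filt_rows(b, a, P);
  Y = fliplr(Y);
  Y = filt_rows(b, a, Y);
  Y = fliplr(Y);
  return Y.cols(npad, npad + n - 1);
}
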