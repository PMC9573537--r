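#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double forget(double u0, double gamma_, double u_min, long i) {
  double u = u0 / std::pow((double)i + 1.0, gamma_);
  return std::max(u, u_min);
}

// Streaming ORICA: per block, whitening and demixing matrices advance by the
// recursive rank-one rules (or the gradient rule for W); activations are
// emitted with the state current at each block's entry.
// activation: 0 = tanh, 1 = cubic; rule: 0 = recursive, 1 = gradient.
// [[Rcpp::export(name = ".orica_stream")]]
Rcpp::List orica_stream(const arma::mat& data, arma::mat X, arma::mat W,
                        arma::vec mu, long i0, double u0, double gamma_,
                        double u_min, int block_size, int activation,
                        int rule, double lr, bool renormalize, bool center,
                        bool emit) {
  const uword n_ch = data.n_rows, n = data.n_cols;
  if (X.n_rows != n_ch || W.n_rows != n_ch)
    Rcpp::stop("state dimension does not match the recording channel count");
  mat acts;
  if (emit) acts.set_size(n_ch, n);
  const mat I = eye<mat>(n_ch, n_ch);
  long i = i0;
  for (uword s0 = 0; s0 < n; s0 += (uword)block_size) {
    uword s1 = std::min(s0 + (uword)block_size, n) - 1;
    const double nb = (double)(s1 - s0 + 1);
    double u = forget(u0, gamma_, u_min, i);
    mat xb = data.cols(s0, s1);
    if (center) {
      mu = (1.0 - u) * mu + u * mean(xb, 1);
      xb.each_col() -= mu;
    }
    mat v = X * xb;
    mat a = W * v;
    if (emit) acts.cols(s0, s1) = a;

    // whitening update (block-averaged rank-one terms)
    {
      mat Rv = v * v.t() / nb;
      double sv = accu(v % v) / nb;
      double denom = 1.0 + u * (sv - 1.0);
      X = X + (u / (1.0 - u)) * (I - Rv / denom) * X;
    }
    // demixing update
    {
      mat fa = (activation == 0) ? mat(tanh(a)) : mat(pow(a, 3));
      if (rule == 0) {
        mat Ra = a * fa.t() / nb;
        double sf = accu(fa % a) / nb;
        double denom = 1.0 + u * (sf - 1.0);
        W = W + (u / (1.0 - u)) * (I - Ra / denom) * W;
      } else {
        W = W + lr * (I - fa * a.t() / nb) * W;
      }
      if (renormalize) {
        for (uword r = 0; r < n_ch; ++r) {
          double nr = norm(W.row(r), 2);
          if (nr > 0) W.row(r) /= nr;
        }
      }
    }
    if (!X.is_finite() || !W.is_finite())
      Rcpp::stop("ORICA update diverged (non-finite state) at block iteration %ld", i);
    ++i;
  }
  return Rcpp::List::create(Rcpp::Named("activations") = acts,
                            Rcpp::Named("X") = X, Rcpp::Named("W") = W,
                            Rcpp::Named("mu") = mu, Rcpp::Named("i") = (double)i);
}
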