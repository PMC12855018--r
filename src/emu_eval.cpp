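#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Evaluate a compiled EMU plan at a flux vector: assemble and solve the
// per-size balance systems in ascending size order. Index arrays are
// 1-based (built in R).
// [[Rcpp::export]]
List emuEvalCpp(List plan, NumericVector fv) {
  List values0 = plan["values0"];
  int K = values0.size();
  std::vector<arma::vec> values(K);
  for (int i = 0; i < K; ++i)
    if (!Rf_isNull(values0[i])) values[i] = as<arma::vec>(values0[i]);
  List systems = plan["systems"];
  for (int si = 0; si < systems.size(); ++si) {
    List sys = systems[si];
    int n = as<int>(sys["n"]);
    int size = as<int>(sys["size"]);
    IntegerVector idx = sys["idx"];
    IntegerVector diag_row = sys["diag_row"];
    IntegerVector diag_flux = sys["diag_flux"];
    NumericVector diag_coef = sys["diag_coef"];
    IntegerVector off_row = sys["off_row"];
    IntegerVector off_col = sys["off_col"];
    IntegerVector off_flux = sys["off_flux"];
    NumericVector off_weight = sys["off_weight"];
    List bterms = sys["bterms"];
    arma::mat A(n, n, arma::fill::zeros);
    arma::mat B(n, size + 1, arma::fill::zeros);
    for (int q = 0; q < diag_row.size(); ++q)
      A(diag_row[q] - 1, diag_row[q] - 1) += fv[diag_flux[q] - 1] * diag_coef[q];
    for (int q = 0; q < off_row.size(); ++q)
      A(off_row[q] - 1, off_col[q] - 1) -= fv[off_flux[q] - 1] * off_weight[q];
    for (int t = 0; t < bterms.size(); ++t) {
      List tm = bterms[t];
      double val = fv[as<int>(tm["flux"]) - 1] * as<double>(tm["weight"]);
      if (val == 0) continue;
      IntegerVector src = tm["src"];
      arma::vec contrib = values[src[0] - 1];
      for (int k = 1; k < src.size(); ++k) {
        // open convolution; source sizes sum to the EMU size
        const arma::vec &b = values[src[k] - 1];
        arma::vec c(contrib.n_elem + b.n_elem - 1, arma::fill::zeros);
        for (arma::uword i = 0; i < contrib.n_elem; ++i)
          for (arma::uword j = 0; j < b.n_elem; ++j)
            c(i + j) += contrib(i) * b(j);
        contrib = c;
      }
      B.row(as<int>(tm["row"]) - 1) += (val * contrib).t();
    }
    // a pool with zero turnover (all producing and consuming fluxes zero)
    // contributes nothing downstream; pin its row so the system stays
    // non-singular instead of letting LAPACK fail on the whole block
    for (int i = 0; i < n; ++i) {
      if (std::abs(A(i, i)) < 1e-12) {
        A.row(i).zeros();
        A(i, i) = 1.0;
        B.row(i).zeros();
      }
    }
    arma::mat X;
    if (!arma::solve(X, A, B, arma::solve_opts::no_approx))
      stop("singular EMU system of size %d (disconnected pool at the given fluxes)", size);
    X.transform([](double v) { return v < 0 ? 0.0 : v; });
    for (int i = 0; i < n; ++i) values[idx[i] - 1] = X.row(i).t();
  }
  IntegerVector tidx = plan["target_idx"];
  List out(tidx.size());
  for (int i = 0; i < tidx.size(); ++i) {
    arma::vec v = values[tidx[i] - 1];
    out[i] = NumericVector(v.begin(), v.end());
  }
  return out;
}
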