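// Epoch-aware Felsenstein pruning for two-epoch (resub) substitution models.
//
// Branches wholly inside the young epoch use the full-alphabet transition
// matrix, branches wholly inside the old epoch use the reduced one, and a
// branch crossing the boundary uses P'(tau2) * Xi * P(tau1). Partial
// likelihood vectors above the boundary live in the reduced state space.
// Transition matrices are built from the spectral decomposition of the
// reversible generator (computed in R and passed in), so a branch costs a
// pair of small dense products. Per-node rescaling guards against
// underflow on deep alignments.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat ptrans(const arma::mat& U, const arma::mat& Ui,
                        const arma::vec& ev, double tau) {
  arma::mat P = U * arma::diagmat(arma::exp(ev * tau)) * Ui;
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  arma::vec rs = arma::sum(P, 1);
  P.each_col() /= rs;
  return P;
}

// [[Rcpp::export]]
List epoch_pruning_cpp(List children, NumericVector heights,
                       IntegerVector order, int root,
                       bool has_origin, double origin_height,
                       NumericVector branch_rate, double te, bool is0,
                       arma::mat U, arma::mat Ui, arma::vec ev,
                       arma::mat Ur, arma::mat Uir, arma::vec evr,
                       arma::mat Xi, arma::vec rf_full, arma::vec rf_red,
                       arma::cube leaf_part, NumericVector cat_rates,
                       NumericVector weights) {
  const int n_node = heights.size();
  const int ntip = (n_node + 1) / 2;
  const int P = leaf_part.n_cols;
  const int k = cat_rates.size();

  arma::mat cat_logs(k, P);  // per-category per-pattern log likelihood

  for (int c = 0; c < k; ++c) {
    const double cr = cat_rates[c];
    std::vector<arma::mat> partial(n_node);
    arma::rowvec scaler(P, arma::fill::zeros);

    for (int t = 0; t < ntip; ++t) partial[t] = leaf_part.slice(t);

    for (int oi = 0; oi < order.size(); ++oi) {
      const int p = order[oi] - 1;
      const double hp = heights[p];
      const bool pred = !is0 && hp > te;
      arma::mat acc;
      IntegerVector kids = children[p];
      for (int ci = 0; ci < kids.size(); ++ci) {
        const int ch = kids[ci] - 1;
        const double hc = heights[ch];
        const double rate = branch_rate[ch] * cr;
        const bool cred = !is0 && hc > te;
        arma::mat M;
        if (!pred) {
          M = ptrans(U, Ui, ev, rate * (hp - hc));
        } else if (cred) {
          M = ptrans(Ur, Uir, evr, rate * (hp - hc));
        } else {
          M = ptrans(Ur, Uir, evr, rate * (hp - te)) * Xi *
              ptrans(U, Ui, ev, rate * (te - hc));
        }
        arma::mat down = M * partial[ch];
        if (ci == 0) acc = down; else acc %= down;
      }
      // rescale each pattern's column to keep partials in range
      arma::rowvec mx = arma::max(acc, 0);
      for (int j = 0; j < P; ++j) {
        if (mx[j] > 0 && mx[j] != 1.0) {
          acc.col(j) /= mx[j];
          scaler[j] += std::log(mx[j]);
        } else if (mx[j] <= 0) {
          scaler[j] = -arma::datum::inf;
        }
      }
      partial[p] = acc;
    }

    arma::mat top = partial[root - 1];
    double top_h = heights[root - 1];
    if (has_origin) {
      const double rate = branch_rate[root - 1] * cr;
      const bool ored = !is0 && origin_height > te;
      const bool rred = !is0 && heights[root - 1] > te;
      arma::mat M;
      if (!ored) {
        M = ptrans(U, Ui, ev, rate * (origin_height - heights[root - 1]));
      } else if (rred) {
        M = ptrans(Ur, Uir, evr, rate * (origin_height - heights[root - 1]));
      } else {
        M = ptrans(Ur, Uir, evr, rate * (origin_height - te)) * Xi *
            ptrans(U, Ui, ev, rate * (te - heights[root - 1]));
      }
      top = M * top;
      top_h = origin_height;
    }
    const arma::vec& f = (!is0 && top_h > te) ? rf_red : rf_full;
    arma::rowvec lik = f.t() * top;
    for (int j = 0; j < P; ++j) {
      cat_logs(c, j) = (lik[j] > 0 && std::isfinite(scaler[j]))
                           ? std::log(lik[j]) + scaler[j]
                           : -arma::datum::inf;
    }
  }

  // equal-weight average over rate categories, in log space
  NumericVector site_log(P);
  double total = 0.0;
  for (int j = 0; j < P; ++j) {
    double m = cat_logs.col(j).max();
    double s;
    if (!std::isfinite(m)) {
      s = -arma::datum::inf;
    } else {
      double acc = 0.0;
      for (int c = 0; c < k; ++c) acc += std::exp(cat_logs(c, j) - m);
      s = m + std::log(acc / k);
    }
    site_log[j] = s;
    total += weights[j] * s;
  }
  return List::create(_["loglik"] = total, _["site_log"] = site_log);
}
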