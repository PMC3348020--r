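// Exhaustive best-subset search over feature columns.
//
// For each candidate subset S the squared multiple correlation of the
// OLS fit (with intercept) is R^2 = Sxy(S)' beta / Syy with
// beta = Sxx(S)^{-1} Sxy(S), computed from centred cross-products that
// are formed once per dataset. Subsets are enumerated size-ascending in
// lexicographic column order; the running top-m list is updated only on
// strictly larger R^2, so the first-seen subset wins ties (smaller size,
// then lexicographic order).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

namespace {

struct TopEntry {
  double r2;
  std::vector<int> cols;  // 1-based column indices
};

void insert_top(std::vector<TopEntry> &top, std::size_t top_m,
                double r2, const arma::uvec &combo) {
  // position of first entry strictly worse than r2
  std::size_t pos = top.size();
  for (std::size_t i = 0; i < top.size(); ++i) {
    if (top[i].r2 < r2) { pos = i; break; }
  }
  if (pos >= top_m) return;
  TopEntry e;
  e.r2 = r2;
  e.cols.reserve(combo.n_elem);
  for (arma::uword j = 0; j < combo.n_elem; ++j)
    e.cols.push_back(static_cast<int>(combo[j]) + 1);
  top.insert(top.begin() + pos, e);
  if (top.size() > top_m) top.resize(top_m);
}

}  // namespace

// [[Rcpp::export(name = ".subset_search_cpp")]]
List subset_search_cpp(const arma::mat &X, const arma::vec &y,
                       const IntegerVector &sizes, int top_m) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  if (y.n_elem != n) stop("X and y dimensions disagree");
  arma::mat Xc = X.each_row() - arma::mean(X, 0);
  arma::vec yc = y - arma::mean(y);
  arma::mat Sxx = Xc.t() * Xc;
  arma::vec Sxy = Xc.t() * yc;
  const double Syy = arma::dot(yc, yc);
  if (Syy <= 0) stop("response is constant; correlation undefined");

  std::vector<TopEntry> top;
  double n_fitted = 0, n_skipped = 0;

  std::vector<int> sz(sizes.begin(), sizes.end());
  std::sort(sz.begin(), sz.end());
  for (int s : sz) {
    if (s < 1 || static_cast<arma::uword>(s) > p) continue;
    // lexicographic enumeration of s-combinations of 0..p-1
    arma::uvec combo(s);
    for (int i = 0; i < s; ++i) combo[i] = i;
    arma::mat A(s, s);
    arma::vec b(s), beta(s);
    for (;;) {
      for (int i = 0; i < s; ++i) {
        b[i] = Sxy[combo[i]];
        for (int j = 0; j < s; ++j) A(i, j) = Sxx(combo[i], combo[j]);
      }
      bool ok = arma::solve(beta, A, b,
                            arma::solve_opts::no_approx + arma::solve_opts::fast);
      n_fitted += 1;
      if (ok) {
        double r2 = arma::dot(b, beta) / Syy;
        if (std::isfinite(r2)) {
          if (r2 < 0) r2 = 0;
          if (r2 > 1) r2 = 1;
          insert_top(top, static_cast<std::size_t>(top_m), r2, combo);
        } else {
          n_skipped += 1;
        }
      } else {
        n_skipped += 1;
      }
      // next combination
      int i = s - 1;
      while (i >= 0 &&
             combo[i] == static_cast<arma::uword>(p) - s + i) --i;
      if (i < 0) break;
      ++combo[i];
      for (int j = i + 1; j < s; ++j) combo[j] = combo[j - 1] + 1;
    }
  }

  List subsets(top.size());
  NumericVector r2s(top.size());
  for (std::size_t i = 0; i < top.size(); ++i) {
    subsets[i] = IntegerVector(top[i].cols.begin(), top[i].cols.end());
    r2s[i] = top[i].r2;
  }
  return List::create(_["subsets"] = subsets, _["R2"] = r2s,
                      _["n_fitted"] = n_fitted, _["n_skipped"] = n_skipped);
}
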