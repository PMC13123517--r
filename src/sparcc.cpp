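// Compositionally aware correlation estimation from count tables
// (log-ratio variation matrix + sparse-basis linear system, iterative
// strong-pair exclusion, Dirichlet resampling, permutation p-values).
// All randomness flows through R's RNG so results are seed-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// variation matrix T from a log-fraction matrix (n samples x p taxa):
// t_ij = var(log f_i - log f_j) = v_i + v_j - 2 cov_ij
static arma::mat variation_from_logf(const arma::mat& logf) {
  arma::mat C = arma::cov(logf);          // p x p, denominator n-1
  arma::vec v = C.diag();
  arma::uword p = C.n_rows;
  arma::mat T = arma::repmat(v, 1, p) + arma::repmat(v.t(), p, 1) - 2.0 * C;
  T.diag().zeros();
  return T;
}

// Solve the sparse-basis system for component variances and form the
// correlation matrix; iteratively drop the strongest-correlated pair from
// the system while max |r| exceeds `excl_threshold` (at most `max_excl`
// rounds). Exclusions zero the pair's contribution to the row sums and
// decrement the pair-count diagonal; the pairwise correlation formula
// always uses the full T.
static arma::mat basis_correlation(const arma::mat& T, double excl_threshold,
                                   int max_excl, arma::vec& omega2_out) {
  arma::uword p = T.n_rows;
  arma::mat M(p, p, arma::fill::ones);
  M.diag().fill((double)(p - 1));
  arma::mat Tw = T;
  arma::umat excluded(p, p, arma::fill::zeros);
  arma::mat r(p, p, arma::fill::eye);
  arma::vec w2(p, arma::fill::ones);

  for (int iter = 0; ; ++iter) {
    arma::vec trow = arma::sum(Tw, 1);
    bool ok = arma::solve(w2, M, trow, arma::solve_opts::no_approx);
    if (!ok) w2.fill(arma::datum::nan);
    w2 = arma::clamp(w2, 1e-12, arma::datum::inf);
    arma::vec w = arma::sqrt(w2);
    r = (arma::repmat(w2, 1, p) + arma::repmat(w2.t(), p, 1) - T) /
        (2.0 * (w * w.t()));
    r = arma::clamp(r, -1.0, 1.0);
    r.diag().ones();
    if (iter >= max_excl) break;

    // strongest not-yet-excluded off-diagonal pair
    double best = -1.0;
    arma::uword bi = 0, bj = 0;
    for (arma::uword i = 0; i + 1 < p; ++i)
      for (arma::uword j = i + 1; j < p; ++j)
        if (!excluded(i, j) && std::abs(r(i, j)) > best) {
          best = std::abs(r(i, j)); bi = i; bj = j;
        }
    if (best <= excl_threshold) break;
    excluded(bi, bj) = excluded(bj, bi) = 1;
    M(bi, bj) = M(bj, bi) = 0.0;
    M(bi, bi) -= 1.0; M(bj, bj) -= 1.0;
    Tw(bi, bj) = Tw(bj, bi) = 0.0;
    // a fully excluded row would make the system singular; stop instead
    if (M(bi, bi) < 1.5 || M(bj, bj) < 1.5) break;
  }
  omega2_out = w2;
  return r;
}

// one Dirichlet resample of fractions: row-wise gamma(count + 1, 1), normalized
static arma::mat draw_log_fractions(const arma::mat& counts) {
  arma::uword n = counts.n_rows, p = counts.n_cols;
  arma::mat f(n, p);
  for (arma::uword i = 0; i < n; ++i) {
    double s = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      double g = R::rgamma(counts(i, j) + 1.0, 1.0);
      if (g < 1e-300) g = 1e-300;
      f(i, j) = g; s += g;
    }
    f.row(i) /= s;
  }
  return arma::log(f);
}

static arma::mat estimate_once(const arma::mat& counts, int n_resamples,
                               double excl_threshold, int max_excl) {
  arma::uword p = counts.n_cols;
  arma::cube rs(p, p, n_resamples);
  arma::vec w2;
  for (int k = 0; k < n_resamples; ++k) {
    arma::mat T = variation_from_logf(draw_log_fractions(counts));
    rs.slice(k) = basis_correlation(T, excl_threshold, max_excl, w2);
  }
  arma::mat out(p, p);
  for (arma::uword i = 0; i < p; ++i)
    for (arma::uword j = 0; j < p; ++j) {
      arma::vec v = rs.tube(i, j);
      out(i, j) = arma::median(v);
    }
  return out;
}

// [[Rcpp::export(name = ".sparcc_basis_cpp")]]
List sparcc_basis_cpp(const arma::mat& variation, double excl_threshold,
                      int max_excl) {
  arma::vec w2;
  arma::mat r = basis_correlation(variation, excl_threshold, max_excl, w2);
  return List::create(_["r"] = r, _["omega2"] = w2);
}

// [[Rcpp::export(name = ".sparcc_variation_cpp")]]
arma::mat sparcc_variation_cpp(const arma::mat& logf) {
  return variation_from_logf(logf);
}

// [[Rcpp::export(name = ".sparcc_estimate_cpp")]]
arma::mat sparcc_estimate_cpp(const arma::mat& counts, int n_resamples,
                              double excl_threshold, int max_excl) {
  return estimate_once(counts, n_resamples, excl_threshold, max_excl);
}

// Permutation null: permute each taxon's counts independently across
// samples, re-estimate, count |r_perm| >= |r_obs| elementwise.
// [[Rcpp::export(name = ".sparcc_perm_counts_cpp")]]
arma::mat sparcc_perm_counts_cpp(const arma::mat& counts,
                                 const arma::mat& r_obs, int n_perm,
                                 int n_resamples, double excl_threshold,
                                 int max_excl) {
  arma::uword n = counts.n_rows, p = counts.n_cols;
  arma::mat exceed(p, p, arma::fill::zeros);
  arma::mat robs_abs = arma::abs(r_obs);
  arma::mat perm(n, p);
  for (int b = 0; b < n_perm; ++b) {
    for (arma::uword j = 0; j < p; ++j) {
      IntegerVector idx = Rcpp::sample((int)n, (int)n, false);
      for (arma::uword i = 0; i < n; ++i)
        perm(i, j) = counts(idx[i] - 1, j);
    }
    arma::mat rp = arma::abs(estimate_once(perm, n_resamples,
                                           excl_threshold, max_excl));
    exceed += arma::conv_to<arma::mat>::from(rp >= robs_abs - 1e-12);
  }
  return exceed;
}
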