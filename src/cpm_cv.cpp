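// Fast inner loop for repeated k-fold CPM cross-validation.
//
// Per fold, training-set statistics are obtained as whole-sample crossprod
// blocks minus the held-out fold's block, so no submatrix of the edge table
// is ever copied. Partial correlations use the projection identities
//   e_r' y_r = e'y - (D'e)' (D'D)^{-1} (D'y)
//   ||e_r||^2 = e'e - (D'e)' (D'D)^{-1} (D'e)
// with D the training design [1, covariates] and subscript r the residual
// after projecting D out.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec avg_rank(const arma::vec& x) {
  const int n = x.n_elem;
  arma::uvec ord = arma::sort_index(x);
  arma::vec r(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x(ord(j + 1)) == x(ord(i))) ++j;
    const double avg = (i + j) / 2.0 + 1.0;
    for (int t = i; t <= j; ++t) r(ord(t)) = avg;
    i = j + 1;
  }
  return r;
}

static double spearman_rho_arma(const arma::vec& x, const arma::vec& y) {
  arma::vec rx = avg_rank(x), ry = avg_rank(y);
  if (arma::stddev(rx) == 0.0 || arma::stddev(ry) == 0.0) return NA_REAL;
  return arma::as_scalar(arma::cor(rx, ry));
}

// variant: 0 = combined (pos_sum + neg_sum), 1 = positive only, 2 = negative only
// [[Rcpp::export(name = ".cpm_cv_cpp")]]
List cpm_cv_cpp(const arma::mat& edges, const arma::vec& y, const arma::mat& covs,
                const arma::imat& folds, double alpha, int variant) {
  const int n = edges.n_rows;
  const int E = edges.n_cols;
  const int q = 1 + covs.n_cols;          // intercept + covariates
  const int R = folds.n_cols;
  const int k = folds.max();
  const double eps = 1e-12;

  arma::vec rho(R);
  arma::mat preds(n, R, arma::fill::zeros);
  arma::vec pos_count(E, arma::fill::zeros);
  arma::vec neg_count(E, arma::fill::zeros);
  int n_degenerate = 0;

  for (int r = 0; r < R; ++r) {
    // per-fold crossprod blocks
    arma::cube DtE(q, E, k, arma::fill::zeros);
    arma::mat sse(k, E, arma::fill::zeros);
    arma::mat Ey(k, E, arma::fill::zeros);
    arma::cube DtD(q, q, k, arma::fill::zeros);
    arma::mat Dty(q, k, arma::fill::zeros);
    arma::vec yy(k, arma::fill::zeros);
    arma::ivec nf(k, arma::fill::zeros);
    arma::vec d(q);

    for (int i = 0; i < n; ++i) {
      const int f = folds(i, r) - 1;
      const arma::rowvec e = edges.row(i);
      d(0) = 1.0;
      for (int a = 1; a < q; ++a) d(a) = covs(i, a - 1);
      sse.row(f) += arma::square(e);
      Ey.row(f) += y(i) * e;
      yy(f) += y(i) * y(i);
      nf(f) += 1;
      for (int a = 0; a < q; ++a) {
        DtE.slice(f).row(a) += d(a) * e;
        Dty(a, f) += d(a) * y(i);
        for (int b = 0; b < q; ++b) DtD(a, b, f) += d(a) * d(b);
      }
    }

    arma::mat tot_DtE = arma::sum(DtE, 2);
    arma::rowvec tot_sse = arma::sum(sse, 0);
    arma::rowvec tot_Ey = arma::sum(Ey, 0);
    arma::mat tot_DtD = arma::sum(DtD, 2);
    arma::vec tot_Dty = arma::sum(Dty, 1);
    const double tot_yy = arma::accu(yy);

    bool bad = false;
    for (int f = 0; f < k && !bad; ++f) {
      const int n_tr = n - nf(f);
      const int df = n_tr - 2 - (q - 1);
      arma::mat A = tot_DtD - DtD.slice(f);
      arma::vec by = tot_Dty - Dty.col(f);
      arma::vec beta_y;
      if (!arma::solve(beta_y, A, by, arma::solve_opts::no_approx)) {
        bad = true; break;  // collinear training design
      }
      const double ss_y = (tot_yy - yy(f)) - arma::dot(by, beta_y);
      if (ss_y < eps * std::max(1.0, tot_yy)) { bad = true; break; }  // constant y in fold

      arma::mat DtE_tr = tot_DtE - DtE.slice(f);        // q x E
      arma::mat AinvDtE;
      if (!arma::solve(AinvDtE, A, DtE_tr, arma::solve_opts::no_approx)) {
        bad = true; break;
      }
      arma::vec num = (tot_Ey - Ey.row(f)).t() - DtE_tr.t() * beta_y;
      arma::vec ss_e = (tot_sse - sse.row(f)).t()
        - arma::sum(DtE_tr % AinvDtE, 0).t();

      // p < alpha  <=>  |t| > t_crit  <=>  |r| > r_crit (strict monotone map),
      // so selection needs one t quantile per degrees-of-freedom value, not
      // a p-value per edge
      const double t_crit = R::qt(1.0 - alpha / 2.0, (double) df, 1, 0);
      const double r_crit = t_crit / std::sqrt(df + t_crit * t_crit);

      arma::vec pos(E, arma::fill::zeros), neg(E, arma::fill::zeros);
      for (int e = 0; e < E; ++e) {
        double se = ss_e(e);
        double rv = (se > eps) ? num(e) / std::sqrt(se * ss_y) : 0.0;
        if (rv > 1.0) rv = 1.0;
        if (rv < -1.0) rv = -1.0;
        if (rv > r_crit) pos(e) = 1.0;
        else if (rv < -r_crit) neg(e) = 1.0;
      }
      pos_count += pos;
      neg_count += neg;

      const bool use_pos = (variant != 2) && arma::accu(pos) > 0;
      const bool use_neg = (variant != 1) && arma::accu(neg) > 0;
      arma::vec psum, nsum;
      int m = 1;
      if (use_pos) { psum = arma::sum(edges.cols(arma::find(pos > 0.5)), 1); ++m; }
      if (use_neg) { nsum = arma::sum(edges.cols(arma::find(neg > 0.5)), 1); ++m; }

      // OLS of training y on [1, pos_sum, neg_sum] (present columns only)
      arma::uvec tr(n_tr), te(nf(f));
      int a = 0, b = 0;
      for (int i = 0; i < n; ++i) {
        if (folds(i, r) - 1 == f) te(b++) = i; else tr(a++) = i;
      }
      arma::mat F(n, m, arma::fill::ones);
      int col = 1;
      if (use_pos) F.col(col++) = psum;
      if (use_neg) F.col(col++) = nsum;
      arma::mat Ftr = F.rows(tr);
      arma::vec coef = arma::pinv(Ftr) * y.elem(tr);
      arma::vec pred_te = F.rows(te) * coef;
      for (arma::uword t = 0; t < te.n_elem; ++t) preds(te(t), r) = pred_te(t);
    }

    if (bad) {
      rho(r) = NA_REAL;
      preds.col(r).fill(NA_REAL);
      ++n_degenerate;
    } else {
      double rr = spearman_rho_arma(preds.col(r), y);
      rho(r) = ISNAN(rr) ? 0.0 : rr;  // constant predictions carry no rank information
    }
  }

  return List::create(
    _["rho"] = rho,
    _["predictions"] = preds,
    _["pos_count"] = pos_count,
    _["neg_count"] = neg_count,
    _["n_degenerate"] = n_degenerate);
}
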