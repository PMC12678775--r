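// Profiled-REML solver for Gaussian random-intercept models with small
// family blocks (twin pairs / singletons). V = sigma2 * (I + lambda Z Z'),
// Z = family indicator. Block structure gives closed-form whitening:
// (I + lambda J_nf)^{-1} = I - c_f J_nf with c_f = lambda / (1 + nf lambda).
// c_f depends on the family only through its size, so grouping families by
// size reduces every REML objective evaluation to O(S p^2) for S distinct
// sizes. Used for the per-pair association scans where hundreds of
// thousands of fits are required; agreement with lme4 is pinned in the
// test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Prepared {
  mat XtX;         // p x p
  vec Xty;         // p
  double yty;
  std::vector<double> sizes;   // distinct family sizes
  std::vector<int> n_fam;      // families per size group
  std::vector<mat> G;          // per size: sum of s_f s_f'
  std::vector<vec> h;          // per size: sum of t_f s_f
  std::vector<double> q;       // per size: sum of t_f^2
  int n;
  int p;
};

double reml_crit(const Prepared &pr, double lambda, vec &beta, double &rW,
                 mat &A) {
  A = pr.XtX;
  vec b = pr.Xty;
  double qq = pr.yty;
  double logdetSig = 0.0;
  for (size_t g = 0; g < pr.sizes.size(); ++g) {
    double nf = pr.sizes[g];
    double cf = lambda / (1.0 + nf * lambda);
    logdetSig += pr.n_fam[g] * std::log(1.0 + nf * lambda);
    A -= cf * pr.G[g];
    b -= cf * pr.h[g];
    qq -= cf * pr.q[g];
  }
  bool ok = solve(beta, A, b, solve_opts::likely_sympd);
  if (!ok) return datum::inf;
  rW = qq - dot(beta, b);
  if (rW <= 0) rW = 1e-12;
  double ldA, sign;
  log_det(ldA, sign, A);
  if (sign <= 0) return datum::inf;
  return (pr.n - pr.p) * std::log(rW) + logdetSig + ldA;
}

// Golden-section minimisation over u = log1p(lambda), then a boundary
// check against lambda = 0.
double optimise_lambda(const Prepared &pr) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  vec beta;
  double rW;
  mat A;
  double a = 0.0, b = std::log1p(1e4);
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = reml_crit(pr, std::expm1(c), beta, rW, A);
  double fd = reml_crit(pr, std::expm1(d), beta, rW, A);
  for (int it = 0; it < 45; ++it) {
    if (fc < fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = reml_crit(pr, std::expm1(c), beta, rW, A);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = reml_crit(pr, std::expm1(d), beta, rW, A);
    }
    if (b - a < 1e-9) break;
  }
  double lam = std::expm1((a + b) / 2.0);
  double f0 = reml_crit(pr, 0.0, beta, rW, A);
  double fm = reml_crit(pr, lam, beta, rW, A);
  return (f0 <= fm) ? 0.0 : lam;
}

void finalise(const Prepared &pr, double lambda, vec &beta, mat &cov,
              double &sigma2) {
  double rW;
  mat A;
  reml_crit(pr, lambda, beta, rW, A);
  sigma2 = rW / (pr.n - pr.p);
  cov = sigma2 * inv_sympd(A);
}

// map each family to its size-group index
void size_groups(const ivec &fam_sizes, std::vector<double> &sizes,
                 std::vector<int> &grp) {
  sizes.clear();
  grp.assign(fam_sizes.n_elem, 0);
  for (uword f = 0; f < fam_sizes.n_elem; ++f) {
    double s = fam_sizes(f);
    size_t g = 0;
    for (; g < sizes.size(); ++g) {
      if (sizes[g] == s) break;
    }
    if (g == sizes.size()) sizes.push_back(s);
    grp[f] = g;
  }
}

}  // namespace

// Single model fit. X must include the intercept column; rows must be
// ordered so that family members are contiguous, fam_sizes gives the
// block sizes in that order.
// [[Rcpp::export]]
Rcpp::List cpp_lmm_fit(const arma::mat &X, const arma::vec &y,
                       const arma::ivec &fam_sizes) {
  const int n = X.n_rows, p = X.n_cols, F = fam_sizes.n_elem;
  Prepared pr;
  pr.n = n;
  pr.p = p;
  pr.XtX = X.t() * X;
  pr.Xty = X.t() * y;
  pr.yty = dot(y, y);
  std::vector<int> grp;
  size_groups(fam_sizes, pr.sizes, grp);
  size_t S = pr.sizes.size();
  pr.n_fam.assign(S, 0);
  pr.G.assign(S, zeros<mat>(p, p));
  pr.h.assign(S, zeros<vec>(p));
  pr.q.assign(S, 0.0);
  int row = 0;
  for (int f = 0; f < F; ++f) {
    int nf = fam_sizes(f);
    rowvec sf = sum(X.rows(row, row + nf - 1), 0);
    double tf = accu(y.subvec(row, row + nf - 1));
    int g = grp[f];
    pr.n_fam[g] += 1;
    pr.G[g] += sf.t() * sf;
    pr.h[g] += tf * sf.t();
    pr.q[g] += tf * tf;
    row += nf;
  }
  if (row != n) Rcpp::stop("family sizes do not sum to the sample size");
  double lambda = optimise_lambda(pr);
  vec beta;
  mat cov;
  double sigma2;
  finalise(pr, lambda, beta, cov, sigma2);
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta, Rcpp::Named("cov") = cov,
      Rcpp::Named("sigma2") = sigma2, Rcpp::Named("lambda") = lambda,
      Rcpp::Named("sigma2_family") = lambda * sigma2);
}

// Association scan: for every exposure column of E and outcome column of Y,
// fit y ~ C + e with a family random intercept and return the exposure
// slope, its standard error and the REML variance ratio. C must contain the
// intercept. Rows of C, E, Y ordered by family.
// [[Rcpp::export]]
Rcpp::List cpp_lmm_scan(const arma::mat &C, const arma::mat &E,
                        const arma::mat &Y, const arma::ivec &fam_sizes) {
  const int n = C.n_rows, p0 = C.n_cols, K = E.n_cols, M = Y.n_cols;
  const int F = fam_sizes.n_elem;
  const int p = p0 + 1;

  mat CtC = C.t() * C;
  mat CtE = C.t() * E;
  mat CtY = C.t() * Y;
  mat EtY = E.t() * Y;
  vec ete(K), yty(M);
  for (int k = 0; k < K; ++k) ete(k) = dot(E.col(k), E.col(k));
  for (int m = 0; m < M; ++m) yty(m) = dot(Y.col(m), Y.col(m));

  mat FC(F, p0), FE(F, K), FY(F, M);
  std::vector<double> sizes;
  std::vector<int> grp;
  size_groups(fam_sizes, sizes, grp);
  size_t S = sizes.size();
  int row = 0;
  for (int f = 0; f < F; ++f) {
    int sz = fam_sizes(f);
    FC.row(f) = sum(C.rows(row, row + sz - 1), 0);
    FE.row(f) = sum(E.rows(row, row + sz - 1), 0);
    FY.row(f) = sum(Y.rows(row, row + sz - 1), 0);
    row += sz;
  }
  if (row != n) Rcpp::stop("family sizes do not sum to the sample size");

  // per size group: cross-product blocks of the family sums
  std::vector<int> n_fam(S, 0);
  std::vector<mat> GCC(S, zeros<mat>(p0, p0)), GCE(S, zeros<mat>(p0, K)),
      GCY(S, zeros<mat>(p0, M)), GEY(S, zeros<mat>(K, M)),
      GEE_diag(S, zeros<mat>(K, 1));
  std::vector<vec> qY(S, zeros<vec>(M));
  std::vector<mat> GEE; // per size: K x K not needed, only diagonal
  for (int f = 0; f < F; ++f) {
    int g = grp[f];
    n_fam[g] += 1;
    rowvec fc = FC.row(f);
    rowvec fe = FE.row(f);
    rowvec fy = FY.row(f);
    GCC[g] += fc.t() * fc;
    GCE[g] += fc.t() * fe;
    GCY[g] += fc.t() * fy;
    GEY[g] += fe.t() * fy;
    GEE_diag[g] += square(fe).t();
    qY[g] += square(fy).t();
  }

  mat beta_out(K, M), se_out(K, M), lambda_out(K, M);

  Prepared pr;
  pr.n = n;
  pr.p = p;
  pr.sizes = sizes;
  pr.n_fam = n_fam;
  pr.G.assign(S, zeros<mat>(p, p));
  pr.h.assign(S, zeros<vec>(p));
  pr.q.assign(S, 0.0);
  pr.XtX.set_size(p, p);
  pr.Xty.set_size(p);

  for (int k = 0; k < K; ++k) {
    pr.XtX.submat(0, 0, p0 - 1, p0 - 1) = CtC;
    pr.XtX.submat(0, p0, p0 - 1, p0) = CtE.col(k);
    pr.XtX.submat(p0, 0, p0, p0 - 1) = CtE.col(k).t();
    pr.XtX(p0, p0) = ete(k);
    for (size_t g = 0; g < S; ++g) {
      pr.G[g].submat(0, 0, p0 - 1, p0 - 1) = GCC[g];
      pr.G[g].submat(0, p0, p0 - 1, p0) = GCE[g].col(k);
      pr.G[g].submat(p0, 0, p0, p0 - 1) = GCE[g].col(k).t();
      pr.G[g](p0, p0) = GEE_diag[g](k, 0);
    }
    for (int m = 0; m < M; ++m) {
      pr.Xty.subvec(0, p0 - 1) = CtY.col(m);
      pr.Xty(p0) = EtY(k, m);
      pr.yty = yty(m);
      for (size_t g = 0; g < S; ++g) {
        pr.h[g].subvec(0, p0 - 1) = GCY[g].col(m);
        pr.h[g](p0) = GEY[g](k, m);
        pr.q[g] = qY[g](m);
      }
      double lambda = optimise_lambda(pr);
      vec beta;
      mat cov;
      double sigma2;
      finalise(pr, lambda, beta, cov, sigma2);
      beta_out(k, m) = beta(p0);
      se_out(k, m) = std::sqrt(cov(p0, p0));
      lambda_out(k, m) = lambda;
    }
  }
  return Rcpp::List::create(Rcpp::Named("beta") = beta_out,
                            Rcpp::Named("se") = se_out,
                            Rcpp::Named("lambda") = lambda_out);
}
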