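// Elastic-net penalized logistic regression: binary and multinomial with an
// optional grouped (group-lasso) penalty over the class coefficients of each
// gene.
//
// Solver: outer quadratic majorization of the log-likelihood (Bohning bound:
// the softmax Hessian is dominated by tau*I with tau = 1/2 for multinomial,
// 1/4 for binary), with an inner cyclic coordinate descent over genes using
// group / scalar soft-thresholding. The lambda path is fitted from largest
// to smallest with warm starts. Intercepts are unpenalized.
//
// The objective minimized (per lambda) is
//   -(1/N) sum_i [ score_{y_i}(x_i) - log sum_k exp(score_k(x_i)) ]
//   + lambda * sum_j [ (1-alpha)/2 * ||beta_j.||_2^2
//                      + alpha * (grouped ? ||beta_j.||_2 : ||beta_j.||_1) ]
// on the scale of the X actually passed in (standardization, when requested,
// happens in the R wrapper).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// row-wise softmax, numerically stable
static arma::mat softmax_rows(const arma::mat& eta) {
  arma::mat e = eta.each_col() - arma::max(eta, 1);
  e = arma::exp(e);
  arma::vec s = arma::sum(e, 1);
  return e.each_col() / s;
}

static double penalty_value(const arma::mat& B, double alpha, bool grouped,
                            double lambda) {
  double pen = 0.0;
  for (arma::uword j = 0; j < B.n_rows; ++j) {
    double l2sq = arma::dot(B.row(j), B.row(j));
    double reg = grouped ? std::sqrt(l2sq)
                         : arma::accu(arma::abs(B.row(j)));
    pen += 0.5 * (1.0 - alpha) * l2sq + alpha * reg;
  }
  return lambda * pen;
}

// stable -loglik/N for the binary logit
static double bin_negloglik(const arma::mat& eta, const arma::mat& Y) {
  const double N = (double)Y.n_rows;
  double s = 0.0;
  for (arma::uword i = 0; i < Y.n_rows; ++i) {
    double e = eta(i, 0);
    double lse = std::max(e, 0.0) + std::log1p(std::exp(-std::fabs(e)));
    s += Y(i, 0) * e - lse;
  }
  return -s / N;
}

static double mn_negloglik(const arma::mat& eta, const arma::mat& Y) {
  const double N = (double)Y.n_rows;
  arma::vec m = arma::max(eta, 1);
  arma::vec lse = m + arma::log(arma::sum(arma::exp(eta.each_col() - m), 1));
  double ll = arma::accu(Y % eta) - arma::accu(lse);
  return -ll / N;
}

// One inner CD pass (returns the largest v_j * delta^2 seen). `active`:
// when non-empty, only those genes are visited.
static double cd_sweep(const arma::mat& X, arma::mat& RW, arma::mat& B,
                       arma::rowvec& b0, const arma::vec& v, double tau,
                       double lambda, double alpha, bool grouped,
                       const std::vector<arma::uword>& genes) {
  const double N = (double)X.n_rows;
  const double l1 = lambda * alpha;
  const double l2 = lambda * (1.0 - alpha);
  double dmax = 0.0;
  for (arma::uword jj = 0; jj < genes.size(); ++jj) {
    arma::uword j = genes[jj];
    if (v(j) <= 0.0) continue;  // constant column: never enters
    arma::rowvec u = tau * ((X.col(j).t() * RW) / N + v(j) * B.row(j));
    arma::rowvec bnew(B.n_cols, arma::fill::zeros);
    const double denom = tau * v(j) + l2;
    if (grouped && B.n_cols > 1) {
      double nrm = arma::norm(u, 2);
      if (nrm > l1) bnew = u * ((1.0 - l1 / nrm) / denom);
    } else {
      for (arma::uword k = 0; k < B.n_cols; ++k)
        bnew(k) = soft(u(k), l1) / denom;
    }
    arma::rowvec d = bnew - B.row(j);
    double dm = v(j) * arma::max(arma::square(d));
    if (dm > 0.0) {
      RW -= X.col(j) * d;
      B.row(j) = bnew;
      if (dm > dmax) dmax = dm;
    }
  }
  // unpenalized intercepts
  arma::rowvec db = arma::mean(RW, 0);
  b0 += db;
  RW.each_row() -= db;
  double im = tau * arma::max(arma::square(db));
  if (im > dmax) dmax = im;
  return dmax;
}

// Fit the full lambda path. Y is an N x K indicator matrix (K = 1 for the
// binary problem, where Y holds 0/1 and eta is the single logit).
// [[Rcpp::export(name = ".enet_path")]]
List enet_path(const arma::mat& X, const arma::mat& Y,
               const arma::vec& lambda, double alpha, bool grouped,
               double tol, int max_iter, bool binary) {
  const arma::uword N = X.n_rows, p = X.n_cols, K = Y.n_cols;
  const double tau = binary ? 0.25 : 0.5;

  arma::vec v(p);
  for (arma::uword j = 0; j < p; ++j)
    v(j) = arma::dot(X.col(j), X.col(j)) / (double)N;

  arma::mat B(p, K, arma::fill::zeros);
  arma::rowvec b0(K);
  arma::rowvec prior = arma::mean(Y, 0);
  for (arma::uword k = 0; k < K; ++k) {
    double pk = std::min(std::max((double)prior(k), 1e-10), 1.0 - 1e-10);
    b0(k) = binary ? std::log(pk / (1.0 - pk)) : std::log(pk);
  }

  std::vector<arma::uword> all_genes(p);
  for (arma::uword j = 0; j < p; ++j) all_genes[j] = j;

  List B_out(lambda.n_elem), b0_out(lambda.n_elem);
  NumericVector obj_out(lambda.n_elem);
  LogicalVector conv_out(lambda.n_elem);
  IntegerVector iters_out(lambda.n_elem);

  for (arma::uword li = 0; li < lambda.n_elem; ++li) {
    const double lam = lambda(li);
    arma::mat eta = arma::repmat(b0, N, 1) + X * B;
    arma::mat P = binary ? arma::mat(1.0 / (1.0 + arma::exp(-eta)))
                         : softmax_rows(eta);
    double obj = (binary ? bin_negloglik(eta, Y) : mn_negloglik(eta, Y)) +
                 penalty_value(B, alpha, grouped, lam);
    bool converged = false;
    bool full_phase = true;  // first sweep visits every gene
    int it = 0;
    std::vector<arma::uword> act;
    for (it = 0; it < max_iter; ++it) {
      // working residual for the majorized least-squares problem
      arma::mat RW = (Y - P) / tau;
      double d = cd_sweep(X, RW, B, b0, v, tau, lam, alpha, grouped,
                          full_phase ? all_genes : act);
      bool was_full = full_phase;
      if (d >= tol || was_full) {
        act.clear();
        for (arma::uword j = 0; j < p; ++j)
          if (arma::any(B.row(j) != 0.0)) act.push_back(j);
        for (int inner = 0; inner < 1000; ++inner) {
          double di = cd_sweep(X, RW, B, b0, v, tau, lam, alpha, grouped,
                               act);
          if (di < tol) break;
        }
      }
      eta = arma::repmat(b0, N, 1) + X * B;
      P = binary ? arma::mat(1.0 / (1.0 + arma::exp(-eta)))
                 : softmax_rows(eta);
      double obj_new =
          (binary ? bin_negloglik(eta, Y) : mn_negloglik(eta, Y)) +
          penalty_value(B, alpha, grouped, lam);
      double rel = std::fabs(obj - obj_new) / (std::fabs(obj_new) + 1e-12);
      obj = obj_new;
      if (rel < tol) {
        if (was_full) { converged = true; ++it; break; }
        full_phase = true;  // verify apparent convergence with a full sweep
      } else {
        full_phase = false;
      }
    }
    B_out[li] = wrap(B);
    b0_out[li] = wrap(b0);
    obj_out[li] = obj;
    conv_out[li] = converged;
    iters_out[li] = it;
  }
  return List::create(_["beta"] = B_out, _["intercepts"] = b0_out,
                      _["objective"] = obj_out, _["converged"] = conv_out,
                      _["iterations"] = iters_out);
}
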