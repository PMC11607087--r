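// Blocked Gibbs sampler for Gaussian mixed models with optional
// covariance-structured random effects:
//   y = X beta + sum_k Z_k u_k + e,  u_k ~ N(0, s2_k K_k),  e ~ N(0, s2_R I)
// Priors: beta ~ N(0, tau2 I); SDs half-t(nu, scale) via the inverse-gamma
// scale-mixture  s2 | a ~ IG(nu/2, nu/a),  a ~ IG(1/2, 1/scale^2).
// Each variance component additionally gets an ancillary move that rescales
// (u_k, sigma_k) jointly by a log-normal Metropolis factor; this targets the
// same posterior and breaks the slow mixing of the centred Gibbs step when a
// component sits near zero.
// All draws use R's RNG so results are reproducible under set.seed().

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double rinvgamma(double shape, double rate) {
  // 1/G with G ~ Gamma(shape, rate); R_rgamma takes the scale
  double g = R::rgamma(shape, 1.0 / rate);
  if (g <= 0) g = std::numeric_limits<double>::min();
  return 1.0 / g;
}

// [[Rcpp::export(name = ".gibbs_lmm_cpp")]]
List gibbs_lmm_cpp(const arma::vec& y,
                   const arma::mat& X,
                   const List& re_index,      // per term: 1-based row->level
                   const List& re_kinv,       // per term: K^{-1} or NULL (iid)
                   int iterations, int warmup, int thin,
                   double tau_beta2, double nu,
                   double scale_sd,           // half-t scale, random-effect SDs
                   double scale_resid,        // half-t scale, residual SD
                   const arma::vec& sigma2_init,
                   double mh_step) {
  RNGScope scope;
  const int n = y.n_elem, p = X.n_cols, K = re_index.size();

  std::vector<arma::uvec> idx(K);
  std::vector<arma::mat> Kinv(K);
  std::vector<bool> iid(K);
  std::vector<int> q(K);
  std::vector<arma::vec> cnt(K);
  std::vector<arma::vec> kinv_one(K);   // K^{-1} 1, for the translation move
  std::vector<double> one_kinv_one(K);
  for (int k = 0; k < K; ++k) {
    IntegerVector iv = re_index[k];
    idx[k] = arma::uvec(iv.size());
    int qk = 0;
    for (int i = 0; i < iv.size(); ++i) {
      idx[k][i] = iv[i] - 1;
      if (iv[i] > qk) qk = iv[i];
    }
    if (!Rf_isNull(re_kinv[k])) {
      Kinv[k] = as<arma::mat>(re_kinv[k]);
      iid[k] = false;
      qk = Kinv[k].n_rows;   // covariance may carry extra (unphenotyped) levels
    } else {
      iid[k] = true;
    }
    q[k] = qk;
    cnt[k] = arma::zeros(qk);
    for (int i = 0; i < n; ++i) cnt[k][idx[k][i]] += 1.0;
    if (iid[k]) {
      kinv_one[k] = arma::ones(qk);
      one_kinv_one[k] = qk;
    } else {
      kinv_one[k] = Kinv[k] * arma::ones(qk);
      one_kinv_one[k] = arma::accu(kinv_one[k]);
    }
  }

  const arma::mat XtX = X.t() * X;
  arma::vec beta = arma::zeros(p);
  beta[0] = arma::mean(y);
  std::vector<arma::vec> u(K);
  for (int k = 0; k < K; ++k) u[k] = arma::zeros(q[k]);
  arma::vec sigma2(K + 1);
  for (int k = 0; k <= K; ++k) sigma2[k] = sigma2_init[k];
  arma::vec aux(K + 1, arma::fill::ones);
  arma::vec step(K, arma::fill::value(mh_step));
  arma::vec acc(K, arma::fill::zeros), acc_block(K, arma::fill::zeros);

  arma::vec e = y - X * beta;   // residual, kept current throughout

  const int n_keep = (iterations - warmup) / thin;
  arma::mat out_beta(n_keep, p), out_sigma2(n_keep, K + 1);
  std::vector<arma::mat> out_u(K);
  for (int k = 0; k < K; ++k) out_u[k] = arma::mat(n_keep, q[k]);
  int keep = 0, since_thin = 0;

  for (int it = 1; it <= iterations; ++it) {
    // --- beta ---
    {
      arma::vec r = e + X * beta;
      arma::mat P = XtX / sigma2[K];
      P.diag() += 1.0 / tau_beta2;
      arma::mat U = arma::chol(P);                    // upper
      arma::vec mu = arma::solve(arma::trimatu(U),
                      arma::solve(arma::trimatl(U.t()), X.t() * r / sigma2[K]));
      arma::vec z(p);
      for (int j = 0; j < p; ++j) z[j] = norm_rand();
      beta = mu + arma::solve(arma::trimatu(U), z);
      e = r - X * beta;
    }

    // --- random-effect blocks (two sweeps per iteration: the variance
    // components indexed by the same grouping factor compete for the same
    // signal and decorrelate slowly under a single sweep) ---
    for (int sweep = 0; sweep < 2; ++sweep)
    for (int k = 0; k < K; ++k) {
      // add current contribution back
      arma::vec r = e;
      for (int i = 0; i < n; ++i) r[i] += u[k][idx[k][i]];
      arma::vec b = arma::zeros(q[k]);
      for (int i = 0; i < n; ++i) b[idx[k][i]] += r[i];
      if (iid[k]) {
        for (int l = 0; l < q[k]; ++l) {
          double prec = cnt[k][l] / sigma2[K] + 1.0 / sigma2[k];
          double sd = std::sqrt(1.0 / prec);
          u[k][l] = b[l] / sigma2[K] / prec + sd * norm_rand();
        }
      } else {
        arma::mat P = Kinv[k] / sigma2[k];
        P.diag() += cnt[k] / sigma2[K];
        arma::mat U = arma::chol(P);
        arma::vec mu = arma::solve(arma::trimatu(U),
                        arma::solve(arma::trimatl(U.t()), b / sigma2[K]));
        arma::vec z(q[k]);
        for (int l = 0; l < q[k]; ++l) z[l] = norm_rand();
        u[k] = mu + arma::solve(arma::trimatu(U), z);
      }
      for (int i = 0; i < n; ++i) r[i] -= u[k][idx[k][i]];
      e = r;

      // conjugate variance step
      double quad = iid[k] ? arma::dot(u[k], u[k])
                           : arma::as_scalar(u[k].t() * Kinv[k] * u[k]);
      sigma2[k] = rinvgamma(0.5 * (nu + q[k]), nu / aux[k] + 0.5 * quad);
      aux[k] = rinvgamma(0.5 * (nu + 1.0),
                         nu / sigma2[k] + 1.0 / (scale_sd * scale_sd));

      // exact translation move: shift intercept mass between beta_0 and the
      // block mean (likelihood-invariant; conditional of the shift is
      // Gaussian because both priors are)
      {
        double a = 1.0 / tau_beta2 + one_kinv_one[k] / sigma2[k];
        double b = -beta[0] / tau_beta2 +
                   arma::dot(kinv_one[k], u[k]) / sigma2[k];
        double delta = b / a + std::sqrt(1.0 / a) * norm_rand();
        beta[0] += delta;
        u[k] -= delta;
      }

      // ancillary rescale: (sigma_k, u_k) -> (c sigma_k, c u_k), w fixed
      {
        arma::vec zu(n);
        for (int i = 0; i < n; ++i) zu[i] = u[k][idx[k][i]];
        for (int rep = 0; rep < 3; ++rep) {
          double c = std::exp(step[k] * norm_rand());
          arma::vec estar = e - (c - 1.0) * zu;
          double s = std::sqrt(sigma2[k]), sstar = c * s;
          double lp_new = -nu * std::log(sstar) - nu / (aux[k] * sstar * sstar);
          double lp_old = -nu * std::log(s) - nu / (aux[k] * s * s);
          double la = -0.5 / sigma2[K] *
                      (arma::dot(estar, estar) - arma::dot(e, e)) +
                      lp_new - lp_old;
          if (std::log(unif_rand()) < la) {
            u[k] *= c;
            zu *= c;
            sigma2[k] = sstar * sstar;
            e = estar;
            acc[k] += 1.0; acc_block[k] += 1.0;
          }
        }
      }
    }

    // --- residual variance ---
    sigma2[K] = rinvgamma(0.5 * (nu + n),
                          nu / aux[K] + 0.5 * arma::dot(e, e));
    aux[K] = rinvgamma(0.5 * (nu + 1.0),
                       nu / sigma2[K] + 1.0 / (scale_resid * scale_resid));

    // --- step-size adaptation during warmup ---
    if (it <= warmup && it % 50 == 0) {
      for (int k = 0; k < K; ++k) {
        double rate = acc_block[k] / 300.0;   // 2 sweeps x 3 proposals
        step[k] *= std::exp(rate - 0.44);
        if (step[k] < 0.01) step[k] = 0.01;
        if (step[k] > 5.0) step[k] = 5.0;
        acc_block[k] = 0.0;
      }
      if (it == warmup) acc.zeros();
    }

    // --- record ---
    if (it > warmup) {
      if (++since_thin == thin) {
        since_thin = 0;
        out_beta.row(keep) = beta.t();
        out_sigma2.row(keep) = sigma2.t();
        for (int k = 0; k < K; ++k) out_u[k].row(keep) = u[k].t();
        ++keep;
      }
    }
  }

  List ulist(K);
  for (int k = 0; k < K; ++k) ulist[k] = out_u[k];
  return List::create(_["beta"] = out_beta,
                      _["sigma2"] = out_sigma2,
                      _["u"] = ulist,
                      _["accept"] = K > 0 ? acc / std::max(1, iterations - warmup)
                                          : acc,
                      _["step"] = step);
}
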