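// Metropolis-within-Gibbs sampler for the multispecies N-mixture model.
//
// Latent abundances N are drawn from their exact discrete full conditional
// (Poisson prior times binomial visit likelihoods, normalized over
// N = max(y) .. cutoff). Species intercepts beta0 get a joint random-walk
// proposal preconditioned by the Cholesky factor of sigma0^2 R, followed by a
// per-species scalar refresh; community means (mu0, mu_beta, mu_alpha) have
// conjugate normal full conditionals and are Gibbs-drawn; standard deviations
// and theta are updated by random walks on the log scale with Jacobians.
// Step sizes adapt during burn-in only (targets 0.234 joint / 0.44 scalar).
// All randomness flows through R's RNG so set.seed() governs the chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct LgammaTable {
  std::vector<double> v;  // v[t] = lgamma(t + 1)
  void ensure(int m) {
    if ((int)v.size() > m) return;
    size_t old = v.size();
    v.resize(m + 1);
    for (size_t t = old; t < v.size(); ++t) v[t] = std::lgamma((double)t + 1.0);
  }
  double operator()(int t) const { return v[t]; }
};

double log_half_cauchy(double x, double s) {
  if (x <= 0.0) return R_NegInf;
  return std::log(2.0) - std::log(M_PI * s * (1.0 + (x / s) * (x / s)));
}

// Build correlation matrix R(theta) with Cholesky, inverse and log-det.
// Returns false when not repairable within the jitter budget.
bool build_R(const arma::mat& D, double theta, int mode, int convention,
             const arma::ivec& guild, arma::mat& R, arma::mat& L,
             arma::mat& Rinv, double& logdet, double& jitter) {
  const arma::uword I = D.n_rows;
  jitter = 0.0;
  if (mode == 0) {
    R.eye(I, I); L.eye(I, I); Rinv.eye(I, I); logdet = 0.0;
    return true;
  }
  arma::mat base(I, I);
  if (convention == 0) base = arma::exp(-D / theta);
  else base = arma::exp(-theta * D);
  if (mode == 1) {
    for (arma::uword i = 0; i < I; ++i)
      for (arma::uword j = 0; j < I; ++j)
        if (guild[i] != guild[j]) base(i, j) = 0.0;
  }
  base.diag().ones();
  double eps = 1e-10;
  arma::mat Rj = base;
  while (true) {
    if (arma::chol(L, Rj, "lower")) {
      R = Rj;
      arma::mat Linv = arma::inv(arma::trimatl(L));
      Rinv = Linv.t() * Linv;
      logdet = 2.0 * arma::accu(arma::log(L.diag()));
      return true;
    }
    if (eps > 1e-6) return false;
    Rj = (base + eps * arma::eye(I, I)) / (1.0 + eps);
    jitter = eps;
    eps *= 2.0;
  }
}

struct Adapt {
  double ls;      // log step size
  int acc, tries; // within current batch
  double target;
  long acc_all, tries_all;  // post-burn-in reporting
  Adapt(double ls0 = 0.0, double target_ = 0.44)
    : ls(ls0), acc(0), tries(0), target(target_), acc_all(0), tries_all(0) {}
  void hit(bool accepted, bool record) {
    ++tries; if (accepted) ++acc;
    if (record) { ++tries_all; if (accepted) ++acc_all; }
  }
  void batch(int bnum) {
    if (tries == 0) return;
    double rate = (double)acc / tries;
    double delta = std::min(0.05, 1.0 / std::sqrt((double)bnum));
    ls += (rate > target) ? delta : -delta;
    acc = 0; tries = 0;
  }
  double rate() const {
    return tries_all > 0 ? (double)acc_all / tries_all : NA_REAL;
  }
};

}  // namespace

// [[Rcpp::export]]
List run_sampler_cpp(IntegerVector y_flat, IntegerVector ydim,
                     IntegerMatrix mask, arma::mat X, arma::mat V,
                     arma::mat D, arma::ivec guild, int mode, int convention,
                     List priors, List init, List control) {
  const int n = ydim[0], I = ydim[1], J = ydim[2];
  const int P = X.n_cols, M = V.n_cols;
  const double mu_sd = priors["mu_sd"];
  const double sig_scale = priors["sigma_scale"];
  const double theta_max = priors["theta_max"];
  const int n_iter = control["n_iter"];
  const int n_burn = control["n_burn"];
  const int thin = control["thin"];
  const bool adapt = control["adapt"];
  const bool save_N = control["save_N"];

  // --- fixed-quantity overrides (toy/diagnostic use) ---
  SEXP fl_sexp = control["fix_lambda"], fp_sexp = control["fix_p"];
  const bool fix_lam = !Rf_isNull(fl_sexp);
  const bool fix_p = !Rf_isNull(fp_sexp);
  arma::mat lam_fix;
  arma::vec p_fix;
  if (fix_lam) lam_fix = as<arma::mat>(fl_sexp);
  if (fix_p) p_fix = as<arma::vec>(fp_sexp);

  // --- data precomputations ---
  auto Y = [&](int k, int i, int j) { return y_flat[k + n * (i + I * (size_t)j)]; };
  arma::ivec Jk(n, arma::fill::zeros);
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < J; ++j) if (mask(k, j)) ++Jk[k];
  arma::imat ymax(n, I, arma::fill::zeros);
  arma::mat sumy(n, I, arma::fill::zeros);
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < I; ++i) {
      int mx = 0; double s = 0.0;
      for (int j = 0; j < J; ++j)
        if (mask(k, j)) { int v = Y(k, i, j); s += v; if (v > mx) mx = v; }
      ymax(k, i) = mx; sumy(k, i) = s;
    }
  arma::vec sy = arma::sum(sumy, 0).t();  // per species

  // --- state ---
  arma::vec beta0 = as<arma::vec>(init["beta0"]);
  arma::mat beta = P > 0 ? as<arma::mat>(init["beta"]) : arma::mat(I, 0);
  arma::vec alpha0 = as<arma::vec>(init["alpha0"]);
  arma::vec alpha = M > 0 ? as<arma::vec>(init["alpha"]) : arma::vec();
  double mu0 = init["mu0"], sigma0 = init["sigma0"], theta = init["theta"];
  arma::vec mu_beta = P > 0 ? as<arma::vec>(init["mu_beta"]) : arma::vec();
  arma::vec sigma_beta = P > 0 ? as<arma::vec>(init["sigma_beta"]) : arma::vec();
  double mu_alpha = init["mu_alpha"], sigma_alpha = init["sigma_alpha"];
  arma::imat N = as<arma::imat>(init["N"]);

  // --- correlation structure ---
  arma::mat R, Lc, Rinv;
  double logdetR = 0.0, jit = 0.0;
  if (!build_R(D, theta, mode, convention, guild, R, Lc, Rinv, logdetR, jit))
    stop("initial correlation matrix is not positive definite");
  double jitter_max = jit;

  // --- derived quantities ---
  arma::mat lam(n, I);
  auto recompute_lambda_col = [&](int i) {
    arma::vec eta(n); eta.fill(beta0[i]);
    if (P > 0) eta += X * beta.row(i).t();
    lam.col(i) = arma::exp(eta);
  };
  auto recompute_lambda = [&]() {
    if (fix_lam) { lam = lam_fix; return; }
    for (int i = 0; i < I; ++i) recompute_lambda_col(i);
  };
  recompute_lambda();

  arma::vec pdet(I);
  auto recompute_pdet = [&]() {
    if (fix_p) { pdet = p_fix; return; }
    arma::vec eta = alpha0;
    if (M > 0) eta += V * alpha;
    pdet = 1.0 / (1.0 + arma::exp(-eta));
  };
  recompute_pdet();

  arma::vec sumN(I), sNJ(I), sumLam(I);
  arma::mat sumNX(I, P);
  auto recompute_N_stats = [&]() {
    for (int i = 0; i < I; ++i) {
      double sn = 0.0, sj = 0.0;
      for (int k = 0; k < n; ++k) { sn += N(k, i); sj += Jk[k] * (double)N(k, i); }
      sumN[i] = sn; sNJ[i] = sj;
      for (int p = 0; p < P; ++p) {
        double s = 0.0;
        for (int k = 0; k < n; ++k) s += N(k, i) * X(k, p);
        sumNX(i, p) = s;
      }
    }
  };
  recompute_N_stats();
  auto recompute_sumLam = [&]() { sumLam = arma::sum(lam, 0).t(); };
  recompute_sumLam();

  auto quad = [&](const arma::vec& b) {
    arma::vec r = b - mu0;
    return arma::as_scalar(r.t() * Rinv * r);
  };
  double q = quad(beta0);

  // detection log-likelihood for one species from sufficient statistics
  auto det_ll = [&](int i, double p) {
    if (p <= 0.0 || p >= 1.0) {
      // p == 1 is admissible only when every count equals N on every visit
      if (p >= 1.0 && sy[i] == sNJ[i]) return 0.0;
      return R_NegInf;
    }
    return sy[i] * std::log(p) + (sNJ[i] - sy[i]) * std::log1p(-p);
  };

  LgammaTable lg;
  lg.ensure(1024);

  // --- adaptation state ---
  Adapt a_joint(std::log(0.1), 0.234);
  std::vector<Adapt> a_b0(I, Adapt(std::log(0.5), 0.44));
  std::vector<Adapt> a_beta(I * P, Adapt(std::log(0.5), 0.44));
  std::vector<Adapt> a_al0(I, Adapt(std::log(0.5), 0.44));
  std::vector<Adapt> a_alM(M, Adapt(std::log(0.1), 0.44));
  std::vector<Adapt> a_ridge(M, Adapt(std::log(0.3), 0.44));
  Adapt a_sig0(std::log(0.3), 0.44), a_theta(std::log(0.3), 0.44);
  std::vector<Adapt> a_sigb(P, Adapt(std::log(0.3), 0.44));
  Adapt a_siga(std::log(0.3), 0.44);

  // --- storage ---
  const int n_keep = (n_iter - n_burn) / thin;
  const int n_hyper = 5 + 2 * P + M;
  NumericMatrix out_hyper(n_keep, n_hyper);
  NumericMatrix out_beta0(n_keep, I);
  NumericMatrix out_beta(n_keep, I * P);
  NumericMatrix out_alpha0(n_keep, I);
  IntegerMatrix out_N(save_N ? n_keep : 0, save_N ? n * I : 0);
  int kept = 0;
  bool tail_warn = false;

  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool post = iter > n_burn;

    if (!fix_lam) {
      // ---- joint beta0 update, preconditioned by chol(sigma0^2 R) ----
      {
        arma::vec z(I);
        for (int i = 0; i < I; ++i) z[i] = norm_rand();
        arma::vec delta = std::exp(a_joint.ls) * sigma0 * (Lc * z);
        double dll = 0.0;
        for (int i = 0; i < I; ++i)
          dll += delta[i] * sumN[i] - (std::exp(delta[i]) - 1.0) * sumLam[i];
        arma::vec prop = beta0 + delta;
        double qp = quad(prop);
        double lr = dll - 0.5 * (qp - q) / (sigma0 * sigma0);
        bool ok = std::isfinite(lr) && std::log(unif_rand()) < lr;
        if (ok) {
          beta0 = prop; q = qp;
          for (int i = 0; i < I; ++i) {
            lam.col(i) *= std::exp(delta[i]);
            sumLam[i] *= std::exp(delta[i]);
          }
        }
        a_joint.hit(ok, post);
      }
      // ---- per-species scalar refresh of beta0 ----
      for (int i = 0; i < I; ++i) {
        double d = std::exp(a_b0[i].ls) * norm_rand();
        double dll = d * sumN[i] - (std::exp(d) - 1.0) * sumLam[i];
        double ci = arma::as_scalar(Rinv.row(i) * (beta0 - mu0));
        double dq = 2.0 * d * ci + d * d * Rinv(i, i);
        double lr = dll - 0.5 * dq / (sigma0 * sigma0);
        bool ok = std::isfinite(lr) && std::log(unif_rand()) < lr;
        if (ok) {
          beta0[i] += d; q += dq;
          lam.col(i) *= std::exp(d);
          sumLam[i] *= std::exp(d);
        }
        a_b0[i].hit(ok, post);
      }
      // ---- covariate effects beta(i, p) ----
      for (int i = 0; i < I; ++i)
        for (int p = 0; p < P; ++p) {
          double d = std::exp(a_beta[i + I * p].ls) * norm_rand();
          double dll = d * sumNX(i, p);
          double sl = 0.0;
          for (int k = 0; k < n; ++k)
            sl += lam(k, i) * (std::exp(d * X(k, p)) - 1.0);
          dll -= sl;
          double b_old = beta(i, p);
          double dpr = R::dnorm(b_old + d, mu_beta[p], sigma_beta[p], 1) -
                       R::dnorm(b_old, mu_beta[p], sigma_beta[p], 1);
          double lr = dll + dpr;
          bool ok = std::isfinite(lr) && std::log(unif_rand()) < lr;
          if (ok) {
            beta(i, p) += d;
            for (int k = 0; k < n; ++k) lam(k, i) *= std::exp(d * X(k, p));
            sumLam[i] = arma::accu(lam.col(i));
          }
          a_beta[i + I * p].hit(ok, post);
        }
      // ---- mu0: conjugate normal full conditional ----
      {
        double s1 = arma::accu(Rinv);
        double sb = arma::accu(Rinv * beta0);
        double tau = s1 / (sigma0 * sigma0) + 1.0 / (mu_sd * mu_sd);
        double mean = (sb / (sigma0 * sigma0)) / tau;
        mu0 = mean + norm_rand() / std::sqrt(tau);
        q = quad(beta0);
      }
      // ---- sigma0: log-scale random walk ----
      {
        double ls = std::log(sigma0) + std::exp(a_sig0.ls) * norm_rand();
        double sp = std::exp(ls);
        double lr = -I * (ls - std::log(sigma0)) -
          0.5 * q * (1.0 / (sp * sp) - 1.0 / (sigma0 * sigma0)) +
          log_half_cauchy(sp, sig_scale) - log_half_cauchy(sigma0, sig_scale) +
          (ls - std::log(sigma0));  // Jacobian
        bool ok = std::isfinite(lr) && std::log(unif_rand()) < lr;
        if (ok) sigma0 = sp;
        a_sig0.hit(ok, post);
      }
      // ---- theta: log-scale random walk (Uniform(0, theta_max) prior) ----
      if (mode != 0) {
        double lt = std::log(theta) + std::exp(a_theta.ls) * norm_rand();
        double tp = std::exp(lt);
        bool ok = false;
        if (tp < theta_max) {
          arma::mat Rp, Lp, Rip;
          double ldp, jp;
          if (build_R(D, tp, mode, convention, guild, Rp, Lp, Rip, ldp, jp)) {
            arma::vec r = beta0 - mu0;
            double qp = arma::as_scalar(r.t() * Rip * r);
            double lr = -0.5 * (ldp - logdetR) -
              0.5 * (qp - q) / (sigma0 * sigma0) + (lt - std::log(theta));
            if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
              ok = true; theta = tp; R = Rp; Lc = Lp; Rinv = Rip;
              logdetR = ldp; q = qp;
              if (jp > jitter_max) jitter_max = jp;
            }
          }
        }
        a_theta.hit(ok, post);
      }
      // ---- slope hyperparameters ----
      for (int p = 0; p < P; ++p) {
        double sg = sigma_beta[p];
        double tau = I / (sg * sg) + 1.0 / (mu_sd * mu_sd);
        double mean = (arma::accu(beta.col(p)) / (sg * sg)) / tau;
        mu_beta[p] = mean + norm_rand() / std::sqrt(tau);
        double ss = arma::accu(arma::square(beta.col(p) - mu_beta[p]));
        double ls = std::log(sg) + std::exp(a_sigb[p].ls) * norm_rand();
        double sp2 = std::exp(ls);
        double lr = -I * (ls - std::log(sg)) -
          0.5 * ss * (1.0 / (sp2 * sp2) - 1.0 / (sg * sg)) +
          log_half_cauchy(sp2, sig_scale) - log_half_cauchy(sg, sig_scale) +
          (ls - std::log(sg));
        bool ok = std::isfinite(lr) && std::log(unif_rand()) < lr;
        if (ok) sigma_beta[p] = sp2;
        a_sigb[p].hit(ok, post);
      }
    }

    if (!fix_p) {
      // ---- species detection intercepts ----
      for (int i = 0; i < I; ++i) {
        double d = std::exp(a_al0[i].ls) * norm_rand();
        double vi = M > 0 ? arma::as_scalar(V.row(i) * alpha) : 0.0;
        double pn = 1.0 / (1.0 + std::exp(-(alpha0[i] + d + vi)));
        double lr = det_ll(i, pn) - det_ll(i, pdet[i]) +
          R::dnorm(alpha0[i] + d, mu_alpha, sigma_alpha, 1) -
          R::dnorm(alpha0[i], mu_alpha, sigma_alpha, 1);
        bool ok = std::isfinite(lr) && std::log(unif_rand()) < lr;
        if (ok) { alpha0[i] += d; pdet[i] = pn; }
        a_al0[i].hit(ok, post);
      }
      // ---- detection covariate effects ----
      for (int m = 0; m < M; ++m) {
        double d = std::exp(a_alM[m].ls) * norm_rand();
        arma::vec an = alpha; an[m] += d;
        arma::vec etan = alpha0 + V * an;
        double lr = R::dnorm(an[m], 0.0, mu_sd, 1) -
                    R::dnorm(alpha[m], 0.0, mu_sd, 1);
        arma::vec pn(I);
        for (int i = 0; i < I; ++i) {
          pn[i] = 1.0 / (1.0 + std::exp(-etan[i]));
          lr += det_ll(i, pn[i]) - det_ll(i, pdet[i]);
        }
        bool ok = std::isfinite(lr) && std::log(unif_rand()) < lr;
        if (ok) { alpha = an; pdet = pn; }
        a_alM[m].hit(ok, post);
      }
      // ---- ridge move: shift alpha[m], compensate alpha0 so that the
      // detection probabilities (and hence the likelihood) are unchanged;
      // accepted on the prior ratio alone. Decorrelates alpha from the
      // species intercepts. ----
      for (int m = 0; m < M; ++m) {
        double d = std::exp(a_ridge[m].ls) * norm_rand();
        arma::vec a0n = alpha0 - V.col(m) * d;
        double lr = R::dnorm(alpha[m] + d, 0.0, mu_sd, 1) -
                    R::dnorm(alpha[m], 0.0, mu_sd, 1);
        for (int i = 0; i < I; ++i)
          lr += R::dnorm(a0n[i], mu_alpha, sigma_alpha, 1) -
                R::dnorm(alpha0[i], mu_alpha, sigma_alpha, 1);
        bool ok = std::isfinite(lr) && std::log(unif_rand()) < lr;
        if (ok) { alpha[m] += d; alpha0 = a0n; }
        a_ridge[m].hit(ok, post);
      }
      // ---- detection hyperparameters ----
      {
        double tau = I / (sigma_alpha * sigma_alpha) + 1.0 / (mu_sd * mu_sd);
        double mean = (arma::accu(alpha0) / (sigma_alpha * sigma_alpha)) / tau;
        mu_alpha = mean + norm_rand() / std::sqrt(tau);
        double ss = arma::accu(arma::square(alpha0 - mu_alpha));
        double ls = std::log(sigma_alpha) + std::exp(a_siga.ls) * norm_rand();
        double sp = std::exp(ls);
        double lr = -I * (ls - std::log(sigma_alpha)) -
          0.5 * ss * (1.0 / (sp * sp) - 1.0 / (sigma_alpha * sigma_alpha)) +
          log_half_cauchy(sp, sig_scale) -
          log_half_cauchy(sigma_alpha, sig_scale) + (ls - std::log(sigma_alpha));
        bool ok = std::isfinite(lr) && std::log(unif_rand()) < lr;
        if (ok) sigma_alpha = sp;
        a_siga.hit(ok, post);
      }
    }

    // ---- latent abundances: exact discrete full conditional per cell ----
    {
      std::vector<double> lw;
      lw.reserve(128);
      for (int i = 0; i < I; ++i) {
        double p = pdet[i];
        for (int k = 0; k < n; ++k) {
          int ym = ymax(k, i);
          if (p >= 1.0) { N(k, i) = ym; continue; }
          double la = lam(k, i);
          int Jkk = Jk[k];
          double ll1 = std::log(la) + Jkk * std::log1p(-p);
          // initial grid end: analytic Poisson(la(1-p)) upper-tail bound;
          // the extension loop below guarantees negligible truncated mass
          double r = la * (1.0 - p);
          int cap = ym + (int)(r + 6.5 * std::sqrt(r)) + 12;
          lg.ensure(cap + 1);
          lw.clear();
          double lmax = R_NegInf;
          auto wfun = [&](int Nv) {
            double s = Nv * ll1 + (Jkk - 1.0) * lg(Nv);
            for (int j = 0; j < J; ++j)
              if (mask(k, j)) s -= lg(Nv - Y(k, i, j));
            return s;
          };
          for (int Nv = ym; Nv <= cap; ++Nv) {
            double w = wfun(Nv);
            lw.push_back(w);
            if (w > lmax) lmax = w;
          }
          // extend if the tail is not yet negligible
          while (lw.back() - lmax > std::log(1e-12) && cap - ym < 100000) {
            int newcap = cap + std::max(16, (cap - ym) / 2);
            lg.ensure(newcap + 1);
            for (int Nv = cap + 1; Nv <= newcap; ++Nv) {
              double w = wfun(Nv);
              lw.push_back(w);
              if (w > lmax) lmax = w;
            }
            cap = newcap;
          }
          if (cap - ym >= 100000) tail_warn = true;
          double tot = 0.0;
          for (double& w : lw) { w = std::exp(w - lmax); tot += w; }
          double u = unif_rand() * tot, c = 0.0;
          int pick = ym;
          for (size_t t = 0; t < lw.size(); ++t) {
            c += lw[t];
            if (u <= c) { pick = ym + (int)t; break; }
          }
          N(k, i) = pick;
        }
      }
      recompute_N_stats();
    }

    // ---- adaptation (burn-in only) ----
    if (adapt && iter <= n_burn && iter % 50 == 0) {
      int bnum = iter / 50;
      a_joint.batch(bnum);
      for (auto& a : a_b0) a.batch(bnum);
      for (auto& a : a_beta) a.batch(bnum);
      for (auto& a : a_al0) a.batch(bnum);
      for (auto& a : a_alM) a.batch(bnum);
      for (auto& a : a_ridge) a.batch(bnum);
      a_sig0.batch(bnum); a_theta.batch(bnum); a_siga.batch(bnum);
      for (auto& a : a_sigb) a.batch(bnum);
    }

    // ---- record ----
    if (post && ((iter - n_burn) % thin == 0) && kept < n_keep) {
      int c = 0;
      out_hyper(kept, c++) = mu0;
      out_hyper(kept, c++) = sigma0;
      out_hyper(kept, c++) = mode == 0 ? NA_REAL : theta;
      out_hyper(kept, c++) = mu_alpha;
      out_hyper(kept, c++) = sigma_alpha;
      for (int p = 0; p < P; ++p) out_hyper(kept, c++) = mu_beta[p];
      for (int p = 0; p < P; ++p) out_hyper(kept, c++) = sigma_beta[p];
      for (int m = 0; m < M; ++m) out_hyper(kept, c++) = alpha[m];
      for (int i = 0; i < I; ++i) out_beta0(kept, i) = beta0[i];
      for (int p = 0; p < P; ++p)
        for (int i = 0; i < I; ++i) out_beta(kept, i + I * p) = beta(i, p);
      for (int i = 0; i < I; ++i) out_alpha0(kept, i) = alpha0[i];
      if (save_N)
        for (int i = 0; i < I; ++i)
          for (int k = 0; k < n; ++k) out_N(kept, k + n * i) = N(k, i);
      ++kept;
    }

    if (iter % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  if (tail_warn)
    Rf_warning("latent-abundance grid reached its hard cap; tail mass may be truncated");

  double b0rate = 0.0, betarate = 0.0, al0rate = 0.0;
  for (auto& a : a_b0) b0rate += a.rate();
  b0rate /= I;
  if (P > 0) {
    for (auto& a : a_beta) betarate += a.rate();
    betarate /= (I * P);
  } else betarate = NA_REAL;
  for (auto& a : a_al0) al0rate += a.rate();
  al0rate /= I;

  List final_state = List::create(
    _["beta0"] = beta0, _["beta"] = beta, _["alpha0"] = alpha0,
    _["alpha"] = alpha, _["mu0"] = mu0, _["sigma0"] = sigma0,
    _["theta"] = theta, _["mu_beta"] = mu_beta, _["sigma_beta"] = sigma_beta,
    _["mu_alpha"] = mu_alpha, _["sigma_alpha"] = sigma_alpha, _["N"] = N);

  return List::create(
    _["hyper"] = out_hyper, _["beta0"] = out_beta0, _["beta"] = out_beta,
    _["alpha0"] = out_alpha0, _["N"] = out_N,
    _["acceptance"] = List::create(
      _["beta0_joint"] = a_joint.rate(), _["beta0_scalar"] = b0rate,
      _["beta"] = betarate, _["alpha0"] = al0rate,
      _["sigma0"] = a_sig0.rate(),
      _["theta"] = mode == 0 ? NA_REAL : a_theta.rate(),
      _["sigma_alpha"] = a_siga.rate()),
    _["jitter_used"] = jitter_max,
    _["final_state"] = final_state);
}
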