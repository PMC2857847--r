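// Gibbs / Metropolis samplers for the four whole-genome regression models.
//
// Model per trait (one time point):
//   y = 1*mu + X beta + Z u + e,   u ~ N(0, A sigma2_u),  e ~ N(0, I sigma2_e)
// with flat chi^-2(-2, 0) priors on sigma2_u and sigma2_e, and method-specific
// priors on beta (see R documentation).
//
// Scaled inverse-chi-squared convention used throughout: a draw from
// ScInvChi2(df, SS) is SS / chisq(df), with mean SS / (df - 2).  Posterior
// updating under a normal likelihood adds sums of squares to SS and counts
// to df, so the flat prior chi^-2(-2, 0) composed with n residual terms
// gives ScInvChi2(n - 2, SSE).

#include <Rcpp.h>
using namespace Rcpp;

static inline double rscinv(double df, double ss) {
  return ss / R::rchisq(df);
}

// [[Rcpp::export]]
NumericVector rscinvchisq_cpp(int n, double df, double ss) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rscinv(df, ss);
  return out;
}

// Log marginal likelihood gain of residual vector r for one SNP when its
// effect is integrated out against N(0, V), relative to V = 0:
//   r ~ N(0, se2 I + V x x')
// depends on the data only through a = x'x and b = x'r.
static inline double log_ml_gain(double V, double a, double b, double se2) {
  if (V <= 0.0) return 0.0;
  return -0.5 * log1p(V * a / se2) + 0.5 * V * b * b / (se2 * (se2 + V * a));
}

// Draw beta from its normal full conditional given effect variance V,
// a = x'x, b = x'r_j (residual with this SNP's contribution added back).
static inline double draw_beta(double V, double a, double b, double se2) {
  double denom = a + se2 / V;
  double mean = b / denom;
  double sd = std::sqrt(se2 / denom);
  return mean + sd * R::norm_rand();
}

// Core MCMC engine.
//
// method: 0 = BLUP (common effect variance), 1 = Bayes A, 2 = Bayes A/B
//         hybrid (reversible jump every k iterations), 3 = Bayes C (SSVS).
// Ainv_*: slots of a dgCMatrix holding A^-1 over the n_ped pedigree animals
//         (both triangles stored).  obs_ped maps each observation (row of X)
//         to its 0-based pedigree index; pass n_ped = 0 to drop the
//         polygenic term.
// Options (opts list):
//   update_mu (bool), mu_init, fix_sigma2_e (bool), sigma2_e_init,
//   fix_sigma2_beta (bool), sigma2_beta_init, var_floor, verbose (bool)
//
// Returned batch means (20 batches over retained samples) support
// Monte-Carlo standard errors for the oracle tests.
// [[Rcpp::export]]
List gs_mcmc_cpp(NumericVector y, NumericMatrix X, int method,
                 double nu, double S, double pi, double csmall,
                 int k, int m,
                 IntegerVector Ainv_i, IntegerVector Ainv_p,
                 NumericVector Ainv_x, IntegerVector obs_ped, int n_ped,
                 int n_iter, int burn_in, int thin, List opts) {
  const int n = y.size();
  const int p = X.ncol();
  if (p > 0 && X.nrow() != n) stop("nrow(X) must equal length(y)");
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter");
  if (thin < 1) stop("thin must be >= 1");

  const bool update_mu   = as<bool>(opts["update_mu"]);
  const bool fix_se2     = as<bool>(opts["fix_sigma2_e"]);
  const bool fix_sb2     = as<bool>(opts["fix_sigma2_beta"]);
  const double mu_init   = as<double>(opts["mu_init"]);
  const double se2_init  = as<double>(opts["sigma2_e_init"]);
  const double sb2_init  = as<double>(opts["sigma2_beta_init"]);
  const double var_floor = as<double>(opts["var_floor"]);
  const bool verbose     = as<bool>(opts["verbose"]);

  const bool poly = n_ped > 0;
  if (poly && obs_ped.size() != n) stop("obs_ped must map every observation");

  // ---- state ----
  double mu = update_mu ? Rcpp::mean(y) : mu_init;
  std::vector<double> beta(p, 0.0), sb2(p, sb2_init);
  std::vector<int> gamma_in(p, 1);           // inclusion / large-component state
  double sb2_common = sb2_init;              // BLUP common variance
  std::vector<double> u(n_ped, 0.0);
  double se2 = se2_init;
  double su2 = fix_se2 ? se2_init : (se2_init > 0 ? se2_init / 2.0 : 1.0);
  {
    double su2_init = as<double>(opts["sigma2_u_init"]);
    if (su2_init > 0) su2 = su2_init;
  }
  const bool fix_su2 = as<bool>(opts["fix_sigma2_u"]);

  std::vector<double> resid(n);
  for (int i = 0; i < n; ++i) resid[i] = y[i] - mu;

  // precompute x'x; raw column pointers for the hot loops
  const double *Xp = X.begin();
  std::vector<double> xtx(p, 0.0);
  std::vector<bool> active(p, true);
  for (int j = 0; j < p; ++j) {
    const double *xj = Xp + (size_t)j * n;
    double a = 0.0;
    for (int i = 0; i < n; ++i) a += xj[i] * xj[i];
    xtx[j] = a;
    if (a < 1e-12) { active[j] = false; beta[j] = 0.0; }
  }

  // diagonal of A^-1 for the single-site polygenic updates
  std::vector<double> ainv_diag(n_ped, 0.0);
  if (poly) {
    for (int col = 0; col < n_ped; ++col)
      for (int idx = Ainv_p[col]; idx < Ainv_p[col + 1]; ++idx)
        if (Ainv_i[idx] == col) ainv_diag[col] = Ainv_x[idx];
  }
  // which observation (if any) belongs to each pedigree animal
  std::vector<int> ped_obs(n_ped, -1);
  if (poly) {
    for (int i = 0; i < n; ++i) {
      int a = obs_ped[i];
      if (a < 0 || a >= n_ped) stop("obs_ped index out of range");
      if (ped_obs[a] != -1) stop("at most one record per animal is supported");
      ped_obs[a] = i;
    }
  }

  // ---- accumulators ----
  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  const int NB = 20;
  double mu_sum = 0.0, mu_sq = 0.0, se2_sum = 0.0, su2_sum = 0.0;
  std::vector<double> beta_sum(p, 0.0), beta_sq(p, 0.0), incl_sum(p, 0.0);
  std::vector<double> sb2_sum(p, 0.0), u_sum(n_ped, 0.0);
  NumericMatrix bm_beta(NB, p), bm_gamma(NB, p), bm_u(NB, n_ped);
  NumericVector bm_mu(NB);
  std::vector<int> bm_n(NB, 0);
  NumericMatrix trace(n_keep, 4); // sigma2_e, sigma2_u, mu, n_included
  int kept = 0;
  double max_resid_dev = 0.0;

  const double log_prior_odds = (pi >= 1.0) ? R_PosInf
                              : (pi <= 0.0) ? R_NegInf
                              : std::log(pi / (1.0 - pi));

  for (int iter = 1; iter <= n_iter; ++iter) {
    // ---- mean ----
    if (update_mu) {
      double rbar = 0.0;
      for (int i = 0; i < n; ++i) rbar += resid[i];
      rbar /= n;
      double mu_new = (mu + rbar) + std::sqrt(se2 / n) * R::norm_rand();
      double d = mu - mu_new;
      for (int i = 0; i < n; ++i) resid[i] += d;
      mu = mu_new;
    }

    // ---- SNP effects ----
    bool rj_iter = (method == 2) && (pi < 1.0) && (k >= 1) && (iter % k == 0);
    for (int j = 0; j < p; ++j) {
      if (!active[j]) continue;
      if (method == 2 && !gamma_in[j] && !rj_iter) continue; // held at zero

      const double *xj = Xp + (size_t)j * n;
      double a = xtx[j];
      double b = beta[j] * a;
      for (int i = 0; i < n; ++i) b += xj[i] * resid[i]; // b = x' r_j
      double beta_new = 0.0;

      if (method == 0) {                       // BLUP: common variance
        beta_new = draw_beta(sb2_common, a, b, se2);
      } else if (method == 1 || (method == 2 && !rj_iter)) {
        // Bayes A step: variance given current beta, then effect
        if (!fix_sb2) sb2[j] = std::max(rscinv(nu + 1.0, S + beta[j] * beta[j]), var_floor);
        beta_new = draw_beta(sb2[j], a, b, se2);
      } else if (method == 2) {                // reversible-jump sweep
        if (gamma_in[j] && !fix_sb2)
          sb2[j] = std::max(rscinv(nu + 1.0, S + beta[j] * beta[j]), var_floor);
        for (int rep = 0; rep < m; ++rep) {
          if (!gamma_in[j]) {
            // birth: propose variance from its prior; beta integrated out
            double v_star = fix_sb2 ? sb2[j] : std::max(rscinv(nu, S), var_floor);
            double logA = log_prior_odds + log_ml_gain(v_star, a, b, se2);
            if (std::log(R::unif_rand()) < logA) { gamma_in[j] = 1; sb2[j] = v_star; }
          } else {
            // death: remove the SNP, using its current variance
            double logA = -log_prior_odds - log_ml_gain(sb2[j], a, b, se2);
            if (std::log(R::unif_rand()) < logA) gamma_in[j] = 0;
          }
        }
        beta_new = gamma_in[j] ? draw_beta(sb2[j], a, b, se2) : 0.0;
      } else {                                 // Bayes C / SSVS
        double v_large = sb2[j];
        double v_small = csmall * sb2[j];
        double logodds = log_prior_odds +
          log_ml_gain(v_large, a, b, se2) - log_ml_gain(v_small, a, b, se2);
        double pr_in = 1.0 / (1.0 + std::exp(-logodds));
        gamma_in[j] = (R::unif_rand() < pr_in) ? 1 : 0;
        double V = gamma_in[j] ? v_large : v_small;
        beta_new = draw_beta(V, a, b, se2);
        if (!fix_sb2) {
          double scaled = beta_new * beta_new / (gamma_in[j] ? 1.0 : csmall);
          sb2[j] = std::max(rscinv(nu + 1.0, S + scaled), var_floor);
        }
      }

      if (beta_new != beta[j]) {
        double d = beta[j] - beta_new;
        for (int i = 0; i < n; ++i) resid[i] += d * xj[i];
        beta[j] = beta_new;
      }
    }

    // BLUP common variance, once per iteration
    if (method == 0 && !fix_sb2) {
      double ssb = 0.0;
      int n_eff = 0;
      for (int j = 0; j < p; ++j) if (active[j]) { ssb += beta[j] * beta[j]; ++n_eff; }
      sb2_common = std::max(rscinv(nu + n_eff, S + ssb), var_floor);
    }

    // ---- polygenic effects: single-site Gibbs with sparse A^-1 ----
    if (poly) {
      for (int a = 0; a < n_ped; ++a) {
        double off = 0.0;
        for (int idx = Ainv_p[a]; idx < Ainv_p[a + 1]; ++idx) {
          int row = Ainv_i[idx];
          if (row != a) off += Ainv_x[idx] * u[row];
        }
        int oi = ped_obs[a];
        double prec = ainv_diag[a] / su2 + (oi >= 0 ? 1.0 / se2 : 0.0);
        double rhs = -off / su2 + (oi >= 0 ? (resid[oi] + u[a]) / se2 : 0.0);
        double mean = rhs / prec;
        double u_new = mean + std::sqrt(1.0 / prec) * R::norm_rand();
        if (oi >= 0) resid[oi] += u[a] - u_new;
        u[a] = u_new;
      }
      if (!fix_su2) {
        // quadratic form u' A^-1 u via the sparse matrix
        double qf = 0.0;
        for (int col = 0; col < n_ped; ++col)
          for (int idx = Ainv_p[col]; idx < Ainv_p[col + 1]; ++idx)
            qf += u[Ainv_i[idx]] * Ainv_x[idx] * u[col];
        if (n_ped <= 2) stop("polygenic variance update needs more than 2 animals");
        su2 = std::max(rscinv((double)n_ped - 2.0, qf), var_floor);
      }
    }

    // ---- residual variance, flat chi^-2(-2, 0) prior ----
    if (!fix_se2) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += resid[i] * resid[i];
      if (n <= 2) stop("residual variance update needs more than 2 records");
      se2 = std::max(rscinv((double)n - 2.0, sse), var_floor);
    }
    if (se2 > 1e12 || su2 > 1e12)
      stop("divergent variance at iteration %d (sigma2_e=%g, sigma2_u=%g)",
           iter, se2, su2);

    // ---- periodic residual refresh / consistency check ----
    if (iter % 1000 == 0 || iter == n_iter) {
      std::vector<double> fit(n, mu);
      for (int j = 0; j < p; ++j) {
        if (beta[j] == 0.0) continue;
        const double *xj = Xp + (size_t)j * n;
        for (int i = 0; i < n; ++i) fit[i] += xj[i] * beta[j];
      }
      for (int i = 0; i < n; ++i) {
        if (poly) fit[i] += u[obs_ped[i]];
        double r_true = y[i] - fit[i];
        double dev = std::fabs(resid[i] - r_true);
        if (dev > max_resid_dev) max_resid_dev = dev;
        resid[i] = r_true;
      }
      if (verbose)
        Rprintf("iter %d: sigma2_e=%.4f sigma2_u=%.4f\n", iter, se2, su2);
    }

    // ---- accumulate ----
    if (iter > burn_in && (iter - burn_in - 1) % thin == 0) {
      int bi = (int)(((long long)kept * NB) / n_keep);
      if (bi >= NB) bi = NB - 1;
      mu_sum += mu; mu_sq += mu * mu;
      se2_sum += se2; su2_sum += su2;
      bm_mu[bi] += mu;
      int n_in = 0;
      for (int j = 0; j < p; ++j) {
        beta_sum[j] += beta[j];
        beta_sq[j] += beta[j] * beta[j];
        double inc = (method == 2 || method == 3) ? (double)gamma_in[j] : 1.0;
        incl_sum[j] += inc;
        sb2_sum[j] += (method == 0) ? sb2_common : sb2[j];
        bm_beta(bi, j) += beta[j];
        bm_gamma(bi, j) += inc;
        if (gamma_in[j]) ++n_in;
      }
      for (int a = 0; a < n_ped; ++a) { u_sum[a] += u[a]; bm_u(bi, a) += u[a]; }
      trace(kept, 0) = se2; trace(kept, 1) = su2; trace(kept, 2) = mu;
      trace(kept, 3) = n_in;
      bm_n[bi] += 1;
      ++kept;
    }
    if (iter % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector beta_mean(p), beta_var(p), incl(p), sb2_mean(p);
  for (int j = 0; j < p; ++j) {
    beta_mean[j] = beta_sum[j] / kept;
    beta_var[j] = beta_sq[j] / kept - beta_mean[j] * beta_mean[j];
    incl[j] = incl_sum[j] / kept;
    sb2_mean[j] = sb2_sum[j] / kept;
  }
  NumericVector u_mean(n_ped);
  for (int a = 0; a < n_ped; ++a) u_mean[a] = u_sum[a] / kept;
  for (int b = 0; b < NB; ++b) {
    if (bm_n[b] == 0) continue;
    bm_mu[b] /= bm_n[b];
    for (int j = 0; j < p; ++j) { bm_beta(b, j) /= bm_n[b]; bm_gamma(b, j) /= bm_n[b]; }
    for (int a = 0; a < n_ped; ++a) bm_u(b, a) /= bm_n[b];
  }
  colnames(trace) = CharacterVector::create("sigma2_e", "sigma2_u", "mu",
                                            "n_included");

  return List::create(
    _["mu"] = mu_sum / kept,
    _["mu_var"] = mu_sq / kept - (mu_sum / kept) * (mu_sum / kept),
    _["beta"] = beta_mean,
    _["beta_var"] = beta_var,
    _["inclusion"] = incl,
    _["sigma2_beta"] = sb2_mean,
    _["u"] = u_mean,
    _["sigma2_e"] = se2_sum / kept,
    _["sigma2_u"] = poly ? su2_sum / kept : NA_REAL,
    _["batch_means"] = List::create(_["mu"] = bm_mu, _["beta"] = bm_beta,
                                    _["gamma"] = bm_gamma, _["u"] = bm_u),
    _["trace"] = trace,
    _["n_samples"] = kept,
    _["max_resid_dev"] = max_resid_dev);
}
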