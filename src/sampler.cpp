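#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Beta(mu*phi, (1-mu)*phi) log density of one trial, with the mean formed
// by interpolating between the initial and social rating either on the
// logit scale (link 0) or the raw unit scale (link 1).
static inline double trial_logdens(double li, double ls, double iu, double su,
                                   double ly, double l1y,
                                   double s, double phi, int link) {
  double mu;
  if (link == 0) {
    double eta = li + s * (ls - li);
    mu = 1.0 / (1.0 + std::exp(-eta));
  } else {
    mu = iu + s * (su - iu);
  }
  const double eps = 1e-12;
  if (mu < eps) mu = eps;
  if (mu > 1.0 - eps) mu = 1.0 - eps;
  double a = mu * phi, b = (1.0 - mu) * phi;
  double v = R::lgammafn(phi) - R::lgammafn(a) - R::lgammafn(b)
    + (a - 1.0) * ly + (b - 1.0) * l1y;
  if (!std::isfinite(v)) return -INFINITY;
  return v;
}

// Adaptive random-walk Metropolis-within-Gibbs for the social-influence
// model. Parameter blocks: beta[c] (condition effects), u[j] (participant
// random effects; absent when re_mode == 2), log sigma2 (RE variances;
// one, n_cond, or none) and log phi. Step sizes adapt toward ~0.44
// acceptance during burn-in only, so the post-burn-in chain satisfies
// detailed balance.
// [[Rcpp::export]]
List mwg_sampler(NumericVector li, NumericVector ls,
                 NumericVector iu, NumericVector su,
                 NumericVector ly, NumericVector l1y,
                 IntegerVector cond, IntegerVector pid,
                 int n_cond, int n_part,
                 int link, int re_mode,   // re: 0 shared, 1 per-cond, 2 none
                 double beta_sd, double re_rate, double phi_rate,
                 int n_iter, int burnin, int thin,
                 NumericVector beta0, NumericVector u0,
                 NumericVector log_sigma2_0, double log_phi0) {
  const int N = li.size();
  const int n_u = (re_mode == 0) ? n_part : (re_mode == 1 ? n_part * n_cond : 0);
  const int n_s2 = (re_mode == 0) ? 1 : (re_mode == 1 ? n_cond : 0);

  std::vector<double> beta(beta0.begin(), beta0.end());
  std::vector<double> u(n_u, 0.0);
  for (int j = 0; j < n_u; ++j) u[j] = u0[j];
  std::vector<double> log_s2(n_s2, 0.0);
  for (int j = 0; j < n_s2; ++j) log_s2[j] = log_sigma2_0[j];
  double log_phi = log_phi0;
  double phi = std::exp(log_phi);

  // trial index lists per condition and per random-effect entry
  std::vector< std::vector<int> > idx_c(n_cond), idx_u(std::max(n_u, 1));
  for (int i = 0; i < N; ++i) {
    idx_c[cond[i]].push_back(i);
    if (re_mode == 0) idx_u[pid[i]].push_back(i);
    else if (re_mode == 1) idx_u[pid[i] * n_cond + cond[i]].push_back(i);
  }

  auto s_of = [&](int i) -> double {
    double s = beta[cond[i]];
    if (re_mode == 0) s += u[pid[i]];
    else if (re_mode == 1) s += u[pid[i] * n_cond + cond[i]];
    return s;
  };

  std::vector<double> dens(N);
  for (int i = 0; i < N; ++i)
    dens[i] = trial_logdens(li[i], ls[i], iu[i], su[i], ly[i], l1y[i],
                            s_of(i), phi, link);

  const int n_blocks = n_cond + n_u + n_s2 + 1;
  std::vector<double> step(n_blocks, 0.2);
  std::vector<int> acc_win(n_blocks, 0), acc_tot(n_blocks, 0);
  const int win = 50;

  int n_keep = 0;
  for (int t = burnin + 1; t <= n_iter; ++t)
    if ((t - burnin) % thin == 0) ++n_keep;
  const int n_par = n_cond + n_u + n_s2 + 1;
  NumericMatrix draws(n_keep, n_par);

  std::vector<double> newdens(N);
  int keep_row = 0;

  for (int t = 1; t <= n_iter; ++t) {
    int blk = 0;

    // condition effects
    for (int c = 0; c < n_cond; ++c, ++blk) {
      double prop = beta[c] + step[blk] * norm_rand();
      double delta = R::dnorm(prop, 0.0, beta_sd, 1)
        - R::dnorm(beta[c], 0.0, beta_sd, 1);
      for (int k : idx_c[c]) {
        double s = prop;
        if (re_mode == 0) s += u[pid[k]];
        else if (re_mode == 1) s += u[pid[k] * n_cond + cond[k]];
        newdens[k] = trial_logdens(li[k], ls[k], iu[k], su[k], ly[k], l1y[k],
                                   s, phi, link);
        delta += newdens[k] - dens[k];
      }
      if (std::log(unif_rand()) < delta) {
        beta[c] = prop;
        for (int k : idx_c[c]) dens[k] = newdens[k];
        ++acc_win[blk]; ++acc_tot[blk];
      }
    }

    // participant random effects
    for (int j = 0; j < n_u; ++j, ++blk) {
      double s2 = std::exp(log_s2[(re_mode == 0) ? 0 : (j % n_cond)]);
      double sd = std::sqrt(s2);
      double prop = u[j] + step[blk] * norm_rand();
      double delta = R::dnorm(prop, 0.0, sd, 1) - R::dnorm(u[j], 0.0, sd, 1);
      double db = prop - u[j];
      for (int k : idx_u[j]) {
        newdens[k] = trial_logdens(li[k], ls[k], iu[k], su[k], ly[k], l1y[k],
                                   s_of(k) + db, phi, link);
        delta += newdens[k] - dens[k];
      }
      if (std::log(unif_rand()) < delta) {
        u[j] = prop;
        for (int k : idx_u[j]) dens[k] = newdens[k];
        ++acc_win[blk]; ++acc_tot[blk];
      }
    }

    // RE variances: conjugate-free log-scale random walk; the likelihood
    // does not involve sigma2, only the u prior and the Exp(1) hyperprior.
    for (int v = 0; v < n_s2; ++v, ++blk) {
      double prop = log_s2[v] + step[blk] * norm_rand();
      double s2_old = std::exp(log_s2[v]), s2_new = std::exp(prop);
      double sum_sq = 0.0; int cnt = 0;
      for (int j = 0; j < n_u; ++j) {
        if (re_mode == 1 && (j % n_cond) != v) continue;
        sum_sq += u[j] * u[j]; ++cnt;
      }
      double delta =
        (-0.5 * cnt * std::log(s2_new) - 0.5 * sum_sq / s2_new)
        - (-0.5 * cnt * std::log(s2_old) - 0.5 * sum_sq / s2_old)
        - re_rate * (s2_new - s2_old)     // Exp(rate) prior on sigma2
        + (prop - log_s2[v]);             // Jacobian of the log transform
      if (std::log(unif_rand()) < delta) {
        log_s2[v] = prop;
        ++acc_win[blk]; ++acc_tot[blk];
      }
    }

    // precision phi
    {
      double prop_lp = log_phi + step[blk] * norm_rand();
      double prop_phi = std::exp(prop_lp);
      double delta = -phi_rate * (prop_phi - phi) + (prop_lp - log_phi);
      for (int i = 0; i < N; ++i) {
        newdens[i] = trial_logdens(li[i], ls[i], iu[i], su[i], ly[i], l1y[i],
                                   s_of(i), prop_phi, link);
        delta += newdens[i] - dens[i];
      }
      if (std::log(unif_rand()) < delta) {
        log_phi = prop_lp; phi = prop_phi;
        dens = newdens;
        ++acc_win[blk]; ++acc_tot[blk];
      }
      ++blk;
    }

    // step-size adaptation, burn-in only
    if (t <= burnin && t % win == 0) {
      for (int b = 0; b < n_blocks; ++b) {
        double rate = acc_win[b] / double(win);
        step[b] *= std::exp(rate > 0.44 ? 0.15 : -0.15);
        if (step[b] < 1e-4) step[b] = 1e-4;
        if (step[b] > 10.0) step[b] = 10.0;
        acc_win[b] = 0;
      }
    }

    if (t > burnin && (t - burnin) % thin == 0) {
      int col = 0;
      for (int c = 0; c < n_cond; ++c) draws(keep_row, col++) = beta[c];
      for (int j = 0; j < n_u; ++j) draws(keep_row, col++) = u[j];
      for (int v = 0; v < n_s2; ++v)
        draws(keep_row, col++) = std::exp(log_s2[v]);
      draws(keep_row, col++) = phi;
      ++keep_row;
    }
  }

  NumericVector acc(n_blocks);
  for (int b = 0; b < n_blocks; ++b) acc[b] = acc_tot[b] / double(n_iter);
  return List::create(_["draws"] = draws, _["accept"] = acc);
}
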