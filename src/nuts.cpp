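// No-U-Turn sampler for the hierarchical double-exponential
// age-performance model, with analytic log-posterior gradients.
//
// Parameter vector layout (dimension 9 + 4N, N = number of individuals):
//   [0..3]        a, log b, c, log d          (population fixed effects)
//   [4 .. 4+N)    z_a   (non-centered offsets, standard-normal prior)
//   [4+N .. )     z_b
//   [4+2N .. )    z_c
//   [4+3N .. )    z_d
//   [4+4N .. +4)  log tau_a..d                (random-effect scales)
//   [8+4N]        log sigma                   (residual scale)
//
// Effective individual parameters:
//   A_i = a + tau_a z_a[i]
//   B_i = exp(log b + tau_b z_b[i])     (positivity via log scale)
//   C_i = c + tau_c z_c[i]
//   D_i = exp(log d + tau_d z_d[i])
// Likelihood: y_m ~ Normal(A_i e^{-B_i t_m} + C_i e^{D_i t_m}, sigma).
// Priors: Normal(prior_mean, prior_scale) on (a, log b, c, log d);
// z ~ N(0,1); half-Normal on tau and sigma (sampled on log scale with
// Jacobian terms).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct ModelData {
  const double *y, *t;
  const int *idx;     // 0-based individual index per record
  int M, N;
  double pm[4], ps[4];  // prior mean/scale for (a, log b, c, log d)
  double tau_scale, sigma_scale;
};

static double logp_grad(const ModelData &D, const std::vector<double> &th,
                        std::vector<double> &g) {
  const int N = D.N;
  const int off_za = 4, off_zb = 4 + N, off_zc = 4 + 2 * N, off_zd = 4 + 3 * N;
  const int off_lt = 4 + 4 * N, off_ls = 8 + 4 * N;
  const int dim = 9 + 4 * N;
  std::fill(g.begin(), g.end(), 0.0);

  const double a = th[0], lb = th[1], c = th[2], ld = th[3];
  const double tau_a = std::exp(th[off_lt + 0]);
  const double tau_b = std::exp(th[off_lt + 1]);
  const double tau_c = std::exp(th[off_lt + 2]);
  const double tau_d = std::exp(th[off_lt + 3]);
  const double sigma = std::exp(th[off_ls]);
  const double inv_s2 = 1.0 / (sigma * sigma);

  double lp = 0.0;
  double g_ls_lik = 0.0;

  for (int m = 0; m < D.M; ++m) {
    const int i = D.idx[m];
    const double za = th[off_za + i], zb = th[off_zb + i];
    const double zc = th[off_zc + i], zd = th[off_zd + i];
    const double A = a + tau_a * za;
    const double B = std::exp(lb + tau_b * zb);
    const double C = c + tau_c * zc;
    const double Dd = std::exp(ld + tau_d * zd);
    const double tm = D.t[m];
    const double e1 = std::exp(-B * tm), e2 = std::exp(Dd * tm);
    const double mu = A * e1 + C * e2;
    const double r = D.y[m] - mu;
    lp += -0.5 * r * r * inv_s2;
    g_ls_lik += r * r * inv_s2 - 1.0;

    const double w = r * inv_s2;       // dlp/dmu
    const double dmu_dB = -A * tm * e1;
    const double dmu_dD = C * tm * e2;
    g[0] += w * e1;                    // a
    g[1] += w * dmu_dB * B;            // log b
    g[2] += w * e2;                    // c
    g[3] += w * dmu_dD * Dd;           // log d
    g[off_za + i] += w * e1 * tau_a;
    g[off_zb + i] += w * dmu_dB * B * tau_b;
    g[off_zc + i] += w * e2 * tau_c;
    g[off_zd + i] += w * dmu_dD * Dd * tau_d;
    g[off_lt + 0] += w * e1 * za * tau_a;
    g[off_lt + 1] += w * dmu_dB * B * zb * tau_b;
    g[off_lt + 2] += w * e2 * zc * tau_c;
    g[off_lt + 3] += w * dmu_dD * Dd * zd * tau_d;
  }
  lp += -double(D.M) * std::log(sigma);
  g[off_ls] += g_ls_lik;               // includes -M from d(-M log sigma)

  // priors on fixed effects (sampling scale)
  for (int j = 0; j < 4; ++j) {
    const double z = (th[j] - D.pm[j]) / D.ps[j];
    lp += -0.5 * z * z;
    g[j] += -z / D.ps[j];
  }
  // standard-normal priors on non-centered offsets
  for (int k = 4; k < 4 + 4 * N; ++k) {
    lp += -0.5 * th[k] * th[k];
    g[k] += -th[k];
  }
  // half-Normal(tau_scale) on tau, log-scale Jacobian
  const double taus[4] = {tau_a, tau_b, tau_c, tau_d};
  for (int j = 0; j < 4; ++j) {
    const double ts = D.tau_scale;
    lp += -0.5 * taus[j] * taus[j] / (ts * ts) + th[off_lt + j];
    g[off_lt + j] += -taus[j] * taus[j] / (ts * ts) + 1.0;
  }
  // half-Normal(sigma_scale) on sigma, log-scale Jacobian
  {
    const double ss = D.sigma_scale;
    lp += -0.5 * sigma * sigma / (ss * ss) + th[off_ls];
    g[off_ls] += -sigma * sigma / (ss * ss) + 1.0;
  }
  (void)dim;
  return lp;
}

// [[Rcpp::export(name = ".logpost_grad")]]
List logpost_grad(NumericVector theta, NumericVector y, NumericVector t,
                  IntegerVector idx, int n_ind,
                  NumericVector prior_mean, NumericVector prior_scale,
                  double tau_scale, double sigma_scale) {
  ModelData D;
  D.y = y.begin(); D.t = t.begin(); D.idx = idx.begin();
  D.M = y.size(); D.N = n_ind;
  for (int j = 0; j < 4; ++j) { D.pm[j] = prior_mean[j]; D.ps[j] = prior_scale[j]; }
  D.tau_scale = tau_scale; D.sigma_scale = sigma_scale;
  std::vector<double> th(theta.begin(), theta.end()), g(theta.size());
  double lp = logp_grad(D, th, g);
  return List::create(_["lp"] = lp, _["grad"] = NumericVector(g.begin(), g.end()));
}

// ---------- NUTS machinery (Hoffman & Gelman 2014, Algorithm 6) ----------

struct Sampler {
  ModelData D;
  int dim;
  std::vector<double> inv_mass;   // diagonal
  double eps;
  int max_depth;
  int n_divergent;

  double joint(const std::vector<double> &th, const std::vector<double> &p,
               double lp) const {
    double k = 0.0;
    for (int j = 0; j < dim; ++j) k += 0.5 * p[j] * p[j] * inv_mass[j];
    return lp - k;
  }

  // one leapfrog step; th/p updated in place; returns lp at new th
  double leapfrog(std::vector<double> &th, std::vector<double> &p,
                  std::vector<double> &g, double dir) {
    const double e = dir * eps;
    for (int j = 0; j < dim; ++j) p[j] += 0.5 * e * g[j];
    for (int j = 0; j < dim; ++j) th[j] += e * p[j] * inv_mass[j];
    double lp = logp_grad(D, th, g);
    for (int j = 0; j < dim; ++j) p[j] += 0.5 * e * g[j];
    return lp;
  }
};

struct Tree {
  std::vector<double> th_minus, p_minus, g_minus;
  std::vector<double> th_plus, p_plus, g_plus;
  std::vector<double> th_prop;
  double lp_prop;
  int n_valid;
  bool ok;          // no U-turn, no divergence
  double sum_alpha; // for dual averaging
  int n_alpha;
};

static bool no_uturn(const Sampler &S, const std::vector<double> &th_minus,
                     const std::vector<double> &th_plus,
                     const std::vector<double> &p_minus,
                     const std::vector<double> &p_plus) {
  double s1 = 0.0, s2 = 0.0;
  for (int j = 0; j < S.dim; ++j) {
    const double dth = th_plus[j] - th_minus[j];
    s1 += dth * p_minus[j] * S.inv_mass[j];
    s2 += dth * p_plus[j] * S.inv_mass[j];
  }
  return s1 >= 0.0 && s2 >= 0.0;
}

static void build_tree(Sampler &S, std::vector<double> th,
                       std::vector<double> p, std::vector<double> g,
                       double log_u, double dir, int depth, double joint0,
                       Tree &out) {
  if (depth == 0) {
    const double lp = S.leapfrog(th, p, g, dir);
    const double j = S.joint(th, p, lp);
    out.th_minus = th; out.p_minus = p; out.g_minus = g;
    out.th_plus = th; out.p_plus = p; out.g_plus = g;
    out.th_prop = th; out.lp_prop = lp;
    out.n_valid = (log_u <= j - joint0) ? 1 : 0;
    const bool divergent = (j - joint0) < -1000.0 || !std::isfinite(j);
    if (divergent) S.n_divergent++;
    out.ok = !divergent;
    double a = std::exp(std::min(0.0, j - joint0));
    if (!std::isfinite(a)) a = 0.0;
    out.sum_alpha = a; out.n_alpha = 1;
    return;
  }
  build_tree(S, th, p, g, log_u, dir, depth - 1, joint0, out);
  if (!out.ok) return;
  Tree t2;
  if (dir < 0) {
    build_tree(S, out.th_minus, out.p_minus, out.g_minus, log_u, dir,
               depth - 1, joint0, t2);
    out.th_minus = t2.th_minus; out.p_minus = t2.p_minus; out.g_minus = t2.g_minus;
  } else {
    build_tree(S, out.th_plus, out.p_plus, out.g_plus, log_u, dir,
               depth - 1, joint0, t2);
    out.th_plus = t2.th_plus; out.p_plus = t2.p_plus; out.g_plus = t2.g_plus;
  }
  const int n_tot = out.n_valid + t2.n_valid;
  if (t2.n_valid > 0 && R::unif_rand() < double(t2.n_valid) / double(n_tot)) {
    out.th_prop = t2.th_prop; out.lp_prop = t2.lp_prop;
  }
  out.n_valid = n_tot;
  out.sum_alpha += t2.sum_alpha;
  out.n_alpha += t2.n_alpha;
  out.ok = t2.ok && no_uturn(S, out.th_minus, out.th_plus, out.p_minus,
                             out.p_plus);
}

// returns accept-stat for dual averaging; th/lp updated in place
static double nuts_transition(Sampler &S, std::vector<double> &th, double &lp,
                              int &depth_used) {
  const int dim = S.dim;
  std::vector<double> p(dim), g(dim);
  for (int j = 0; j < dim; ++j)
    p[j] = R::norm_rand() / std::sqrt(S.inv_mass[j]);
  logp_grad(S.D, th, g);
  const double joint0 = S.joint(th, p, lp);
  const double log_u = -R::exp_rand();   // log u ~ log Uniform(0, 1) + joint0 offset

  Tree tr;
  tr.th_minus = th; tr.p_minus = p; tr.g_minus = g;
  tr.th_plus = th; tr.p_plus = p; tr.g_plus = g;
  tr.th_prop = th; tr.lp_prop = lp;
  tr.n_valid = 1; tr.ok = true; tr.sum_alpha = 0.0; tr.n_alpha = 0;

  double sum_alpha = 0.0; int n_alpha = 0;
  int depth = 0;
  while (tr.ok && depth < S.max_depth) {
    const double dir = (R::unif_rand() < 0.5) ? -1.0 : 1.0;
    Tree t2;
    if (dir < 0) {
      build_tree(S, tr.th_minus, tr.p_minus, tr.g_minus, log_u, dir, depth,
                 joint0, t2);
      if (t2.ok) { tr.th_minus = t2.th_minus; tr.p_minus = t2.p_minus; tr.g_minus = t2.g_minus; }
    } else {
      build_tree(S, tr.th_plus, tr.p_plus, tr.g_plus, log_u, dir, depth,
                 joint0, t2);
      if (t2.ok) { tr.th_plus = t2.th_plus; tr.p_plus = t2.p_plus; tr.g_plus = t2.g_plus; }
    }
    sum_alpha += t2.sum_alpha; n_alpha += t2.n_alpha;
    if (t2.ok && t2.n_valid > 0 &&
        R::unif_rand() < double(t2.n_valid) / double(tr.n_valid)) {
      tr.th_prop = t2.th_prop; tr.lp_prop = t2.lp_prop;
    }
    tr.n_valid += t2.n_valid;
    if (!t2.ok) break;
    if (!no_uturn(S, tr.th_minus, tr.th_plus, tr.p_minus, tr.p_plus)) break;
    ++depth;
  }
  depth_used = depth;
  th = tr.th_prop; lp = tr.lp_prop;
  return n_alpha > 0 ? sum_alpha / double(n_alpha) : 0.0;
}

// [[Rcpp::export(name = ".nuts_chain")]]
List nuts_chain(NumericVector init, NumericVector y, NumericVector t,
                IntegerVector idx, int n_ind,
                NumericVector prior_mean, NumericVector prior_scale,
                double tau_scale, double sigma_scale,
                int n_warmup, int n_draws, double target_accept,
                int max_depth) {
  Sampler S;
  S.D.y = y.begin(); S.D.t = t.begin(); S.D.idx = idx.begin();
  S.D.M = y.size(); S.D.N = n_ind;
  for (int j = 0; j < 4; ++j) { S.D.pm[j] = prior_mean[j]; S.D.ps[j] = prior_scale[j]; }
  S.D.tau_scale = tau_scale; S.D.sigma_scale = sigma_scale;
  S.dim = init.size();
  S.inv_mass.assign(S.dim, 1.0);
  S.max_depth = max_depth;
  S.n_divergent = 0;

  std::vector<double> th(init.begin(), init.end()), g(S.dim);
  double lp = logp_grad(S.D, th, g);

  // crude reasonable initial step size: scale down until one leapfrog is stable
  S.eps = 0.1;
  {
    std::vector<double> p(S.dim), th2, g2;
    for (int j = 0; j < S.dim; ++j) p[j] = R::norm_rand();
    for (int tries = 0; tries < 40; ++tries) {
      th2 = th; g2 = g; std::vector<double> p2 = p;
      double lp2 = S.leapfrog(th2, p2, g2, 1.0);
      double dj = S.joint(th2, p2, lp2) - S.joint(th, p, lp);
      if (std::isfinite(dj) && std::fabs(dj) < 10.0) break;
      S.eps *= 0.5;
    }
  }

  // dual averaging state
  double mu = std::log(10.0 * S.eps), log_eps = std::log(S.eps),
         log_eps_bar = 0.0, h_bar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int adapt_count = 0;

  // mass-matrix estimation window (Welford)
  const int w1 = std::max(1, int(0.15 * n_warmup));
  const int w2 = std::max(w1 + 2, int(0.8 * n_warmup));
  std::vector<double> mean_acc(S.dim, 0.0), m2_acc(S.dim, 0.0);
  int n_acc = 0;

  NumericMatrix draws(n_draws, S.dim);
  IntegerVector treedepths(n_draws);
  double sum_accept = 0.0;
  int divergent_after_warmup_start; // divergences counted post-warmup only

  for (int it = 0; it < n_warmup + n_draws; ++it) {
    if (it == n_warmup) {
      S.eps = std::exp(log_eps_bar);
      S.n_divergent = 0;
    }
    int depth = 0;
    double alpha = nuts_transition(S, th, lp, depth);

    if (it < n_warmup) {
      // dual averaging
      adapt_count++;
      const double eta = 1.0 / (adapt_count + t0);
      h_bar = (1.0 - eta) * h_bar + eta * (target_accept - alpha);
      log_eps = mu - std::sqrt((double)adapt_count) / gamma * h_bar;
      const double xeta = std::pow((double)adapt_count, -kappa);
      log_eps_bar = xeta * log_eps + (1.0 - xeta) * log_eps_bar;
      S.eps = std::exp(log_eps);

      if (it >= w1 && it < w2) {
        n_acc++;
        for (int j = 0; j < S.dim; ++j) {
          const double d = th[j] - mean_acc[j];
          mean_acc[j] += d / n_acc;
          m2_acc[j] += d * (th[j] - mean_acc[j]);
        }
      }
      if (it == w2 - 1 && n_acc > 10) {
        for (int j = 0; j < S.dim; ++j) {
          double v = m2_acc[j] / (n_acc - 1);
          // shrink toward unit (Stan-style regularization)
          v = (double(n_acc) / (n_acc + 5.0)) * v + 1e-3 * (5.0 / (n_acc + 5.0));
          S.inv_mass[j] = std::max(v, 1e-8);
        }
        // restart step-size adaptation around current eps
        mu = std::log(10.0 * std::exp(log_eps));
        h_bar = 0.0; adapt_count = 0; log_eps_bar = std::log(std::exp(log_eps));
      }
    } else {
      const int k = it - n_warmup;
      for (int j = 0; j < S.dim; ++j) draws(k, j) = th[j];
      treedepths[k] = depth;
      sum_accept += alpha;
    }
  }
  (void)divergent_after_warmup_start;

  return List::create(_["draws"] = draws,
                      _["n_divergent"] = S.n_divergent,
                      _["step_size"] = S.eps,
                      _["mean_accept"] = sum_accept / std::max(1, n_draws),
                      _["treedepth"] = treedepths);
}
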