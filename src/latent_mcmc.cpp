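// Metropolis-within-Gibbs sampler for the two-state latent behavioural-response
// model. One block-level binary state z_t multiplies the log-scale enhancement;
// z_t ~ Bernoulli(p_phase[t]) with a conjugate Beta update; the lambda (and
// observation-sd) parameters move by adaptive random-walk Metropolis inside
// their uniform prior bounds, with the adaptation frozen after burn-in.
//
// Families: 0 = poisson counts, 1 = zero-truncated-normal counts,
// 2 = switching OU block-velocity transitions (shared indicator for the
// persistence and variation parameters).
//
// Per-iteration cost is O(n_blocks) arithmetic: per-block log-likelihoods under
// both states are cached and refreshed only when a parameter move is accepted,
// and parameter updates use sufficient statistics accumulated per state.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct SuffStats {
  // count families (per state 0/1, observed blocks only)
  double n[2] = {0, 0}, sy[2] = {0, 0}, sy2[2] = {0, 0};
  // movement family: transition blocks per state
  double nt[2] = {0, 0}, scc[2] = {0, 0}, scp[2] = {0, 0}, spp[2] = {0, 0};
  // movement family: stationary (gap-start) blocks per state
  double ns[2] = {0, 0}, s2[2] = {0, 0};
};

// log-likelihood (up to z-independent constants) given sufficient statistics
double loglik_from_stats(int family, const std::vector<double>& th,
                         const SuffStats& st) {
  if (family == 0) {
    double ll = 0.0;
    for (int g = 0; g < 2; ++g) {
      double eta = th[0] + (g ? th[1] : 0.0);
      ll += st.sy[g] * eta - st.n[g] * std::exp(eta);
    }
    return ll;
  }
  if (family == 1) {
    double sd = th[2];
    double ll = 0.0;
    for (int g = 0; g < 2; ++g) {
      if (st.n[g] == 0) continue;
      double m = std::exp(th[0] + (g ? th[1] : 0.0));
      double ss = st.sy2[g] - 2.0 * m * st.sy[g] + st.n[g] * m * m;
      ll += -st.n[g] * std::log(sd) - ss / (2.0 * sd * sd)
            - st.n[g] * R::pnorm(m / sd, 0.0, 1.0, 1, 1);
    }
    return ll;
  }
  // movement
  double ll = 0.0;
  for (int g = 0; g < 2; ++g) {
    double beta = std::exp(th[0] + (g ? th[1] : 0.0));
    double sig  = std::exp(th[2] + (g ? th[3] : 0.0));
    double tau2 = sig * sig / (2.0 * beta);
    double rho  = std::exp(-beta * th[4]);           // th[4] carries delta
    double v    = tau2 * (-std::expm1(-2.0 * beta * th[4]));
    if (st.nt[g] > 0) {
      double ss = st.scc[g] - 2.0 * rho * st.scp[g] + rho * rho * st.spp[g];
      ll += -st.nt[g] * std::log(v) - ss / (2.0 * v);
    }
    if (st.ns[g] > 0)
      ll += -st.ns[g] * std::log(tau2) - st.s2[g] / (2.0 * tau2);
  }
  return ll;
}

} // namespace

// [[Rcpp::export(name = ".latent_mcmc_cpp")]]
List latent_mcmc_cpp(int family,
                     NumericVector y, LogicalVector obs,
                     NumericVector vcx, NumericVector vcy,
                     NumericVector vpx, NumericVector vpy,
                     IntegerVector ltype,
                     IntegerVector phase,
                     double delta,
                     int n_iter, int n_burn,
                     NumericVector init_theta, NumericVector init_p,
                     NumericVector lo, NumericVector hi,
                     NumericVector prop_sd_init) {
  const int n = phase.size();
  const int n_th = init_theta.size();
  std::vector<double> th(init_theta.begin(), init_theta.end());
  // movement family: smuggle delta as an extra fixed slot past the free params
  std::vector<double> th_ext = th;
  if (family == 2) th_ext.push_back(delta);

  double p[3] = {init_p[0], init_p[1], init_p[2]};
  std::vector<int> z(n, 0);
  std::vector<double> ll0(n, 0.0), ll1(n, 0.0);
  std::vector<bool> has_data(n, false);
  for (int t = 0; t < n; ++t)
    has_data[t] = (family == 2) ? (ltype[t] > 0) : (bool)obs[t];

  // Update moves: one per free parameter, plus joint moves along the weakly
  // identified directions. Count families: (lambda0, -lambda1) keeps the
  // enhanced mean fixed while the baseline moves. Movement family: the block
  // likelihood pins the stationary variance tau^2 = sigma^2/(2 beta) much
  // harder than rho, so (2 d_beta, d_sigma) ridge moves (per state) are
  // needed for the chains to traverse the beta/sigma ridge.
  std::vector<std::vector<double>> dirs;
  for (int j = 0; j < n_th; ++j) {
    std::vector<double> d(n_th, 0.0);
    d[j] = 1.0;
    dirs.push_back(d);
  }
  if (family == 0 || family == 1) {
    std::vector<double> d(n_th, 0.0);
    d[0] = 1.0; d[1] = -1.0;
    dirs.push_back(d);
  } else if (family == 2) {
    std::vector<double> d1(n_th, 0.0), d2(n_th, 0.0);
    d1[0] = 2.0; d1[2] = 1.0;   // baseline (beta, sigma) ridge
    d2[1] = 2.0; d2[3] = 1.0;   // enhancement ridge
    dirs.push_back(d1);
    dirs.push_back(d2);
  }
  const int n_upd = (int)dirs.size();
  std::vector<double> psd(n_upd, prop_sd_init[0]);
  for (int j = 0; j < n_th; ++j) psd[j] = prop_sd_init[j];
  std::vector<int> acc(n_upd, 0), acc_batch(n_upd, 0);
  int batch = 0, batch_n = 0;

  // refresh cached per-block log-likelihoods under z = 0 and z = 1
  auto refresh_cache = [&]() {
    if (family == 0) {
      double e0 = th[0], e1 = th[0] + th[1];
      double x0 = std::exp(e0), x1 = std::exp(e1);
      for (int t = 0; t < n; ++t) {
        if (!has_data[t]) continue;
        ll0[t] = y[t] * e0 - x0;
        ll1[t] = y[t] * e1 - x1;
      }
    } else if (family == 1) {
      double sd = th[2];
      double m0 = std::exp(th[0]), m1 = std::exp(th[0] + th[1]);
      double c0 = -std::log(sd) - R::pnorm(m0 / sd, 0.0, 1.0, 1, 1);
      double c1 = -std::log(sd) - R::pnorm(m1 / sd, 0.0, 1.0, 1, 1);
      double is2 = 1.0 / (2.0 * sd * sd);
      for (int t = 0; t < n; ++t) {
        if (!has_data[t]) continue;
        double d0 = y[t] - m0, d1 = y[t] - m1;
        ll0[t] = c0 - d0 * d0 * is2;
        ll1[t] = c1 - d1 * d1 * is2;
      }
    } else {
      double beta[2], tau2[2], rho[2], v[2], lv[2], lt[2];
      for (int g = 0; g < 2; ++g) {
        beta[g] = std::exp(th[0] + (g ? th[1] : 0.0));
        double sig = std::exp(th[2] + (g ? th[3] : 0.0));
        tau2[g] = sig * sig / (2.0 * beta[g]);
        rho[g] = std::exp(-beta[g] * delta);
        v[g] = tau2[g] * (-std::expm1(-2.0 * beta[g] * delta));
        lv[g] = std::log(v[g]);
        lt[g] = std::log(tau2[g]);
      }
      for (int t = 0; t < n; ++t) {
        if (ltype[t] == 1) {
          for (int g = 0; g < 2; ++g) {
            double dx = vcx[t] - rho[g] * vpx[t], dy = vcy[t] - rho[g] * vpy[t];
            double l = -lv[g] - (dx * dx + dy * dy) / (2.0 * v[g]);
            (g ? ll1[t] : ll0[t]) = l;
          }
        } else if (ltype[t] == 2) {
          double s2 = vcx[t] * vcx[t] + vcy[t] * vcy[t];
          ll0[t] = -lt[0] - s2 / (2.0 * tau2[0]);
          ll1[t] = -lt[1] - s2 / (2.0 * tau2[1]);
        }
      }
    }
  };

  auto accumulate_stats = [&](SuffStats& st) {
    st = SuffStats();
    if (family != 2) {
      for (int t = 0; t < n; ++t) {
        if (!has_data[t]) continue;
        int g = z[t];
        st.n[g] += 1.0; st.sy[g] += y[t]; st.sy2[g] += y[t] * y[t];
      }
    } else {
      for (int t = 0; t < n; ++t) {
        int g = z[t];
        if (ltype[t] == 1) {
          st.nt[g] += 1.0;
          st.scc[g] += vcx[t] * vcx[t] + vcy[t] * vcy[t];
          st.scp[g] += vcx[t] * vpx[t] + vcy[t] * vpy[t];
          st.spp[g] += vpx[t] * vpx[t] + vpy[t] * vpy[t];
        } else if (ltype[t] == 2) {
          st.ns[g] += 1.0;
          st.s2[g] += vcx[t] * vcx[t] + vcy[t] * vcy[t];
        }
      }
    }
  };

  refresh_cache();

  const int n_keep = n_iter;
  const int n_col = n_th + 3;
  NumericMatrix draws(n_keep, n_col);

  RNGScope scope;
  SuffStats st;

  for (int it = 0; it < n_burn + n_iter; ++it) {
    // --- Gibbs: latent states ---
    for (int t = 0; t < n; ++t) {
      double pp = p[phase[t]];
      if (!has_data[t]) {
        z[t] = (unif_rand() < pp) ? 1 : 0;
        continue;
      }
      double a = std::log(pp) + ll1[t];
      double b = std::log1p(-pp) + ll0[t];
      double m = (a > b) ? a : b;
      double w1 = std::exp(a - m), w0 = std::exp(b - m);
      z[t] = (unif_rand() * (w0 + w1) < w1) ? 1 : 0;
    }

    // --- Gibbs: phase probabilities, conjugate Beta(1 + n1, 1 + n0) ---
    {
      double n1[3] = {0, 0, 0}, n0[3] = {0, 0, 0};
      for (int t = 0; t < n; ++t) {
        if (z[t]) n1[phase[t]] += 1.0; else n0[phase[t]] += 1.0;
      }
      for (int k = 0; k < 3; ++k)
        p[k] = R::rbeta(1.0 + n1[k], 1.0 + n0[k]);
    }

    // --- Metropolis: lambda / obs-sd parameters ---
    accumulate_stats(st);
    if (family == 2) { for (int j = 0; j < n_th; ++j) th_ext[j] = th[j]; }
    double cur_ll = loglik_from_stats(family, (family == 2) ? th_ext : th, st);
    bool any_acc = false;
    for (int j = 0; j < n_upd; ++j) {
      double eps = psd[j] * norm_rand();
      bool ok = true;
      std::vector<double> thp = (family == 2) ? th_ext : th;
      for (int k = 0; k < n_th; ++k) {
        if (dirs[j][k] == 0.0) continue;
        thp[k] = th[k] + dirs[j][k] * eps;
        if (thp[k] < lo[k] || thp[k] > hi[k]) { ok = false; break; }
      }
      if (!ok) continue;                       // flat prior: reject outside
      double new_ll = loglik_from_stats(family, thp, st);
      if (std::log(unif_rand()) < new_ll - cur_ll) {
        for (int k = 0; k < n_th; ++k) {
          th[k] = thp[k];
          if (family == 2) th_ext[k] = thp[k];
        }
        cur_ll = new_ll;
        acc[j]++; acc_batch[j]++;
        any_acc = true;
      }
    }
    if (any_acc) refresh_cache();

    // --- adapt proposal scales during burn-in only ---
    if (it < n_burn) {
      if (++batch_n == 50) {
        ++batch;
        double step = std::min(0.1, 1.0 / std::sqrt((double)batch));
        for (int j = 0; j < n_upd; ++j) {
          double rate = acc_batch[j] / 50.0;
          psd[j] *= std::exp((rate > 0.44 ? 1.0 : -1.0) * step);
          acc_batch[j] = 0;
        }
        batch_n = 0;
      }
    }

    if (it >= n_burn) {
      int r = it - n_burn;
      for (int j = 0; j < n_th; ++j) draws(r, j) = th[j];
      for (int k = 0; k < 3; ++k) draws(r, n_th + k) = p[k];
    }
  }

  NumericVector acc_rate(n_upd);
  for (int j = 0; j < n_upd; ++j)
    acc_rate[j] = acc[j] / (double)(n_burn + n_iter);

  return List::create(_["draws"] = draws,
                      _["accept_rate"] = acc_rate,
                      _["prop_sd"] = NumericVector(psd.begin(), psd.end()));
}
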