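// Two-boundary Wiener diffusion: first-passage-time density (small- and
// large-time series), exact absorption probabilities, an inverse-CDF grid
// sampler, and a brute-force Euler path simulator kept as an independent
// reference for the series code.

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Density of the normalised first-passage time at the LOWER boundary for a
// zero-drift, unit-boundary diffusion started at relative position w, as a
// function of u = tau / a^2.  Two series expansions; the number of terms
// needed to reach absolute tolerance eps follows the standard bounds, and
// the cheaper expansion is selected (small-time wins at small u, large-time
// at large u).
// ---------------------------------------------------------------------------

static double ft_small(double u, double w, int K) {
  double s = 0.0;
  for (int k = -K; k <= K; ++k) {
    double x = w + 2.0 * k;
    s += x * std::exp(-x * x / (2.0 * u));
  }
  return s / std::sqrt(2.0 * M_PI * u * u * u);
}

static double ft_large(double u, double w, int K) {
  double s = 0.0;
  for (int k = 1; k <= K; ++k) {
    s += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
  }
  return M_PI * s;
}

// force: 0 = pick cheaper expansion, 1 = small-time, 2 = large-time
static double ft_density(double u, double w, double eps, int force) {
  if (!(u > 0.0)) return 0.0;
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }
  bool use_small = (force == 1) || (force == 0 && ks < kl);
  double f = use_small ? ft_small(u, w, (int)std::ceil(ks))
                       : ft_large(u, w, (int)std::ceil(kl));
  return f;
}

// log defective FPT density at time t and the given boundary.
// upper-boundary density comes from the lower-boundary form under the
// reflection (v, w) -> (-v, 1 - w).  t <= t0 has zero density.
static double wiener_logpdf_one(double t, int upper, double v, double a,
                                double w, double t0, double eps) {
  double tau = t - t0;
  if (!(tau > 0.0)) return R_NegInf;
  double vv = v, ww = w;
  if (upper) { vv = -v; ww = 1.0 - w; }
  double u = tau / (a * a);
  double f = ft_density(u, ww, eps, 0);
  if (!(f > 0.0)) return R_NegInf;  // series truncation can graze zero
  return -vv * a * ww - vv * vv * tau / 2.0 - 2.0 * std::log(a) + std::log(f);
}

// [[Rcpp::export]]
NumericVector cpp_wiener_logpdf(NumericVector t, IntegerVector upper, double v,
                                double a, double w, double t0, double eps,
                                int force) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (force == 0) {
      out[i] = wiener_logpdf_one(t[i], upper[i], v, a, w, t0, eps);
    } else {
      double tau = t[i] - t0;
      if (!(tau > 0.0)) { out[i] = R_NegInf; continue; }
      double vv = v, ww = w;
      if (upper[i]) { vv = -v; ww = 1.0 - w; }
      double f = ft_density(tau / (a * a), ww, eps, force);
      out[i] = (f > 0.0)
        ? -vv * a * ww - vv * vv * tau / 2.0 - 2.0 * std::log(a) + std::log(f)
        : R_NegInf;
    }
  }
  return out;
}

// [[Rcpp::export]]
double cpp_upper_prob(double v, double a, double w) {
  double x = -2.0 * v * a;          // s = 1 scaling convention
  if (std::fabs(x) < 1e-10) return w;
  if (x > 500.0)  return std::exp(x * (w - 1.0));
  if (x < -500.0) return -std::expm1(x * w);
  return std::expm1(x * w) / std::expm1(x);
}

// ---------------------------------------------------------------------------
// Inverse-CDF sampler on a quadratically spaced time grid.  The defective
// density at the realised boundary is integrated by the trapezoid rule out
// to a point where the surviving mass is negligible (the slowest decay rate
// is pi^2/(2 a^2) + v^2/2), then a uniform draw is inverted by binary
// search with linear interpolation.
// ---------------------------------------------------------------------------

struct FptGrid {
  std::vector<double> tau, cdf;
  double total;
};

static void build_grid(FptGrid &g, double vv, double ww, double a, int n,
                       double eps) {
  double lambda = M_PI * M_PI / (2.0 * a * a) + vv * vv / 2.0;
  double tmax = 25.0 / lambda;
  g.tau.assign(n + 1, 0.0);
  g.cdf.assign(n + 1, 0.0);
  double prev_f = 0.0, prev_t = 0.0, c = 0.0;
  for (int j = 1; j <= n; ++j) {
    double fr = (double)j / n;
    double tau = tmax * fr * fr;
    double f = ft_density(tau / (a * a), ww, eps, 0);
    double dens = (f > 0.0)
      ? std::exp(-vv * a * ww - vv * vv * tau / 2.0) * f / (a * a)
      : 0.0;
    c += 0.5 * (dens + prev_f) * (tau - prev_t);
    g.tau[j] = tau;
    g.cdf[j] = c;
    prev_f = dens;
    prev_t = tau;
  }
  g.total = c;
}

static double draw_from_grid(const FptGrid &g) {
  double u = unif_rand() * g.total;
  int lo = 0, hi = (int)g.cdf.size() - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (g.cdf[mid] < u) lo = mid; else hi = mid;
  }
  double c0 = g.cdf[lo], c1 = g.cdf[hi];
  double frac = (c1 > c0) ? (u - c0) / (c1 - c0) : 0.5;
  return g.tau[lo] + frac * (g.tau[hi] - g.tau[lo]);
}

// n joint draws (boundary, t) at fixed parameters; grids built once.
// [[Rcpp::export]]
List cpp_sample_fpt(int n, double v, double a, double w, double t0, int ngrid,
                    double eps) {
  double pu = cpp_upper_prob(v, a, w);
  FptGrid gu, gl;
  build_grid(gu, -v, 1.0 - w, a, ngrid, eps);
  build_grid(gl,  v,       w, a, ngrid, eps);
  IntegerVector resp(n);
  NumericVector t(n);
  for (int i = 0; i < n; ++i) {
    bool up = unif_rand() < pu;
    resp[i] = up ? 1 : 0;
    t[i] = t0 + draw_from_grid(up ? gu : gl);
  }
  return List::create(_["response"] = resp, _["rt"] = t);
}

// one trial; policy: 0 free (diffusion), 1 force upper, 2 force lower
static void sample_one(double v, double a, double w, double t0, int ngrid,
                       double eps, int policy, int &resp, double &t) {
  int up;
  if (policy == 1) up = 1;
  else if (policy == 2) up = 0;
  else up = (unif_rand() < cpp_upper_prob(v, a, w)) ? 1 : 0;
  FptGrid g;
  build_grid(g, up ? -v : v, up ? 1.0 - w : w, a, ngrid, eps);
  resp = up;
  t = t0 + draw_from_grid(g);
}

// ---------------------------------------------------------------------------
// PST session: drift from the running Q-values, choice/RT from the diffusion,
// Bernoulli feedback, delta-rule update of the chosen option, blockwise
// accuracy-criterion termination.  Pair and cell indices are 0-based.
// ---------------------------------------------------------------------------

// schedule: 0 = i.i.d. Bernoulli feedback; 1 = exact-proportion shuffled
// outcomes per pair within each block
// [[Rcpp::export]]
List cpp_simulate_session(NumericVector p_reward, NumericVector criterion,
                          IntegerVector cell_of_pair, NumericVector eta,
                          NumericVector v_sc, NumericVector a_cell, double t0,
                          double w, int block_length, int max_blocks,
                          int policy, int ngrid, double eps, int schedule) {
  int P = p_reward.size();
  int reps = block_length / P;
  std::vector<double> qt(P, 0.5), qo(P, 0.5);
  std::vector<int> pair_out, block_out, resp_out, fb_out;
  std::vector<double> rt_out;
  std::vector<int> seq(block_length);
  for (int b = 1; b <= max_blocks; ++b) {
    int idx = 0;
    for (int p = 0; p < P; ++p)
      for (int r = 0; r < reps; ++r) seq[idx++] = p;
    for (int i = block_length - 1; i > 0; --i) {  // Fisher-Yates
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(seq[i], seq[j]);
    }
    // exact-proportion option: each pair gets a shuffled vector of
    // "target is correct" outcomes with round(p * reps) ones per block
    std::vector<std::vector<int> > sched(P);
    std::vector<int> sched_pos(P, 0);
    if (schedule == 1) {
      for (int p = 0; p < P; ++p) {
        int n1 = (int)(p_reward[p] * reps + 0.5);
        sched[p].assign(reps, 0);
        for (int r = 0; r < n1; ++r) sched[p][r] = 1;
        for (int i = reps - 1; i > 0; --i) {
          int j = (int)(unif_rand() * (i + 1));
          if (j > i) j = i;
          std::swap(sched[p][i], sched[p][j]);
        }
      }
    }
    std::vector<int> n_pair(P, 0), n_correct(P, 0);
    for (int i = 0; i < block_length; ++i) {
      int p = seq[i];
      int c = cell_of_pair[p];
      double drift = v_sc[c] * (qt[p] - qo[p]);
      int resp; double t;
      sample_one(drift, a_cell[c], w, t0, ngrid, eps, policy, resp, t);
      int fb;
      if (schedule == 1) {
        int target_correct = sched[p][sched_pos[p]++];
        fb = resp ? target_correct : 1 - target_correct;
      } else {
        double pr = resp ? p_reward[p] : 1.0 - p_reward[p];
        fb = (unif_rand() < pr) ? 1 : 0;
      }
      if (resp) qt[p] += eta[c] * (fb - qt[p]);
      else      qo[p] += eta[c] * (fb - qo[p]);
      pair_out.push_back(p);
      block_out.push_back(b);
      resp_out.push_back(resp);
      fb_out.push_back(fb);
      rt_out.push_back(t);
      n_pair[p]++;
      n_correct[p] += resp;
    }
    bool stop = true;
    for (int p = 0; p < P; ++p)
      if ((double)n_correct[p] / n_pair[p] < criterion[p]) { stop = false; break; }
    if (stop) break;
  }
  return List::create(_["pair"] = wrap(pair_out), _["block"] = wrap(block_out),
                      _["response"] = wrap(resp_out), _["rt"] = wrap(rt_out),
                      _["feedback"] = wrap(fb_out));
}

// session log-likelihood with deterministic Q replay from the logged
// feedback; any rt <= t0 makes the whole session -Inf (the sampler rejects).
static double session_loglik_raw(const int *pair, const int *resp,
                                 const double *rt, const int *fb,
                                 const int *cell, int n, int P,
                                 const double *eta, const double *v_sc,
                                 const double *a_cell, double t0, double w,
                                 double eps) {
  std::vector<double> qt(P, 0.5), qo(P, 0.5);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    int p = pair[i], c = cell[i];
    double drift = v_sc[c] * (qt[p] - qo[p]);
    double l = wiener_logpdf_one(rt[i], resp[i], drift, a_cell[c], w, t0, eps);
    if (l == R_NegInf) return R_NegInf;
    ll += l;
    if (resp[i]) qt[p] += eta[c] * (fb[i] - qt[p]);
    else         qo[p] += eta[c] * (fb[i] - qo[p]);
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_session_loglik(IntegerVector pair, IntegerVector resp,
                          NumericVector rt, IntegerVector fb,
                          IntegerVector cell, int n_pairs, NumericVector eta,
                          NumericVector v_sc, NumericVector a_cell, double t0,
                          double w, double eps) {
  return session_loglik_raw(pair.begin(), resp.begin(), rt.begin(), fb.begin(),
                            cell.begin(), pair.size(), n_pairs, eta.begin(),
                            v_sc.begin(), a_cell.begin(), t0, w, eps);
}

// ---------------------------------------------------------------------------
// Euler-Maruyama path simulator.  Deliberately naive: fixed-step Gaussian
// increments with its own counter-based RNG, used in tests as a reference
// for the series density, the absorption probability and the grid sampler.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &s) {
  s += 0x9E3779B97f4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// [[Rcpp::export]]
List cpp_euler_fpt(int n, double v, double a, double w, double t0, double dt,
                   int seed) {
  uint64_t s = (uint64_t)seed * 0x9E3779B97f4A7C15ULL + 1ULL;
  IntegerVector resp(n);
  NumericVector t(n);
  double sdt = std::sqrt(dt);
  bool have_spare = false;
  double spare = 0.0;
  for (int i = 0; i < n; ++i) {
    double x = w * a, tt = 0.0;
    while (x > 0.0 && x < a && tt < 200.0) {
      double z;
      if (have_spare) { z = spare; have_spare = false; }
      else {
        double u1 = ((splitmix64(s) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
        double u2 = ((splitmix64(s) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
        double r = std::sqrt(-2.0 * std::log(u1));
        z = r * std::cos(2.0 * M_PI * u2);
        spare = r * std::sin(2.0 * M_PI * u2);
        have_spare = true;
      }
      x += v * dt + sdt * z;
      tt += dt;
    }
    resp[i] = (x >= a) ? 1 : 0;
    t[i] = t0 + tt;
  }
  return List::create(_["response"] = resp, _["rt"] = t);
}

// ---------------------------------------------------------------------------
// Hierarchical RL-DDM chain: adaptive Metropolis-within-Gibbs on subject
// nodes (random-walk on the sampling scales), conjugate Gibbs for group
// means, random-walk MH on log group SDs.  All randomness flows through R's
// RNG so set.seed() on the R side fixes the chain.
//
// Node layout of the returned draw matrix (columns):
//   for p in {eta, v, a}: mu[p, cell 0..K-1]        (3K)
//   for p in {eta, v, a}: sigma[p, cell 0..K-1]     (3K)
//   mu_t0, sigma_t0                                 (2)
//   for each subject: eta[0..L-1], v[...], a[...], log_t0   (sum 3L_s + 1)
//   deviance                                        (1)
// Sampling scales: logit(eta), natural v, log(a), log(t0).
// ---------------------------------------------------------------------------

struct SubjData {
  std::vector<int> pair, resp, fb, cell;
  std::vector<double> rt;
  int n_pairs, L;
  std::vector<int> map;  // local cell -> global cell
};

static double subj_loglik(const SubjData &d, const std::vector<double> &x,
                          double w, double eps) {
  int L = d.L;
  std::vector<double> eta(L), v(L), a(L);
  for (int l = 0; l < L; ++l) {
    eta[l] = 1.0 / (1.0 + std::exp(-x[l]));
    v[l] = x[L + l];
    a[l] = std::exp(x[2 * L + l]);
  }
  double t0 = std::exp(x[3 * L]);
  return session_loglik_raw(d.pair.data(), d.resp.data(), d.rt.data(),
                            d.fb.data(), d.cell.data(), (int)d.pair.size(),
                            d.n_pairs, eta.data(), v.data(), a.data(), t0, w,
                            eps);
}

static double half_normal_logpost(const std::vector<double> &vals, double mu,
                                  double lsig, double hn_scale) {
  double sig = std::exp(lsig);
  double lp = -sig * sig / (2.0 * hn_scale * hn_scale) + lsig;  // prior + jacobian
  for (size_t i = 0; i < vals.size(); ++i)
    lp += R::dnorm(vals[i], mu, sig, 1);
  return lp;
}

// [[Rcpp::export]]
List cpp_run_chain(List subjects, int K, int n_samples, int n_burn,
                   NumericVector m0, double s0, double hn_scale, double w,
                   double eps, List init) {
  int S = subjects.size();
  std::vector<SubjData> dat(S);
  for (int s = 0; s < S; ++s) {
    List sd = subjects[s];
    SubjData &d = dat[s];
    d.pair = as<std::vector<int> >(sd["pair"]);
    d.resp = as<std::vector<int> >(sd["response"]);
    d.rt = as<std::vector<double> >(sd["rt"]);
    d.fb = as<std::vector<int> >(sd["feedback"]);
    d.cell = as<std::vector<int> >(sd["cell"]);
    d.n_pairs = as<int>(sd["n_pairs"]);
    d.map = as<std::vector<int> >(sd["map"]);
    d.L = (int)d.map.size();
  }

  // state
  std::vector<std::vector<double> > mu(3, std::vector<double>(K)),
      sig(3, std::vector<double>(K, 0.3));
  NumericMatrix mu_init = init["mu"];    // 3 x K
  for (int p = 0; p < 3; ++p)
    for (int c = 0; c < K; ++c) mu[p][c] = mu_init(p, c);
  double mu_t0 = as<double>(init["mu_t0"]), sig_t0 = 0.2;
  List xs_init = init["x"];
  std::vector<std::vector<double> > x(S);
  std::vector<double> ll(S);
  for (int s = 0; s < S; ++s) {
    x[s] = as<std::vector<double> >(xs_init[s]);
    ll[s] = subj_loglik(dat[s], x[s], w, eps);
  }

  // adaptive step sizes
  std::vector<std::vector<double> > lstep(S);
  for (int s = 0; s < S; ++s) lstep[s].assign(x[s].size(), std::log(0.15));
  std::vector<double> lstep_sig(3 * K + 1, std::log(0.3));

  int n_keep = n_samples - n_burn;
  int n_group = 6 * K + 2;
  int n_subj_nodes = 0;
  for (int s = 0; s < S; ++s) n_subj_nodes += (int)x[s].size();
  NumericMatrix draws(n_keep, n_group + n_subj_nodes + 1);
  std::vector<double> xbar_sum(n_subj_nodes, 0.0);

  for (int it = 0; it < n_samples; ++it) {
    bool adapting = it < n_burn;
    double gamma = 1.0 / std::sqrt((double)(it + 1));

    // subject-level updates
    for (int s = 0; s < S; ++s) {
      int L = dat[s].L, J = (int)x[s].size();
      for (int j = 0; j < J; ++j) {
        double old = x[s][j];
        double prop = old + std::exp(lstep[s][j]) * norm_rand();
        double pm, psd;
        if (j < 3 * L) {
          int p = j / L, g = dat[s].map[j % L];
          pm = mu[p][g]; psd = sig[p][g];
        } else {
          pm = mu_t0; psd = sig_t0;
        }
        double lp_old = R::dnorm(old, pm, psd, 1);
        double lp_new = R::dnorm(prop, pm, psd, 1);
        x[s][j] = prop;
        double ll_new = subj_loglik(dat[s], x[s], w, eps);
        double lacc = (ll_new + lp_new) - (ll[s] + lp_old);
        bool acc = std::log(unif_rand()) < lacc;
        if (acc) ll[s] = ll_new; else x[s][j] = old;
        if (adapting)
          lstep[s][j] += gamma * ((acc ? 1.0 : 0.0) - 0.44);
      }
    }

    // group-level updates
    for (int p = 0; p < 3; ++p) {
      for (int c = 0; c < K; ++c) {
        std::vector<double> vals;
        for (int s = 0; s < S; ++s)
          for (int l = 0; l < dat[s].L; ++l)
            if (dat[s].map[l] == c) vals.push_back(x[s][p * dat[s].L + l]);
        if (vals.empty()) continue;
        double n = (double)vals.size(), sum = 0.0;
        for (size_t i = 0; i < vals.size(); ++i) sum += vals[i];
        double s2 = sig[p][c] * sig[p][c];
        double prec = n / s2 + 1.0 / (s0 * s0);
        double mean = (sum / s2 + m0[p] / (s0 * s0)) / prec;
        mu[p][c] = mean + norm_rand() / std::sqrt(prec);

        int k = p * K + c;
        double lold = std::log(sig[p][c]);
        double lprop = lold + std::exp(lstep_sig[k]) * norm_rand();
        double la = half_normal_logpost(vals, mu[p][c], lprop, hn_scale) -
                    half_normal_logpost(vals, mu[p][c], lold, hn_scale);
        bool acc = std::log(unif_rand()) < la;
        if (acc) sig[p][c] = std::exp(lprop);
        if (adapting) lstep_sig[k] += gamma * ((acc ? 1.0 : 0.0) - 0.44);
      }
    }
    {  // t0 hyper-parameters
      std::vector<double> vals(S);
      double sum = 0.0;
      for (int s = 0; s < S; ++s) { vals[s] = x[s][3 * dat[s].L]; sum += vals[s]; }
      double s2 = sig_t0 * sig_t0;
      double prec = S / s2 + 1.0 / (s0 * s0);
      double mean = (sum / s2 + m0[3] / (s0 * s0)) / prec;
      mu_t0 = mean + norm_rand() / std::sqrt(prec);
      int k = 3 * K;
      double lold = std::log(sig_t0);
      double lprop = lold + std::exp(lstep_sig[k]) * norm_rand();
      double la = half_normal_logpost(vals, mu_t0, lprop, hn_scale) -
                  half_normal_logpost(vals, mu_t0, lold, hn_scale);
      bool acc = std::log(unif_rand()) < la;
      if (acc) sig_t0 = std::exp(lprop);
      if (adapting) lstep_sig[k] += gamma * ((acc ? 1.0 : 0.0) - 0.44);
    }

    if (it >= n_burn) {
      int row = it - n_burn, col = 0;
      for (int p = 0; p < 3; ++p)
        for (int c = 0; c < K; ++c) draws(row, col++) = mu[p][c];
      for (int p = 0; p < 3; ++p)
        for (int c = 0; c < K; ++c) draws(row, col++) = sig[p][c];
      draws(row, col++) = mu_t0;
      draws(row, col++) = sig_t0;
      double dev = 0.0;
      int off = 0;
      for (int s = 0; s < S; ++s) {
        for (size_t j = 0; j < x[s].size(); ++j) {
          draws(row, col++) = x[s][j];
          xbar_sum[off + j] += x[s][j];
        }
        off += (int)x[s].size();
        dev += ll[s];
      }
      draws(row, col) = -2.0 * dev;
    }
  }

  // plug-in deviance at posterior means of the subject-level nodes
  double dev_hat = 0.0;
  {
    int off = 0;
    for (int s = 0; s < S; ++s) {
      std::vector<double> xb(x[s].size());
      for (size_t j = 0; j < xb.size(); ++j)
        xb[j] = xbar_sum[off + j] / n_keep;
      off += (int)xb.size();
      dev_hat += subj_loglik(dat[s], xb, w, eps);
    }
    dev_hat *= -2.0;
  }

  return List::create(_["draws"] = draws, _["plugin_deviance"] = dev_hat);
}
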