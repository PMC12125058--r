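// Core numerical kernels: IGT payoff schedules, trial-by-trial model engines
// (ORL, VSE, and the EV / PVL / EV-PU / PVL-Delta family), streamed parameter
// space partitioning, and the hierarchical log posterior used by the fitting
// backend. Everything here is deterministic given the seeds passed in.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based RNG (splitmix64). Used instead of R's stream so that every
// parameter set / simulated subject can be keyed independently on
// (global seed, index): aggregation is then invariant to chunking order.
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

static uint64_t mix_seed(uint64_t seed, uint64_t index) {
  Rng r(seed ^ (0x9E3779B97F4A7C15ULL * (index + 1ULL)));
  r.next();
  return r.next();
}

// ---------------------------------------------------------------------------
// Standard payoff scheme: gains 100/100/50/50 per draw; loss magnitudes
// 250/1250/50/250 occurring 5/1/5/1 times per block of 10 draws, so each
// block nets -250/-250/+250/+250.
// ---------------------------------------------------------------------------
static const double DECK_GAIN[4] = {100.0, 100.0, 50.0, 50.0};
static const double DECK_LOSS[4] = {250.0, 1250.0, 50.0, 250.0};
static const int DECK_NLOSS[4] = {5, 1, 5, 1};

static void build_schedule(int n_trials, Rng &rng, bool canonical,
                           std::vector<double> *gain, std::vector<double> *loss) {
  int nblocks = (n_trials + 9) / 10;
  for (int d = 0; d < 4; ++d) {
    gain[d].assign(n_trials, DECK_GAIN[d]);
    loss[d].assign(n_trials, 0.0);
    for (int b = 0; b < nblocks; ++b) {
      int pos[10];
      for (int i = 0; i < 10; ++i) pos[i] = i;
      if (canonical) {
        // documented deterministic layout: frequent-loss decks at in-block
        // positions 2,4,6,8,10; infrequent-loss decks at position 10
        if (DECK_NLOSS[d] == 5) {
          pos[0] = 1; pos[1] = 3; pos[2] = 5; pos[3] = 7; pos[4] = 9;
        } else {
          pos[0] = 9;
        }
      } else {
        for (int i = 0; i < DECK_NLOSS[d]; ++i) {
          int j = i + rng.below(10 - i);
          int tmp = pos[i]; pos[i] = pos[j]; pos[j] = tmp;
        }
      }
      for (int i = 0; i < DECK_NLOSS[d]; ++i) {
        int t = b * 10 + pos[i];
        if (t < n_trials) loss[d][t] = DECK_LOSS[d];
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_build_schedule(int n_trials, double seed, bool canonical) {
  Rng rng(mix_seed((uint64_t)seed, 0));
  std::vector<double> gain[4], loss[4];
  build_schedule(n_trials, rng, canonical, gain, loss);
  NumericMatrix G(n_trials, 4), L(n_trials, 4);
  for (int d = 0; d < 4; ++d)
    for (int t = 0; t < n_trials; ++t) {
      G(t, d) = gain[d][t];
      L(t, d) = loss[d][t];
    }
  return List::create(_["gain"] = G, _["loss"] = L);
}

// ---------------------------------------------------------------------------
// Model engines. Model ids: 1 ORL, 2 VSE, 3 EV, 4 PVL, 5 EV-PU, 6 PVL-Delta.
// State layout (12 doubles): ORL EV[0..3] EF[4..7] PS[8..11];
// VSE exploit[0..3] explore[4..7]; legacy expectancies [0..3].
// ---------------------------------------------------------------------------
static void softmax4(const double *v, double *p) {
  double m = v[0];
  for (int i = 1; i < 4; ++i) if (v[i] > m) m = v[i];
  double s = 0.0;
  for (int i = 0; i < 4; ++i) { p[i] = std::exp(v[i] - m); s += p[i]; }
  for (int i = 0; i < 4; ++i) p[i] /= s;
}

static void model_probs(int id, const double *par, const double *st, int trial1,
                        double *p) {
  double v[4];
  switch (id) {
  case 1: // ORL: softmax on V = EV + EF*beta_F + PS*beta_P, sensitivity 1
    for (int j = 0; j < 4; ++j) v[j] = st[j] + st[4 + j] * par[3] + st[8 + j] * par[4];
    break;
  case 2: { // VSE: softmax on (Explore + Exploit) * c, c = 3^beta - 1
    double c = std::pow(3.0, par[4]) - 1.0;
    for (int j = 0; j < 4; ++j) v[j] = (st[j] + st[4 + j]) * c;
    break;
  }
  case 3: case 5: { // EV, EV-PU: trial-dependent sensitivity (t/10)^c
    double c = (id == 3) ? par[2] : par[3];
    double th = std::pow(trial1 / 10.0, c);
    for (int j = 0; j < 4; ++j) v[j] = th * st[j];
    break;
  }
  default: { // PVL, PVL-Delta: sensitivity 3^c - 1
    double th = std::pow(3.0, par[3]) - 1.0;
    for (int j = 0; j < 4; ++j) v[j] = th * st[j];
  }
  }
  softmax4(v, p);
}

static void model_update(int id, const double *par, double *st, int chosen,
                         double gain, double loss) {
  double x = gain - loss;
  switch (id) {
  case 1: { // ORL
    double A = (x >= 0) ? par[0] : par[1];
    // fictive (unchosen-deck) frequency updates use the opposite rate, as in
    // the model's original counterfactual formulation: a win on the chosen
    // deck is a relative loss for the alternatives
    double Af = (x >= 0) ? par[1] : par[0];
    double sg = (x > 0) ? 1.0 : ((x < 0) ? -1.0 : 0.0);
    st[chosen] += A * (x - st[chosen]);
    for (int j = 0; j < 4; ++j) {
      if (j == chosen) st[4 + j] += A * (sg - st[4 + j]);
      else st[4 + j] += Af * (-sg / 3.0 - st[4 + j]);
    }
    double K = std::pow(3.0, par[2]) - 1.0;
    for (int j = 0; j < 4; ++j)
      st[8 + j] = (j == chosen) ? 1.0 / (1.0 + K) : st[8 + j] / (1.0 + K);
    break;
  }
  case 2: { // VSE
    double v = std::pow(gain, par[0]) - std::pow(loss, par[0]);
    for (int j = 0; j < 4; ++j) st[j] *= par[1];
    st[chosen] += v;
    for (int j = 0; j < 4; ++j)
      st[4 + j] = (j == chosen) ? 0.0 : st[4 + j] + par[2] * (par[3] - st[4 + j]);
    break;
  }
  case 3: { // EV: u = (1-w)W - wL, delta rule on chosen deck
    double u = (1.0 - par[0]) * gain - par[0] * loss;
    st[chosen] += par[1] * (u - st[chosen]);
    break;
  }
  case 4: { // PVL: prospect utility, decay rule on all decks
    double u = (x >= 0) ? std::pow(x, par[0]) : -par[1] * std::pow(-x, par[0]);
    for (int j = 0; j < 4; ++j) st[j] *= par[2];
    st[chosen] += u;
    break;
  }
  default: { // EV-PU / PVL-Delta: prospect utility, delta rule on chosen deck
    double u = (x >= 0) ? std::pow(x, par[0]) : -par[1] * std::pow(-x, par[0]);
    st[chosen] += par[2] * (u - st[chosen]);
  }
  }
}

static void simulate_core(int id, const double *par, int n_trials,
                          const std::vector<double> *gain,
                          const std::vector<double> *loss, double scale,
                          Rng &rng, int *choices, double *rgain, double *rloss) {
  double st[12] = {0};
  int cur[4] = {0, 0, 0, 0};
  double p[4];
  for (int t = 0; t < n_trials; ++t) {
    model_probs(id, par, st, t + 1, p);
    double u = rng.unif(), acc = 0.0;
    int ch = 3;
    for (int j = 0; j < 4; ++j) {
      acc += p[j];
      if (u < acc) { ch = j; break; }
    }
    double g = gain[ch][cur[ch]], l = loss[ch][cur[ch]];
    cur[ch]++;
    choices[t] = ch + 1;
    rgain[t] = g;
    rloss[t] = l;
    model_update(id, par, st, ch, g * scale, l * scale);
  }
}

// [[Rcpp::export]]
List cpp_simulate_agent(int model_id, NumericVector par, NumericMatrix gain,
                        NumericMatrix loss, int n_trials, double seed,
                        double scale) {
  std::vector<double> G[4], L[4];
  for (int d = 0; d < 4; ++d) {
    G[d].resize(gain.nrow());
    L[d].resize(loss.nrow());
    for (int t = 0; t < gain.nrow(); ++t) {
      G[d][t] = gain(t, d);
      L[d][t] = loss(t, d);
    }
  }
  IntegerVector choices(n_trials);
  NumericVector rg(n_trials), rl(n_trials);
  Rng rng(mix_seed((uint64_t)seed, 1));
  simulate_core(model_id, par.begin(), n_trials, G, L, scale, rng,
                choices.begin(), rg.begin(), rl.begin());
  return List::create(_["deck"] = choices, _["gain"] = rg, _["loss"] = rl);
}

static double loglik_core(int id, const double *par, int n, const int *choices,
                          const double *g, const double *l, double scale,
                          double *pointwise) {
  double st[12] = {0};
  double p[4], tot = 0.0;
  for (int t = 0; t < n; ++t) {
    model_probs(id, par, st, t + 1, p);
    int ch = choices[t] - 1;
    double pc = p[ch] > 1e-300 ? p[ch] : 1e-300;
    double lp = std::log(pc);
    if (pointwise) pointwise[t] = lp;
    tot += lp;
    model_update(id, par, st, ch, g[t] * scale, l[t] * scale);
  }
  return tot;
}

// [[Rcpp::export]]
NumericVector cpp_loglik(int model_id, NumericVector par, IntegerVector choices,
                         NumericVector gain, NumericVector loss, double scale,
                         bool pointwise) {
  int n = choices.size();
  if (pointwise) {
    NumericVector out(n);
    loglik_core(model_id, par.begin(), n, choices.begin(), gain.begin(),
                loss.begin(), scale, out.begin());
    return out;
  }
  double tot = loglik_core(model_id, par.begin(), n, choices.begin(),
                           gain.begin(), loss.begin(), scale, nullptr);
  return NumericVector::create(tot);
}

// ---------------------------------------------------------------------------
// Streamed PSP: decode parameter sets from a lexicographic index (first
// parameter slowest), simulate one run per set with a per-set seed, return
// deck counts for the requested index window.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_psp_counts(int model_id, NumericVector lo, NumericVector hi,
                             int npoints, double idx_from, double idx_to,
                             int n_trials, double seed, double scale,
                             bool canonical, int replicate) {
  int P = lo.size();
  long long from = (long long)idx_from, to = (long long)idx_to;
  int n = (int)(to - from);
  IntegerMatrix counts(n, 4);
  std::vector<double> gain[4], loss[4];
  std::vector<double> par(P);
  std::vector<int> choices(n_trials);
  std::vector<double> rg(n_trials), rl(n_trials);
  for (int k = 0; k < n; ++k) {
    long long idx = from + k;
    long long rem = idx;
    for (int p = P - 1; p >= 0; --p) {
      int d = (int)(rem % npoints);
      rem /= npoints;
      par[p] = (npoints == 1) ? (lo[p] + hi[p]) / 2.0
                              : lo[p] + d * (hi[p] - lo[p]) / (npoints - 1);
    }
    uint64_t run_key = (uint64_t)idx * 1000003ULL + (uint64_t)replicate;
    Rng rng(mix_seed((uint64_t)seed, run_key));
    build_schedule(n_trials, rng, canonical, gain, loss);
    simulate_core(model_id, par.data(), n_trials, gain, loss, scale, rng,
                  choices.data(), rg.data(), rl.data());
    int c4[4] = {0, 0, 0, 0};
    for (int t = 0; t < n_trials; ++t) c4[choices[t] - 1]++;
    for (int j = 0; j < 4; ++j) counts(k, j) = c4[j];
  }
  return counts;
}

// ---------------------------------------------------------------------------
// Hierarchical model, non-centered parameterization: per parameter p a group
// mean mu_p and SD sigma_p (log-scale in eta), per subject i a standard
// normal deviate z_ip; subject-level natural parameters are
// transform(mu_p + sigma_p * z_ip), with the transform a probit CDF scaled
// to the parameter's range (identity for unbounded parameters).
// eta = [mu (P), log sigma (P), z (N*P)].
// The posterior is approximated by mean-field Gaussian variational inference
// (ADVI): reparameterized stochastic gradient ascent on the ELBO, with
// analytic forward-sensitivity gradients of the trial-level likelihood.
// ---------------------------------------------------------------------------
struct HierSpec {
  int P;
  int type[5];          // 0: (0,1) probit; 1: [0,ub] scaled probit; 2: identity
  double ub[5];
  double mu_sd[5];      // prior SD of mu
  int sig_type[5];      // 0 half-normal, 1 half-Cauchy
  double sig_scale[5];
};

static void hier_spec(int model_id, HierSpec &s) {
  s.P = 5;
  if (model_id == 1) { // ORL
    int ty[5] = {0, 0, 1, 2, 2};
    double ub[5] = {1, 1, 5, 0, 0};
    int st[5] = {0, 0, 0, 1, 1};
    double ss[5] = {0.2, 0.2, 0.2, 1.0, 1.0};
    for (int p = 0; p < 5; ++p) {
      s.type[p] = ty[p]; s.ub[p] = ub[p]; s.mu_sd[p] = 1.0;
      s.sig_type[p] = st[p]; s.sig_scale[p] = ss[p];
    }
  } else { // VSE
    int ty[5] = {0, 0, 0, 2, 1};
    double ub[5] = {1, 1, 1, 0, 5};
    for (int p = 0; p < 5; ++p) {
      s.type[p] = ty[p]; s.ub[p] = ub[p]; s.mu_sd[p] = 3.0;
      s.sig_type[p] = 0; s.sig_scale[p] = 3.0;
    }
  }
}

static double transform1(int type, double ub, double x) {
  if (type == 0) return R::pnorm(x, 0.0, 1.0, 1, 0);
  if (type == 1) return ub * R::pnorm(x, 0.0, 1.0, 1, 0);
  return x;
}

static double transform1_deriv(int type, double ub, double x) {
  if (type == 0) return R::dnorm(x, 0.0, 1.0, 0);
  if (type == 1) return ub * R::dnorm(x, 0.0, 1.0, 0);
  return 1.0;
}

// ---- per-subject log-likelihood with analytic gradient -------------------
// Forward sensitivities of the latent state with respect to the 5 natural
// parameters, propagated through the softmax at every observed choice.

static double ll_grad_orl(const double *par, int n, const int *choices,
                          const double *g, const double *l, double scale,
                          double *grad) {
  double EV[4] = {0}, EF[4] = {0}, PS[4] = {0};
  double dEV[4][2] = {{0}}, dEF[4][2] = {{0}}, dPS[4] = {0};
  const double Arew = par[0], Apun = par[1], Kp = par[2], bF = par[3],
               bP = par[4];
  const double K = std::pow(3.0, Kp) - 1.0;
  const double dK = std::pow(3.0, Kp) * std::log(3.0);
  double ll = 0.0;
  for (int p = 0; p < 5; ++p) grad[p] = 0.0;
  for (int t = 0; t < n; ++t) {
    // choice probabilities and logit sensitivities from the current state
    double V[4], dV[4][5], pr[4];
    for (int j = 0; j < 4; ++j) {
      V[j] = EV[j] + EF[j] * bF + PS[j] * bP;
      dV[j][0] = dEV[j][0] + bF * dEF[j][0];
      dV[j][1] = dEV[j][1] + bF * dEF[j][1];
      dV[j][2] = bP * dPS[j];
      dV[j][3] = EF[j];
      dV[j][4] = PS[j];
    }
    softmax4(V, pr);
    int ch = choices[t] - 1;
    double pc = pr[ch] > 1e-300 ? pr[ch] : 1e-300;
    ll += std::log(pc);
    for (int p = 0; p < 5; ++p) {
      double e = dV[ch][p];
      for (int j = 0; j < 4; ++j) e -= pr[j] * dV[j][p];
      grad[p] += e;
    }
    // state update (teacher forcing)
    double x = (g[t] - l[t]) * scale;
    double A = (x >= 0) ? Arew : Apun;
    double sg = (x > 0) ? 1.0 : ((x < 0) ? -1.0 : 0.0);
    int iA = (x >= 0) ? 0 : 1;   // index of the rate used for chosen updates
    int iF = 1 - iA;             // fictive updates use the opposite rate
    double Af = (x >= 0) ? Apun : Arew;
    // EV (chosen only)
    dEV[ch][iA] = dEV[ch][iA] * (1.0 - A) + (x - EV[ch]);
    dEV[ch][1 - iA] *= (1.0 - A);
    EV[ch] += A * (x - EV[ch]);
    // EF
    for (int j = 0; j < 4; ++j) {
      if (j == ch) {
        dEF[j][iA] = dEF[j][iA] * (1.0 - A) + (sg - EF[j]);
        dEF[j][1 - iA] *= (1.0 - A);
        EF[j] += A * (sg - EF[j]);
      } else {
        double target = -sg / 3.0;
        dEF[j][iF] = dEF[j][iF] * (1.0 - Af) + (target - EF[j]);
        dEF[j][1 - iF] *= (1.0 - Af);
        EF[j] += Af * (target - EF[j]);
      }
    }
    // PS
    for (int j = 0; j < 4; ++j) {
      if (j == ch) {
        PS[j] = 1.0 / (1.0 + K);
        dPS[j] = -dK / ((1.0 + K) * (1.0 + K));
      } else {
        dPS[j] = dPS[j] / (1.0 + K) - PS[j] * dK / ((1.0 + K) * (1.0 + K));
        PS[j] /= (1.0 + K);
      }
    }
  }
  return ll;
}

static double ll_grad_vse(const double *par, int n, const int *choices,
                          const double *g, const double *l, double scale,
                          double *grad) {
  double E[4] = {0}, X[4] = {0};
  double dE[4][2] = {{0}}, dX[4][2] = {{0}}; // E: theta, delta; X: alpha, phi
  const double th = par[0], del = par[1], al = par[2], ph = par[3],
               be = par[4];
  const double c = std::pow(3.0, be) - 1.0;
  const double dc = std::pow(3.0, be) * std::log(3.0);
  double ll = 0.0;
  for (int p = 0; p < 5; ++p) grad[p] = 0.0;
  for (int t = 0; t < n; ++t) {
    double L[4], dL[4][5], pr[4];
    for (int j = 0; j < 4; ++j) {
      double w = E[j] + X[j];
      L[j] = w * c;
      dL[j][0] = dE[j][0] * c;
      dL[j][1] = dE[j][1] * c;
      dL[j][2] = dX[j][0] * c;
      dL[j][3] = dX[j][1] * c;
      dL[j][4] = w * dc;
    }
    softmax4(L, pr);
    int ch = choices[t] - 1;
    double pc = pr[ch] > 1e-300 ? pr[ch] : 1e-300;
    ll += std::log(pc);
    for (int p = 0; p < 5; ++p) {
      double e = dL[ch][p];
      for (int j = 0; j < 4; ++j) e -= pr[j] * dL[j][p];
      grad[p] += e;
    }
    double gs = g[t] * scale, ls = l[t] * scale;
    double v = std::pow(gs, th) - std::pow(ls, th);
    double dv = (gs > 0 ? std::pow(gs, th) * std::log(gs) : 0.0) -
                (ls > 0 ? std::pow(ls, th) * std::log(ls) : 0.0);
    for (int j = 0; j < 4; ++j) {
      dE[j][1] = dE[j][1] * del + E[j];
      dE[j][0] *= del;
      E[j] *= del;
      if (j == ch) {
        E[j] += v;
        dE[j][0] += dv;
        X[j] = 0.0; dX[j][0] = 0.0; dX[j][1] = 0.0;
      } else {
        dX[j][0] = dX[j][0] * (1.0 - al) + (ph - X[j]);
        dX[j][1] = dX[j][1] * (1.0 - al) + al;
        X[j] += al * (ph - X[j]);
      }
    }
  }
  return ll;
}

static double ll_grad_subject(int model_id, const double *par, int n,
                              const int *choices, const double *g,
                              const double *l, double scale, double *grad) {
  if (model_id == 1) return ll_grad_orl(par, n, choices, g, l, scale, grad);
  return ll_grad_vse(par, n, choices, g, l, scale, grad);
}

// [[Rcpp::export]]
List cpp_ll_grad(int model_id, NumericVector par, IntegerVector choices,
                 NumericVector gain, NumericVector loss, double scale) {
  NumericVector grad(5);
  double ll = ll_grad_subject(model_id, par.begin(), choices.size(),
                              choices.begin(), gain.begin(), loss.begin(),
                              scale, grad.begin());
  return List::create(_["loglik"] = ll, _["gradient"] = grad);
}

// log joint density and its gradient in the unconstrained eta space
static double hier_lp_grad(int model_id, const double *eta, int N,
                           const int *off, const int *choices, const double *g,
                           const double *l, double scale, double *grad) {
  HierSpec s;
  hier_spec(model_id, s);
  const int P = s.P;
  const double *mu = eta;
  const double *lsig = eta + P;
  const double *z = eta + 2 * P;
  const int D = 2 * P + N * P;
  for (int d = 0; d < D; ++d) grad[d] = 0.0;
  double lp = 0.0;
  double sig[5];
  for (int p = 0; p < P; ++p) {
    sig[p] = std::exp(lsig[p]);
    lp += R::dnorm(mu[p], 0.0, s.mu_sd[p], 1);
    grad[p] += -mu[p] / (s.mu_sd[p] * s.mu_sd[p]);
    double r = sig[p] / s.sig_scale[p];
    if (s.sig_type[p] == 0) {
      lp += -0.5 * r * r;
      grad[P + p] += -r * r;
    } else {
      lp += -std::log1p(r * r);
      grad[P + p] += -2.0 * r * r / (1.0 + r * r);
    }
    lp += lsig[p]; // Jacobian of sigma = exp(log sigma)
    grad[P + p] += 1.0;
  }
  double par[8], gnat[8];
  for (int i = 0; i < N; ++i) {
    double u[5], dT[5];
    for (int p = 0; p < P; ++p) {
      double zi = z[i * P + p];
      lp += R::dnorm(zi, 0.0, 1.0, 1);
      grad[2 * P + i * P + p] += -zi;
      u[p] = mu[p] + sig[p] * zi;
      par[p] = transform1(s.type[p], s.ub[p], u[p]);
      dT[p] = transform1_deriv(s.type[p], s.ub[p], u[p]);
    }
    int a = off[i], b = off[i + 1];
    lp += ll_grad_subject(model_id, par, b - a, choices + a, g + a, l + a,
                          scale, gnat);
    for (int p = 0; p < P; ++p) {
      double du = gnat[p] * dT[p];
      grad[p] += du;
      grad[P + p] += du * sig[p] * z[i * P + p];
      grad[2 * P + i * P + p] += du * sig[p];
    }
  }
  return lp;
}

// [[Rcpp::export]]
List cpp_hier_lp_grad(int model_id, NumericVector eta, IntegerVector off,
                      IntegerVector choices, NumericVector gain,
                      NumericVector loss, double scale) {
  int N = off.size() - 1;
  NumericVector grad(eta.size());
  double lp = hier_lp_grad(model_id, eta.begin(), N, off.begin(),
                           choices.begin(), gain.begin(), loss.begin(), scale,
                           grad.begin());
  return List::create(_["lp"] = lp, _["gradient"] = grad);
}

// [[Rcpp::export]]
double cpp_hier_nlp(int model_id, NumericVector eta, IntegerVector off,
                    IntegerVector choices, NumericVector gain,
                    NumericVector loss, double scale) {
  int N = off.size() - 1;
  std::vector<double> grad(eta.size());
  double lp = hier_lp_grad(model_id, eta.begin(), N, off.begin(),
                           choices.begin(), gain.begin(), loss.begin(), scale,
                           grad.data());
  return -lp;
}

// Mean-field ADVI: maximize the ELBO over (m, omega) with q = N(m, e^omega),
// one reparameterized draw per iteration, Adam steps. Deterministic given
// `seed`.
// [[Rcpp::export]]
List cpp_hier_advi(int model_id, IntegerVector off, IntegerVector choices,
                   NumericVector gain, NumericVector loss, double scale,
                   int iters, double seed, double lr) {
  int N = off.size() - 1;
  HierSpec s;
  hier_spec(model_id, s);
  const int P = s.P;
  const int D = 2 * P + N * P;
  std::vector<double> m(D, 0.0), om(D, std::log(0.1));
  for (int p = 0; p < P; ++p) m[P + p] = std::log(0.2);
  std::vector<double> g(D), gm(D), gw(D);
  std::vector<double> a1m(D, 0.0), a2m(D, 0.0), a1w(D, 0.0), a2w(D, 0.0);
  std::vector<double> eta(D), epsv(D);
  const double b1 = 0.9, b2 = 0.999, adeps = 1e-8;
  Rng rng(mix_seed((uint64_t)seed, 777));
  double elbo_run = 0.0;
  NumericVector trace(iters / 100 + 1);
  int tk = 0;
  for (int it = 1; it <= iters; ++it) {
    for (int d = 0; d < D; d += 2) { // Box-Muller
      double u1 = rng.unif(), u2 = rng.unif();
      if (u1 < 1e-300) u1 = 1e-300;
      double rr = std::sqrt(-2.0 * std::log(u1));
      epsv[d] = rr * std::cos(2.0 * M_PI * u2);
      if (d + 1 < D) epsv[d + 1] = rr * std::sin(2.0 * M_PI * u2);
    }
    double ent = 0.0;
    for (int d = 0; d < D; ++d) {
      eta[d] = m[d] + std::exp(om[d]) * epsv[d];
      ent += om[d];
    }
    double lp = hier_lp_grad(model_id, eta.data(), N, off.begin(),
                             choices.begin(), gain.begin(), loss.begin(),
                             scale, g.data());
    double elbo = lp + ent; // + const
    elbo_run = (it == 1) ? elbo : 0.99 * elbo_run + 0.01 * elbo;
    if (it % 100 == 0 && tk < trace.size()) trace[tk++] = elbo_run;
    double step = lr / (1.0 + it / (double)iters);
    for (int d = 0; d < D; ++d) {
      gm[d] = g[d];
      gw[d] = g[d] * std::exp(om[d]) * epsv[d] + 1.0;
      a1m[d] = b1 * a1m[d] + (1 - b1) * gm[d];
      a2m[d] = b2 * a2m[d] + (1 - b2) * gm[d] * gm[d];
      a1w[d] = b1 * a1w[d] + (1 - b1) * gw[d];
      a2w[d] = b2 * a2w[d] + (1 - b2) * gw[d] * gw[d];
      double c1 = 1.0 - std::pow(b1, it), c2 = 1.0 - std::pow(b2, it);
      m[d] += step * (a1m[d] / c1) / (std::sqrt(a2m[d] / c2) + adeps);
      om[d] += step * (a1w[d] / c1) / (std::sqrt(a2w[d] / c2) + adeps);
      if (om[d] > 3.0) om[d] = 3.0;
      if (om[d] < -12.0) om[d] = -12.0;
    }
  }
  return List::create(_["mean"] = NumericVector(m.begin(), m.end()),
                      _["log_sd"] = NumericVector(om.begin(), om.end()),
                      _["elbo_trace"] = trace);
}

// Pointwise log-likelihood matrix (S draws x total trials) for WAIC.
// [[Rcpp::export]]
NumericMatrix cpp_hier_pointwise(int model_id, NumericMatrix draws,
                                 IntegerVector off, IntegerVector choices,
                                 NumericVector gain, NumericVector loss,
                                 double scale) {
  HierSpec s;
  hier_spec(model_id, s);
  int P = s.P, N = off.size() - 1, S = draws.nrow();
  int ntot = choices.size();
  NumericMatrix out(S, ntot);
  std::vector<double> pw(ntot);
  double par[8];
  for (int sdraw = 0; sdraw < S; ++sdraw) {
    for (int i = 0; i < N; ++i) {
      for (int p = 0; p < P; ++p) {
        double mu = draws(sdraw, p);
        double sig = std::exp(draws(sdraw, P + p));
        double zi = draws(sdraw, 2 * P + i * P + p);
        par[p] = transform1(s.type[p], s.ub[p], mu + sig * zi);
      }
      int a = off[i], b = off[i + 1];
      loglik_core(model_id, par, b - a, choices.begin() + a, gain.begin() + a,
                  loss.begin() + a, scale, pw.data() + a);
    }
    for (int t = 0; t < ntot; ++t) out(sdraw, t) = pw[t];
  }
  return out;
}

// Hamiltonian Monte Carlo on the same non-centered posterior: leapfrog with
// dual-averaging step-size adaptation and a diagonal mass matrix estimated
// during warmup. Deterministic given `seed`. Returns S draws (rows) in the
// eta space plus diagnostics.
// [[Rcpp::export]]
List cpp_hier_hmc(int model_id, IntegerVector off, IntegerVector choices,
                  NumericVector gain, NumericVector loss, double scale,
                  int warmup, int n_draws, double seed, int n_leapfrog) {
  int N = off.size() - 1;
  HierSpec s;
  hier_spec(model_id, s);
  const int P = s.P;
  const int D = 2 * P + N * P;
  std::vector<double> q(D, 0.0), g(D), qn(D), gn(D), p(D), minv(D, 1.0);
  for (int pp = 0; pp < P; ++pp) q[P + pp] = std::log(0.2);
  Rng rng(mix_seed((uint64_t)seed, 4242));
  double lp = hier_lp_grad(model_id, q.data(), N, off.begin(), choices.begin(),
                           gain.begin(), loss.begin(), scale, g.data());
  // dual averaging state
  double eps = 0.05, mu_da = std::log(10.0 * eps), logebar = std::log(eps);
  double hbar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75, delta_target = 0.8;
  // warmup variance accumulation for the mass matrix
  std::vector<double> wsum(D, 0.0), wsum2(D, 0.0);
  int wn = 0;
  int total = warmup + n_draws;
  NumericMatrix draws(n_draws, D);
  int accepted = 0;
  for (int it = 1; it <= total; ++it) {
    bool in_warmup = it <= warmup;
    double e = in_warmup ? eps : std::exp(logebar);
    // jitter the path length to avoid resonances
    int L = n_leapfrog / 2 + rng.below(n_leapfrog);
    double ke0 = 0.0;
    for (int d = 0; d < D; ++d) {
      // momentum ~ N(0, M) with M = 1/minv
      double u1 = rng.unif(), u2 = rng.unif();
      if (u1 < 1e-300) u1 = 1e-300;
      double z = std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
      p[d] = z / std::sqrt(minv[d]);
      ke0 += 0.5 * p[d] * p[d] * minv[d];
    }
    qn = q;
    gn = g;
    double lpn = lp;
    // leapfrog
    std::vector<double> pm = p;
    for (int d = 0; d < D; ++d) pm[d] += 0.5 * e * gn[d];
    bool diverged = false;
    for (int step = 0; step < L; ++step) {
      for (int d = 0; d < D; ++d) qn[d] += e * minv[d] * pm[d];
      lpn = hier_lp_grad(model_id, qn.data(), N, off.begin(), choices.begin(),
                         gain.begin(), loss.begin(), scale, gn.data());
      if (!std::isfinite(lpn)) { diverged = true; break; }
      double half = (step == L - 1) ? 0.5 : 1.0;
      for (int d = 0; d < D; ++d) pm[d] += half * e * gn[d];
    }
    double alpha = 0.0;
    if (!diverged) {
      double ke1 = 0.0;
      for (int d = 0; d < D; ++d) ke1 += 0.5 * pm[d] * pm[d] * minv[d];
      double logr = (lpn - ke1) - (lp - ke0);
      alpha = logr > 0 ? 1.0 : std::exp(logr);
      if (rng.unif() < alpha) {
        q = qn; g = gn; lp = lpn;
        if (!in_warmup) ++accepted;
      }
    }
    if (in_warmup) {
      // dual averaging (Hoffman & Gelman)
      double w = 1.0 / (it + t0);
      hbar = (1.0 - w) * hbar + w * (delta_target - alpha);
      double logeps = mu_da - std::sqrt((double)it) / gamma * hbar;
      eps = std::exp(logeps);
      double wk = std::pow((double)it, -kappa);
      logebar = wk * logeps + (1.0 - wk) * logebar;
      if (it > warmup / 4 && it <= (3 * warmup) / 4) {
        for (int d = 0; d < D; ++d) { wsum[d] += q[d]; wsum2[d] += q[d] * q[d]; }
        ++wn;
      }
      if (it == (3 * warmup) / 4 && wn > 10) {
        for (int d = 0; d < D; ++d) {
          double v = wsum2[d] / wn - (wsum[d] / wn) * (wsum[d] / wn);
          minv[d] = v > 1e-6 ? v : 1e-6;
        }
        // restart step-size adaptation for the new metric
        mu_da = std::log(10.0 * eps);
        hbar = 0.0;
      }
    } else {
      int k = it - warmup - 1;
      for (int d = 0; d < D; ++d) draws(k, d) = q[d];
    }
  }
  return List::create(_["draws"] = draws,
                      _["accept_rate"] = (double)accepted / n_draws,
                      _["step_size"] = std::exp(logebar));
}
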