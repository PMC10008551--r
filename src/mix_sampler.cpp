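// Random-walk Metropolis for the dietary mixing posterior.
//
// State: z in R^{K-1} (softmax coordinates with the last component pinned
// at 0) mapping to alpha on the simplex, plus latent source signals,
// caloric concentrations and diet-to-tissue offsets. The base prior on
// alpha is uniform on the simplex, which in z-coordinates contributes the
// softmax Jacobian log|J| = sum_k log(alpha_k). Inequality priors A a >= b
// are enforced by rejecting violating proposals. Latents are refreshed by
// an independence Metropolis step with the prior as proposal, so only the
// likelihood ratio enters the acceptance probability.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

void softmax(const std::vector<double>& z, std::vector<double>& a) {
  const int K = a.size();
  double mx = 0.0;
  for (int k = 0; k < K - 1; ++k) mx = std::max(mx, z[k]);
  double s = std::exp(0.0 - mx);
  a[K - 1] = s;
  for (int k = 0; k < K - 1; ++k) { a[k] = std::exp(z[k] - mx); s += a[k]; }
  for (int k = 0; k < K; ++k) a[k] /= s;
}

bool feasible(const std::vector<double>& a, const NumericMatrix& A,
              const NumericVector& b) {
  for (int m = 0; m < A.nrow(); ++m) {
    double acc = 0.0;
    for (int k = 0; k < A.ncol(); ++k) acc += A(m, k) * a[k];
    if (acc < b[m] - 1e-12) return false;
  }
  return true;
}

double log_jac(const std::vector<double>& a) {
  double s = 0.0;
  for (double v : a) s += std::log(std::max(v, 1e-300));
  return s;
}

double rtruncnorm01(double mu, double sd) {
  if (sd <= 0.0) return std::min(1.0, std::max(0.0, mu));
  for (int t = 0; t < 100; ++t) {
    double v = R::rnorm(mu, sd);
    if (v >= 0.0 && v <= 1.0) return v;
  }
  return std::min(1.0, std::max(0.0, mu));
}

struct Latents {
  std::vector<double> sig;   // K*F*P signals
  std::vector<double> cprot; // K protein caloric fractions
  std::vector<double> off;   // P offsets
};

void draw_latents(Latents& L, const NumericVector& sig_mean,
                  const NumericVector& sig_sd, const NumericMatrix& conc_mean,
                  const NumericVector& conc_sd, const NumericVector& off_mean,
                  const NumericVector& off_sd, int K, int F, int P) {
  for (size_t i = 0; i < L.sig.size(); ++i)
    L.sig[i] = sig_sd[i] > 0 ? R::rnorm(sig_mean[i], sig_sd[i]) : sig_mean[i];
  for (int k = 0; k < K; ++k)
    L.cprot[k] = rtruncnorm01(conc_mean(k, 0), conc_sd[k]);
  for (int i = 0; i < P; ++i)
    L.off[i] = off_sd[i] > 0 ? R::rnorm(off_mean[i], off_sd[i]) : off_mean[i];
  (void)F;
}

// likelihood of the group targets given alpha and latent values
double loglik(const std::vector<double>& a, const Latents& L,
              const NumericMatrix& routing, const NumericVector& target_mean,
              const NumericVector& target_sd, int K, int F, int P) {
  double ll = 0.0;
  for (int i = 0; i < P; ++i) {
    double pred = L.off[i];
    for (int f = 0; f < F; ++f) {
      double w = routing(i, f);
      if (w == 0.0) continue;
      double num = 0.0, den = 0.0;
      for (int k = 0; k < K; ++k) {
        double c = (f == 0) ? L.cprot[k] : 1.0 - L.cprot[k];
        // sig index: k + K*f + K*F*i (column-major cube as passed from R)
        num += a[k] * c * L.sig[k + K * f + K * F * i];
        den += a[k] * c;
      }
      if (den <= 1e-12) return -1e300;
      pred += w * num / den;
    }
    ll += R::dnorm4(target_mean[i], pred, target_sd[i], 1);
  }
  return ll;
}

}  // namespace

// [[Rcpp::export]]
List mix_mcmc_chain(NumericVector sig_mean, NumericVector sig_sd,
                    NumericMatrix conc_mean, NumericVector conc_sd,
                    NumericMatrix routing, NumericVector offset_mean,
                    NumericVector offset_sd, NumericVector target_mean,
                    NumericVector target_sd, NumericMatrix A, NumericVector b,
                    NumericVector init_alpha, int iter, int burn_in, int thin,
                    double step0) {
  const int K = conc_mean.nrow();
  const int P = target_mean.size();
  const int F = routing.ncol();

  std::vector<double> z(K - 1), zprop(K - 1), a(K), aprop(K);
  for (int k = 0; k < K - 1; ++k)
    z[k] = std::log(std::max(init_alpha[k], 1e-10)) -
           std::log(std::max(init_alpha[K - 1], 1e-10));
  softmax(z, a);

  Latents L, Lprop;
  L.sig.resize(K * F * P); L.cprot.resize(K); L.off.resize(P);
  Lprop = L;
  draw_latents(L, sig_mean, sig_sd, conc_mean, conc_sd, offset_mean,
               offset_sd, K, F, P);
  double ll = loglik(a, L, routing, target_mean, target_sd, K, F, P);
  double lj = log_jac(a);

  const int n_keep = (iter - burn_in) / thin;
  NumericMatrix draws(n_keep, K);
  double step = step0;
  int acc = 0, tries = 0, win_acc = 0, win_n = 0, kept = 0;

  for (int it = 0; it < iter; ++it) {
    // alpha update: random walk in z
    for (int k = 0; k < K - 1; ++k) zprop[k] = z[k] + step * R::norm_rand();
    softmax(zprop, aprop);
    ++tries; ++win_n;
    if (feasible(aprop, A, b)) {
      double llp = loglik(aprop, L, routing, target_mean, target_sd, K, F, P);
      double ljp = log_jac(aprop);
      if (std::log(R::unif_rand()) < llp + ljp - ll - lj) {
        z = zprop; a = aprop; ll = llp; lj = ljp;
        ++acc; ++win_acc;
      }
    }
    // latent refresh: independence proposal from the prior
    draw_latents(Lprop, sig_mean, sig_sd, conc_mean, conc_sd, offset_mean,
                 offset_sd, K, F, P);
    double llL = loglik(a, Lprop, routing, target_mean, target_sd, K, F, P);
    if (std::log(R::unif_rand()) < llL - ll) { L = Lprop; ll = llL; }

    // step-size adaptation during burn-in only
    if (it < burn_in && win_n == 50) {
      double rate = (double)win_acc / win_n;
      step *= std::exp(rate - 0.3);
      step = std::min(5.0, std::max(1e-3, step));
      win_acc = 0; win_n = 0;
    }
    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int k = 0; k < K; ++k) draws(kept, k) = a[k];
      ++kept;
    }
  }
  return List::create(_["draws"] = draws,
                      _["accept_rate"] = (double)acc / tries,
                      _["step"] = step);
}
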