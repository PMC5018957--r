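// Gibbs sampler for the haploid admixture model (STRUCTURE-style, one
// allele draw per accession-site, uncorrelated allele-frequency prior).
// Uses R's RNG so results are reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static int sample_cat(const double *w, int K) {
  double tot = 0.0;
  for (int k = 0; k < K; ++k) tot += w[k];
  double u = unif_rand() * tot, acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// [[Rcpp::export]]
List admixture_gibbs(IntegerMatrix G, int K, int burnin, int reps,
                     double alpha_init, double alpha_prop_sd,
                     double alpha_max, double lambda) {
  const int n = G.nrow(), S = G.ncol();
  const int total = burnin + reps;

  NumericMatrix P(K, S);        // cluster alt-allele frequencies
  NumericMatrix Q(n, K);        // ancestry proportions
  IntegerMatrix z(n, S);        // latent origins
  NumericMatrix Qsum(n, K), Psum(K, S);
  NumericVector Ltrace(total);
  double alpha = alpha_init, alpha_sum = 0.0, Lsum = 0.0;

  GetRNGstate();
  for (int k = 0; k < K; ++k)
    for (int s = 0; s < S; ++s) P(k, s) = R::rbeta(lambda, lambda);
  for (int a = 0; a < n; ++a)
    for (int k = 0; k < K; ++k) Q(a, k) = 1.0 / K;

  std::vector<double> w(K);
  IntegerMatrix nalt(K, S), ntot(K, S);
  NumericMatrix m(n, K);        // per-accession origin counts

  for (int it = 0; it < total; ++it) {
    // z | Q, P  and counts
    std::fill(nalt.begin(), nalt.end(), 0);
    std::fill(ntot.begin(), ntot.end(), 0);
    std::fill(m.begin(), m.end(), 0.0);
    double ll = 0.0;
    for (int a = 0; a < n; ++a) {
      for (int s = 0; s < S; ++s) {
        const int g = G(a, s);
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          const double th = g ? P(k, s) : 1.0 - P(k, s);
          w[k] = Q(a, k) * th;
          tot += w[k];
        }
        const int zz = sample_cat(w.data(), K);
        z(a, s) = zz;
        m(a, zz) += 1.0;
        ntot(zz, s) += 1;
        if (g) nalt(zz, s) += 1;
        ll += std::log(tot);
      }
    }
    Ltrace[it] = ll;
    // P | z
    for (int k = 0; k < K; ++k)
      for (int s = 0; s < S; ++s)
        P(k, s) = R::rbeta(lambda + nalt(k, s),
                           lambda + ntot(k, s) - nalt(k, s));
    // Q | z (Dirichlet via gammas)
    for (int a = 0; a < n; ++a) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        Q(a, k) = R::rgamma(alpha + m(a, k), 1.0);
        tot += Q(a, k);
      }
      for (int k = 0; k < K; ++k) Q(a, k) /= tot;
    }
    // alpha | Q: Metropolis step, uniform prior on (0, alpha_max]
    if (K > 1) {
      const double prop = alpha + norm_rand() * alpha_prop_sd;
      if (prop > 0.0 && prop <= alpha_max) {
        double slq = 0.0;
        for (int a = 0; a < n; ++a)
          for (int k = 0; k < K; ++k) slq += std::log(Q(a, k));
        const double lp_new = n * (R::lgammafn(K * prop) -
                                   K * R::lgammafn(prop)) + (prop - 1.0) * slq;
        const double lp_old = n * (R::lgammafn(K * alpha) -
                                   K * R::lgammafn(alpha)) + (alpha - 1.0) * slq;
        if (std::log(unif_rand()) < lp_new - lp_old) alpha = prop;
      }
    }
    if (it >= burnin) {
      Lsum += ll;
      alpha_sum += alpha;
      for (int a = 0; a < n; ++a)
        for (int k = 0; k < K; ++k) Qsum(a, k) += Q(a, k);
      for (int k = 0; k < K; ++k)
        for (int s = 0; s < S; ++s) Psum(k, s) += P(k, s);
    }
  }
  PutRNGstate();

  for (int a = 0; a < n; ++a)
    for (int k = 0; k < K; ++k) Qsum(a, k) /= reps;
  for (int k = 0; k < K; ++k)
    for (int s = 0; s < S; ++s) Psum(k, s) /= reps;

  return List::create(_["Q"] = Qsum, _["P"] = Psum,
                      _["L"] = Lsum / reps, _["L_trace"] = Ltrace,
                      _["alpha"] = alpha_sum / reps);
}
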