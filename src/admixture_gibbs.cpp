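// Collapsed-state Gibbs sampler for the admixture model with the
// independent (uncorrelated) allele-frequency prior.
//
// Model: each gene copy c of individual i at locus l originates from
// cluster z ~ Categorical(q_i); conditional on origin k the allele is drawn
// from that cluster's locus frequencies p_{k,l}. Priors:
// p_{k,l} ~ Dirichlet(lambda, ..., lambda), q_i ~ Dirichlet(alpha, ...,
// alpha) with a single alpha shared across clusters under a Uniform(0,
// alpha_max) hyperprior updated by a Normal random-walk Metropolis step.
//
// All randomness goes through R's RNG (RNGScope), so set.seed() on the R
// side yields bit-identical traces.

#include <Rcpp.h>
using namespace Rcpp;

static inline int sample_cat(const double *w, int K, double tot) {
  double u = unif_rand() * tot, c = 0.0;
  for (int k = 0; k < K; ++k) {
    c += w[k];
    if (u <= c) return k;
  }
  return K - 1;
}

// Dirichlet draw via normalized gammas; tiny floor guards shape << 1
// underflow so log(q) stays finite in the alpha Metropolis step.
static inline void rdirichlet(double *out, const double *shape, int K) {
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    double g = R::rgamma(shape[k], 1.0);
    if (g < 1e-100) g = 1e-100;
    out[k] = g;
    s += g;
  }
  for (int k = 0; k < K; ++k) out[k] /= s;
}

// geno: 2N x L matrix of 1-based allele indices, 0 = missing (rows 2i, 2i+1
// are individual i's gene copies). n_alleles: per-locus allele count.
// [[Rcpp::export]]
List gibbs_admixture_cpp(IntegerMatrix geno, IntegerVector n_alleles, int K,
                         int n_iter, int burnin, double lambda,
                         double alpha_init, double alpha_max,
                         double alpha_sd) {
  const int twoN = geno.nrow(), L = geno.ncol(), N = twoN / 2;
  if (K < 1) stop("K must be >= 1");
  if (n_iter < 1) stop("n_iter must be >= 1");

  // state: P[l] is K x A_l stored row-major by cluster (index k * A + a)
  std::vector<std::vector<double> > P(L), Psum(L), cnt(L);
  for (int l = 0; l < L; ++l) {
    P[l].assign((size_t)K * n_alleles[l], 0.0);
    Psum[l].assign((size_t)K * n_alleles[l], 0.0);
    cnt[l].assign((size_t)K * n_alleles[l], 0.0);
  }
  NumericMatrix Q(N, K), Qsum(N, K);
  IntegerMatrix z(twoN, L);
  std::vector<double> w(K), shape(K);
  std::vector<double> m((size_t)N * K);
  NumericVector alpha_trace(n_iter), loglik_trace(n_iter);
  double alpha = alpha_init;

  // init: random origins, then one conditional draw of P and Q
  for (int l = 0; l < L; ++l)
    for (int c = 0; c < twoN; ++c)
      z(c, l) = geno(c, l) > 0 ? (int)(unif_rand() * K) : -1;

  double loglik = 0.0;
  for (int sweep = 0; sweep < burnin + n_iter; ++sweep) {
    bool first = sweep == 0;

    if (!first) {
      // (a) origin of every non-missing gene copy
      for (int l = 0; l < L; ++l) {
        const int A = n_alleles[l];
        for (int c = 0; c < twoN; ++c) {
          int a = geno(c, l);
          if (a <= 0) continue;
          const int i = c / 2;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            w[k] = Q(i, k) * P[l][(size_t)k * A + (a - 1)];
            tot += w[k];
          }
          z(c, l) = tot > 0 ? sample_cat(w.data(), K, tot)
                            : (int)(unif_rand() * K);
        }
      }
    }

    // (b) cluster x locus allele frequencies
    for (int l = 0; l < L; ++l) {
      const int A = n_alleles[l];
      std::fill(cnt[l].begin(), cnt[l].end(), 0.0);
      for (int c = 0; c < twoN; ++c) {
        int a = geno(c, l);
        if (a > 0) cnt[l][(size_t)z(c, l) * A + (a - 1)] += 1.0;
      }
      std::vector<double> sh(A);
      for (int k = 0; k < K; ++k) {
        for (int a = 0; a < A; ++a) sh[a] = lambda + cnt[l][(size_t)k * A + a];
        rdirichlet(&P[l][(size_t)k * A], sh.data(), A);
      }
    }

    // (c) per-individual memberships
    std::fill(m.begin(), m.end(), 0.0);
    for (int l = 0; l < L; ++l)
      for (int c = 0; c < twoN; ++c)
        if (geno(c, l) > 0) m[(size_t)(c / 2) * K + z(c, l)] += 1.0;
    for (int i = 0; i < N; ++i) {
      for (int k = 0; k < K; ++k) shape[k] = alpha + m[(size_t)i * K + k];
      rdirichlet(w.data(), shape.data(), K);
      for (int k = 0; k < K; ++k) Q(i, k) = w[k];
    }

    // (d) Metropolis update of alpha under Uniform(0, alpha_max)
    if (K > 1 && alpha_sd > 0) {
      double prop = alpha + norm_rand() * alpha_sd;
      if (prop > 0 && prop < alpha_max) {
        double slq = 0.0;
        for (int i = 0; i < N; ++i)
          for (int k = 0; k < K; ++k) slq += std::log(Q(i, k));
        double lr = N * (R::lgammafn(K * prop) - K * R::lgammafn(prop)) -
                    N * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) +
                    (prop - alpha) * slq;
        if (std::log(unif_rand()) < lr) alpha = prop;
      }
    }

    // complete-data log-likelihood of the allele data given (Z, P)
    loglik = 0.0;
    for (int l = 0; l < L; ++l) {
      const int A = n_alleles[l];
      for (int c = 0; c < twoN; ++c) {
        int a = geno(c, l);
        if (a > 0) loglik += std::log(P[l][(size_t)z(c, l) * A + (a - 1)]);
      }
    }

    if (sweep >= burnin) {
      int t = sweep - burnin;
      alpha_trace[t] = alpha;
      loglik_trace[t] = loglik;
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int l = 0; l < L; ++l)
        for (size_t x = 0; x < P[l].size(); ++x) Psum[l][x] += P[l][x];
    }
  }

  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= n_iter;
  List Pmean(L), Plast(L);
  for (int l = 0; l < L; ++l) {
    const int A = n_alleles[l];
    NumericMatrix pm(K, A), pl(K, A);
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < A; ++a) {
        pm(k, a) = Psum[l][(size_t)k * A + a] / n_iter;
        pl(k, a) = P[l][(size_t)k * A + a];
      }
    Pmean[l] = pm;
    Plast[l] = pl;
  }
  IntegerMatrix z_out(twoN, L);
  for (int l = 0; l < L; ++l)
    for (int c = 0; c < twoN; ++c)
      z_out(c, l) = z(c, l) < 0 ? NA_INTEGER : z(c, l) + 1;

  return List::create(
      _["Q"] = Qsum, _["P"] = Pmean, _["alpha_trace"] = alpha_trace,
      _["loglik_trace"] = loglik_trace, _["z_last"] = z_out,
      _["P_last"] = Plast, _["loglik_last"] = loglik);
}
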