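#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for the multinomial mixed-membership model.
// Tokens are (participant, vocabulary-entry) pairs; missing biomarkers simply
// contribute no token, which is how conditioning on observed data happens.
// Uses R's RNG so set.seed() in R makes runs bit-for-bit reproducible.

static double collapsed_loglik(const std::vector<int> &ndk,
                               const std::vector<int> &nkv,
                               const std::vector<int> &nk,
                               const std::vector<int> &nd,
                               int D, int V, int K,
                               double alpha, double beta) {
  double ll = 0.0;
  const double Vbeta = V * beta, Kalpha = K * alpha;
  ll += K * (R::lgammafn(Vbeta) - V * R::lgammafn(beta));
  for (int k = 0; k < K; ++k) {
    for (int v = 0; v < V; ++v) {
      int c = nkv[k * V + v];
      if (c > 0) ll += R::lgammafn(c + beta) - R::lgammafn(beta);
    }
    ll -= R::lgammafn(nk[k] + Vbeta) - R::lgammafn(Vbeta);
  }
  for (int d = 0; d < D; ++d) {
    if (nd[d] == 0) continue;
    ll += R::lgammafn(Kalpha) - R::lgammafn(nd[d] + Kalpha);
    for (int k = 0; k < K; ++k) {
      int c = ndk[d * K + k];
      if (c > 0) ll += R::lgammafn(c + alpha) - R::lgammafn(alpha);
    }
  }
  return ll;
}

// doc, word are 0-based token vectors of equal length.
// Returns retained posterior samples of phi (K x V) and theta (D x K),
// the collapsed log-likelihood trace, and final counts for audit.
// [[Rcpp::export]]
List cpp_gibbs_fit(IntegerVector doc, IntegerVector word,
                   int D, int V, int K,
                   double alpha, double beta,
                   int n_burn, int n_samples, int thin) {
  const int N = doc.size();
  std::vector<int> z(N), ndk((size_t)D * K, 0), nkv((size_t)K * V, 0),
      nk(K, 0), nd(D, 0);

  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    ndk[(size_t)doc[i] * K + k]++;
    nkv[(size_t)k * V + word[i]]++;
    nk[k]++;
    nd[doc[i]]++;
  }

  const double Vbeta = V * beta;
  const int total = n_burn + n_samples * thin;
  NumericVector loglik(total);
  List phis(n_samples), thetas(n_samples), phi_draws(n_samples);
  std::vector<double> p(K);
  int kept = 0;

  for (int s = 0; s < total; ++s) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      int k = z[i];
      ndk[(size_t)d * K + k]--;
      nkv[(size_t)k * V + w]--;
      nk[k]--;
      double tot = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        tot += (ndk[(size_t)d * K + kk] + alpha) *
               (nkv[(size_t)kk * V + w] + beta) / (nk[kk] + Vbeta);
        p[kk] = tot;
      }
      const double u = unif_rand() * tot;
      k = 0;
      while (k < K - 1 && p[k] < u) ++k;
      z[i] = k;
      ndk[(size_t)d * K + k]++;
      nkv[(size_t)k * V + w]++;
      nk[k]++;
    }
    loglik[s] = collapsed_loglik(ndk, nkv, nk, nd, D, V, K, alpha, beta);
    if (s >= n_burn && (s - n_burn + 1) % thin == 0 && kept < n_samples) {
      NumericMatrix phi(K, V), theta(D, K), phid(K, V);
      for (int k = 0; k < K; ++k) {
        double tot_g = 0.0;
        for (int v = 0; v < V; ++v) {
          phi(k, v) = (nkv[(size_t)k * V + v] + beta) / (nk[k] + Vbeta);
          // a true posterior draw phi | z ~ Dirichlet(n_kv + beta): the
          // conditional-mean samples alone understate posterior width
          double g = R::rgamma(nkv[(size_t)k * V + v] + beta, 1.0);
          phid(k, v) = g;
          tot_g += g;
        }
        for (int v = 0; v < V; ++v) phid(k, v) /= tot_g;
      }
      for (int d = 0; d < D; ++d)
        for (int k = 0; k < K; ++k)
          theta(d, k) = (ndk[(size_t)d * K + k] + alpha) / (nd[d] + K * alpha);
      phis[kept] = phi;
      thetas[kept] = theta;
      phi_draws[kept] = phid;
      ++kept;
    }
  }

  IntegerMatrix ndk_out(D, K), nkv_out(K, V);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) ndk_out(d, k) = ndk[(size_t)d * K + k];
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v) nkv_out(k, v) = nkv[(size_t)k * V + v];

  return List::create(_["phi"] = phis, _["theta"] = thetas,
                      _["phi_draw"] = phi_draws, _["loglik"] = loglik,
                      _["z"] = IntegerVector(z.begin(), z.end()),
                      _["n_dk"] = ndk_out, _["n_kv"] = nkv_out);
}

// One sweep over an explicit state, for unit-level conservation checks.
// [[Rcpp::export]]
List cpp_gibbs_sweep(IntegerVector doc, IntegerVector word, IntegerVector z0,
                     int D, int V, int K, double alpha, double beta) {
  const int N = doc.size();
  std::vector<int> z(z0.begin(), z0.end());
  std::vector<int> ndk((size_t)D * K, 0), nkv((size_t)K * V, 0), nk(K, 0);
  for (int i = 0; i < N; ++i) {
    ndk[(size_t)doc[i] * K + z[i]]++;
    nkv[(size_t)z[i] * V + word[i]]++;
    nk[z[i]]++;
  }
  const double Vbeta = V * beta;
  std::vector<double> p(K);
  for (int i = 0; i < N; ++i) {
    const int d = doc[i], w = word[i];
    int k = z[i];
    ndk[(size_t)d * K + k]--;
    nkv[(size_t)k * V + w]--;
    nk[k]--;
    double tot = 0.0;
    for (int kk = 0; kk < K; ++kk) {
      tot += (ndk[(size_t)d * K + kk] + alpha) *
             (nkv[(size_t)kk * V + w] + beta) / (nk[kk] + Vbeta);
      p[kk] = tot;
    }
    const double u = unif_rand() * tot;
    k = 0;
    while (k < K - 1 && p[k] < u) ++k;
    z[i] = k;
    ndk[(size_t)d * K + k]++;
    nkv[(size_t)k * V + w]++;
    nk[k]++;
  }
  IntegerMatrix ndk_out(D, K), nkv_out(K, V);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) ndk_out(d, k) = ndk[(size_t)d * K + k];
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v) nkv_out(k, v) = nkv[(size_t)k * V + v];
  return List::create(_["z"] = IntegerVector(z.begin(), z.end()),
                      _["n_dk"] = ndk_out, _["n_kv"] = nkv_out,
                      _["n_k"] = IntegerVector(nk.begin(), nk.end()));
}

// [[Rcpp::export]]
double cpp_collapsed_loglik(IntegerVector doc, IntegerVector word,
                            IntegerVector z, int D, int V, int K,
                            double alpha, double beta) {
  const int N = doc.size();
  std::vector<int> ndk((size_t)D * K, 0), nkv((size_t)K * V, 0), nk(K, 0),
      nd(D, 0);
  for (int i = 0; i < N; ++i) {
    ndk[(size_t)doc[i] * K + z[i]]++;
    nkv[(size_t)z[i] * V + word[i]]++;
    nk[z[i]]++;
    nd[doc[i]]++;
  }
  return collapsed_loglik(ndk, nkv, nk, nd, D, V, K, alpha, beta);
}

// Dense linear assignment (Jonker-Volgenant shortest augmenting path),
// minimizing total cost over bijections. Deterministic scan order gives a
// fixed tie-break. Returns 1-based column assigned to each row.
// [[Rcpp::export]]
IntegerVector cpp_lap(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<bool> used(n + 1, false);
    do {
      used[j0] = true;
      const int i0 = p[j0];
      int j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      const int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector assign(n);
  for (int j = 1; j <= n; ++j) assign[p[j] - 1] = j;
  return assign;
}
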