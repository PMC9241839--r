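#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sweeps for source attribution of a single sink.
//
// Reads are assigned to V known sources plus one learned "unknown" source
// (index V). Source compositions are integrated out (collapsed Dirichlet-
// multinomial): a known source's posterior composition is informed by its
// observed counts m plus the sink reads currently assigned to it; the
// unknown source starts from zero counts. Full conditional for read i
// carrying taxon t:
//   P(z_i = v | z_-i) proportional to
//     (m_vt + n_vt^-i + alpha_v) / (M_v + n_v^-i + T * alpha_v)
//       * (n_v^-i + beta)
// with alpha_v = alpha_known for known sources (m_vt their counts) and
// alpha_v = alpha_unknown, m = 0 for the unknown source.
// Each restart: uniform random initial assignment, `burnins` full sweeps,
// then one retained draw of the mixing proportions n_v / N.
// Uses R's RNG, so results are reproducible under set.seed().
//
// [[Rcpp::export]]
NumericMatrix gibbs_restarts_cpp(IntegerVector sink_taxa,
                                 NumericMatrix source_counts,
                                 double alpha_known,
                                 double alpha_unknown,
                                 double beta,
                                 int burnins,
                                 int restarts) {
  const int N = sink_taxa.size();
  const int V = source_counts.nrow();
  const int T = source_counts.ncol();
  const int K = V + 1;
  NumericMatrix out(restarts, K);
  std::vector<double> alpha(K, alpha_known);
  alpha[V] = alpha_unknown;

  // taxon-major layout: mt[t*K + v] = m_vt + n_vt + alpha_v (updated with
  // sink assignments in place); denom[v] = M_v + n_v + T * alpha_v
  std::vector<double> base(T * K);
  for (int t = 0; t < T; ++t) {
    for (int v = 0; v < V; ++v) base[t * K + v] = source_counts(v, t) + alpha[v];
    base[t * K + V] = alpha[V];
  }
  std::vector<double> denom_base(K, T * alpha_known);
  denom_base[V] = T * alpha_unknown;
  for (int v = 0; v < V; ++v)
    for (int t = 0; t < T; ++t) denom_base[v] += source_counts(v, t);

  std::vector<int> z(N);
  std::vector<double> n_v(K), prob(K), mt(T * K), denom(K);
  const int* taxa = INTEGER(sink_taxa);

  for (int r = 0; r < restarts; ++r) {
    std::fill(n_v.begin(), n_v.end(), 0.0);
    std::copy(base.begin(), base.end(), mt.begin());
    std::copy(denom_base.begin(), denom_base.end(), denom.begin());
    for (int i = 0; i < N; ++i) {
      int v = (int)(unif_rand() * K);
      if (v >= K) v = K - 1;
      z[i] = v;
      n_v[v] += 1.0;
      mt[taxa[i] * K + v] += 1.0;
      denom[v] += 1.0;
    }
    for (int sweep = 0; sweep < burnins; ++sweep) {
      for (int i = 0; i < N; ++i) {
        const int old = z[i];
        double* row = &mt[taxa[i] * K];
        n_v[old] -= 1.0;
        row[old] -= 1.0;
        denom[old] -= 1.0;
        double tot = 0.0;
        for (int v = 0; v < K; ++v) {
          prob[v] = row[v] / denom[v] * (n_v[v] + beta);
          tot += prob[v];
        }
        double uu = unif_rand() * tot;
        int v = 0;
        double c = prob[0];
        while (uu > c && v < K - 1) { ++v; c += prob[v]; }
        z[i] = v;
        n_v[v] += 1.0;
        row[v] += 1.0;
        denom[v] += 1.0;
      }
    }
    for (int v = 0; v < K; ++v) out(r, v) = n_v[v] / N;
  }
  return out;
}
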