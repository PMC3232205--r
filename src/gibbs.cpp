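#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs sweep for the Bio-LDA (author-topic with journal stamps)
// model. Each token carries a latent (bio-term, topic) pair; the pair is
// resampled jointly from the collapsed conditional
//   P(x = b, z = t | rest) \propto (n_bt + alpha) / (n_b + T alpha)
//                          * (n_tw + beta)  / (n_t + W beta)
//                          * (n_tj + mu)    / (n_t + J mu)
// with the current token excluded from all counts, and b restricted to the
// document's tagged bio-term set (uniform prior over that set).
//
// All indices are 0-based. Randomness comes from R's RNG (unif_rand), so a
// set.seed() in the calling R code makes the run reproducible.

// [[Rcpp::export]]
List gibbs_sampler_cpp(IntegerVector doc_of, IntegerVector word_of,
                       IntegerVector journal_of_doc, List bd,
                       int B, int T, int W, int J,
                       double alpha, double beta, double mu,
                       int sweeps, bool keep_trace) {
  const int N = doc_of.size();
  const int D = bd.size();

  std::vector< std::vector<int> > bdv(D);
  for (int d = 0; d < D; ++d) bdv[d] = as< std::vector<int> >(bd[d]);

  IntegerMatrix n_bt(B, T), n_tw(T, W), n_tj(T, J);
  std::vector<int> n_b(B, 0), n_t(T, 0);
  IntegerVector z(N), x(N);

  // random initialisation: bio-term uniform over the document set, topic
  // uniform over 1..T
  for (int i = 0; i < N; ++i) {
    const int d = doc_of[i];
    const std::vector<int>& bs = bdv[d];
    int b = bs[std::min((int)(unif_rand() * bs.size()), (int)bs.size() - 1)];
    int t = std::min((int)(unif_rand() * T), T - 1);
    x[i] = b; z[i] = t;
    const int w = word_of[i], j = journal_of_doc[d];
    ++n_bt(b, t); ++n_b[b]; ++n_tw(t, w); ++n_tj(t, j); ++n_t[t];
  }

  IntegerMatrix trace;
  if (keep_trace) trace = IntegerMatrix(sweeps, N);

  std::vector<double> cum;
  for (int s = 0; s < sweeps; ++s) {
    for (int i = 0; i < N; ++i) {
      const int d = doc_of[i], w = word_of[i], j = journal_of_doc[d];
      const int b0 = x[i], t0 = z[i];
      --n_bt(b0, t0); --n_b[b0]; --n_tw(t0, w); --n_tj(t0, j); --n_t[t0];

      const std::vector<int>& bs = bdv[d];
      const int K = (int)bs.size() * T;
      if ((int)cum.size() < K) cum.resize(K);
      double tot = 0.0;
      int k = 0;
      for (size_t a = 0; a < bs.size(); ++a) {
        const int b = bs[a];
        const double denb = n_b[b] + T * alpha;
        for (int t = 0; t < T; ++t) {
          const double p = (n_bt(b, t) + alpha) / denb
                         * (n_tw(t, w) + beta) / (n_t[t] + W * beta)
                         * (n_tj(t, j) + mu)  / (n_t[t] + J * mu);
          tot += p;
          cum[k++] = tot;
        }
      }
      const double u = unif_rand() * tot;
      int sel = (int)(std::lower_bound(cum.begin(), cum.begin() + K, u)
                      - cum.begin());
      if (sel >= K) sel = K - 1;
      const int b1 = bs[sel / T], t1 = sel % T;
      x[i] = b1; z[i] = t1;
      ++n_bt(b1, t1); ++n_b[b1]; ++n_tw(t1, w); ++n_tj(t1, j); ++n_t[t1];
      if (keep_trace) trace(s, i) = t1;
    }
  }

  List out = List::create(_["z"] = z, _["x"] = x,
                          _["n_bt"] = n_bt, _["n_tw"] = n_tw,
                          _["n_tj"] = n_tj);
  if (keep_trace) out["trace_z"] = trace;
  return out;
}
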