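// Second-order biased random walks and skip-gram-with-negative-sampling
// training. Both use R's RNG stream (set.seed() in R makes them
// deterministic) and run single-threaded.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline bool contains_sorted(const std::vector<int>& v, int x) {
  return std::binary_search(v.begin(), v.end(), x);
}

// Sample an index proportional to 'w' (unnormalized, all >= 0, sum > 0).
static int sample_weighted(const std::vector<double>& w, double total) {
  double r = unif_rand() * total;
  double acc = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    acc += w[i];
    if (r <= acc) return (int)i;
  }
  return (int)w.size() - 1;
}

// nbrs: per-node sorted 1-based neighbor indices; wts: matching weights.
// Returns walks_per_node * m walks (each an IntegerVector of 1-based ids),
// grouped by repetition then by start node.
// [[Rcpp::export]]
List cpp_biased_walks(List nbrs, List wts, double p, double q,
                      int walks_per_node, int walk_length) {
  int m = nbrs.size();
  std::vector<std::vector<int>> nb(m);
  std::vector<std::vector<double>> wt(m);
  for (int i = 0; i < m; ++i) {
    nb[i] = as<std::vector<int>>(nbrs[i]);
    wt[i] = as<std::vector<double>>(wts[i]);
  }
  List out(walks_per_node * m);
  int oi = 0;
  std::vector<double> bias;
  for (int rep = 0; rep < walks_per_node; ++rep) {
    for (int s = 0; s < m; ++s) {
      IntegerVector walk(walk_length);
      int cur = s, prev = -1;
      walk[0] = cur + 1;
      for (int step = 1; step < walk_length; ++step) {
        const std::vector<int>& cn = nb[cur];
        const std::vector<double>& cw = wt[cur];
        if (cn.empty()) {  // cannot happen on a connected graph
          walk = walk[Range(0, step - 1)];
          break;
        }
        int nxt;
        if (prev < 0) {
          double tot = 0.0;
          for (double w : cw) tot += w;
          nxt = cn[sample_weighted(cw, tot)] - 1;
        } else {
          bias.assign(cn.size(), 0.0);
          double tot = 0.0;
          const std::vector<int>& pn = nb[prev];
          for (size_t j = 0; j < cn.size(); ++j) {
            int x = cn[j] - 1;
            double w = cw[j];
            if (x == prev) w /= p;
            else if (!contains_sorted(pn, cn[j])) w /= q;
            bias[j] = w;
            tot += w;
          }
          nxt = cn[sample_weighted(bias, tot)] - 1;
        }
        prev = cur;
        cur = nxt;
        walk[step] = cur + 1;
      }
      out[oi++] = walk;
    }
  }
  return out;
}

// Skip-gram with negative sampling over node walks. Dynamic window
// shrinkage (uniform 1..window per center token) and linear learning-rate
// decay, as in the reference word2vec trainer. Negative-sampling
// distribution is the corpus unigram frequency raised to 0.75.
// Returns the m x dim input-embedding matrix.
// [[Rcpp::export]]
NumericMatrix cpp_sgns(List walks, int m, int dim, int window,
                       int epochs, int negative, double alpha) {
  int n_walks = walks.size();
  std::vector<std::vector<int>> W(n_walks);
  long long total_tokens = 0;
  std::vector<double> freq(m, 0.0);
  for (int i = 0; i < n_walks; ++i) {
    W[i] = as<std::vector<int>>(walks[i]);
    total_tokens += (long long)W[i].size();
    for (int v : W[i]) freq[v - 1] += 1.0;
  }
  std::vector<double> cum(m);
  double tot = 0.0;
  for (int i = 0; i < m; ++i) { tot += std::pow(freq[i], 0.75); cum[i] = tot; }

  std::vector<double> syn0((size_t)m * dim), syn1((size_t)m * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (unif_rand() - 0.5) / dim;
  }

  const double alpha_min = alpha * 1e-4;
  long long processed = 0;
  long long budget = (long long)epochs * total_tokens;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int wi = 0; wi < n_walks; ++wi) {
      const std::vector<int>& walk = W[wi];
      int n = (int)walk.size();
      for (int c = 0; c < n; ++c) {
        double lr = alpha * (1.0 - (double)processed / (double)budget);
        if (lr < alpha_min) lr = alpha_min;
        ++processed;
        int b = 1 + (int)(unif_rand() * window);  // dynamic window size
        if (b > window) b = window;
        int center = walk[c] - 1;
        double* v = &syn0[(size_t)center * dim];
        for (int o = -b; o <= b; ++o) {
          if (o == 0) continue;
          int cp = c + o;
          if (cp < 0 || cp >= n) continue;
          int ctx = walk[cp] - 1;
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int s = 0; s <= negative; ++s) {
            int target;
            double label;
            if (s == 0) { target = ctx; label = 1.0; }
            else {
              double r = unif_rand() * tot;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), r)
                             - cum.begin());
              if (target >= m) target = m - 1;
              if (target == ctx) continue;
              label = 0.0;
            }
            double* u = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v[d] * u[d];
            double g;
            if (dot > 6.0) g = (label - 1.0) * lr;
            else if (dot < -6.0) g = label * lr;
            else g = (label - 1.0 / (1.0 + std::exp(-dot))) * lr;
            for (int d = 0; d < dim; ++d) grad[d] += g * u[d];
            for (int d = 0; d < dim; ++d) u[d] += g * v[d];
          }
          for (int d = 0; d < dim; ++d) v[d] += grad[d];
        }
      }
    }
  }
  NumericMatrix out(m, dim);
  for (int i = 0; i < m; ++i)
    for (int d = 0; d < dim; ++d) out(i, d) = syn0[(size_t)i * dim + d];
  return out;
}
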