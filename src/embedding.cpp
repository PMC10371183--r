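#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// splitmix64: fast deterministic RNG independent of platform and of R's
// RNG stream, so walk generation and training are byte-reproducible.
struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(unif() * n); }
};

// Uniform random walks of fixed length from every node, walks_per_node each.
// Adjacency in CSR form (0-based). Returns an integer matrix, one walk per
// row, entries 0-based node indices.
// [[Rcpp::export]]
IntegerMatrix cpp_generate_walks(IntegerVector offsets, IntegerVector neighbors,
                                 int walks_per_node, int walk_length,
                                 double seed) {
  const int n = offsets.size() - 1;
  IntegerMatrix walks(n * walks_per_node, walk_length);
  SplitMix64 rng((uint64_t)seed + 0x51ED270B);
  int row = 0;
  for (int w = 0; w < walks_per_node; ++w) {
    for (int v = 0; v < n; ++v) {
      int cur = v;
      walks(row, 0) = cur;
      for (int s = 1; s < walk_length; ++s) {
        int deg = offsets[cur + 1] - offsets[cur];
        if (deg <= 0) stop("internal error: node with zero neighbors in walk");
        cur = neighbors[offsets[cur] + rng.below(deg)];
        walks(row, s) = cur;
      }
      ++row;
    }
  }
  return walks;
}

// Precomputed sigmoid, word2vec style: 4096 bins over [-8, 8], saturated
// outside. The training loop only needs ~3 significant digits here.
struct SigmoidTable {
  static const int kBins = 4096;
  float table[kBins];
  SigmoidTable() {
    for (int i = 0; i < kBins; ++i) {
      double x = (i + 0.5) / kBins * 16.0 - 8.0;
      table[i] = (float)(1.0 / (1.0 + std::exp(-x)));
    }
  }
  float operator()(float x) const {
    if (x >= 8.0f) return 1.0f;
    if (x <= -8.0f) return 0.0f;
    int i = (int)((x + 8.0f) * (kBins / 16.0f));
    if (i < 0) i = 0;
    if (i >= kBins) i = kBins - 1;
    return table[i];
  }
};
static const SigmoidTable sigmoid;

// Skip-gram with negative sampling over walk "sentences". Single-threaded
// SGD with linear learning-rate decay; negatives drawn from the corpus
// unigram distribution raised to the 0.75 power. Returns dim x n center
// matrix (column per node). epochs = 0 returns the seeded initialization.
// [[Rcpp::export]]
NumericMatrix cpp_train_sgns(IntegerMatrix walks, int n_nodes, int dim,
                             int window, int negatives, int epochs,
                             double learning_rate, double seed,
                             bool report_loss = false) {
  if (dim < 2) stop("configuration error: dimension must be >= 2");
  const int n_walks = walks.nrow(), wl = walks.ncol();
  SplitMix64 rng((uint64_t)seed + 0xA5A5A5A5);

  // Row-major copy of the walk corpus: the training loop scans each walk
  // left to right, which is a strided access pattern on R's column-major
  // matrix storage.
  std::vector<int> corpus((size_t)n_walks * wl);
  for (int r = 0; r < n_walks; ++r)
    for (int s = 0; s < wl; ++s) corpus[(size_t)r * wl + s] = walks(r, s);

  // Single-precision weights, as in the reference word2vec implementation:
  // SGNS gradients tolerate float rounding and the narrower type doubles
  // the SIMD lane count in the hot loop.
  std::vector<float> W((size_t)n_nodes * dim), C((size_t)n_nodes * dim, 0.0f);
  for (size_t i = 0; i < W.size(); ++i)
    W[i] = (float)((rng.unif() - 0.5) / dim);

  // Unigram^0.75 cumulative table for negative sampling.
  std::vector<double> freq(n_nodes, 0.0);
  for (int r = 0; r < n_walks; ++r)
    for (int s = 0; s < wl; ++s) freq[walks(r, s)] += 1.0;
  std::vector<double> cum(n_nodes);
  double tot = 0.0;
  for (int v = 0; v < n_nodes; ++v) { tot += std::pow(freq[v], 0.75); cum[v] = tot; }
  auto sample_neg = [&]() {
    double u = rng.unif() * tot;
    int lo = 0, hi = n_nodes - 1;
    while (lo < hi) { int mid = (lo + hi) / 2; if (cum[mid] < u) lo = mid + 1; else hi = mid; }
    return lo;
  };

  // Total center-context pairs per epoch, for the linear LR decay.
  double pairs_per_epoch = 0.0;
  for (int s = 0; s < wl; ++s) {
    int ctx = std::min(s, window) + std::min(wl - 1 - s, window);
    pairs_per_epoch += ctx;
  }
  pairs_per_epoch *= n_walks;
  const double total_pairs = pairs_per_epoch * std::max(epochs, 1);
  const double min_lr = learning_rate * 1e-4;

  std::vector<float> grad(dim);
  double pair_count = 0.0;
  NumericVector epoch_loss(epochs > 0 ? epochs : 0);

  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0, loss_n = 0.0;
    for (int r = 0; r < n_walks; ++r) {
      const int *walk = &corpus[(size_t)r * wl];
      for (int s = 0; s < wl; ++s) {
        int center = walk[s];
        float *wc = &W[(size_t)center * dim];
        int lo = std::max(0, s - window), hi = std::min(wl - 1, s + window);
        for (int t = lo; t <= hi; ++t) {
          if (t == s) continue;
          double lr = learning_rate * (1.0 - pair_count / total_pairs);
          if (lr < min_lr) lr = min_lr;
          pair_count += 1.0;
          const float lrf = (float)lr;
          std::fill(grad.begin(), grad.end(), 0.0f);
          for (int k = 0; k <= negatives; ++k) {
            int target; float label;
            if (k == 0) { target = walk[t]; label = 1.0f; }
            else { target = sample_neg(); label = 0.0f; }
            float *ct = &C[(size_t)target * dim];
            float dot = 0.0f;
            for (int d = 0; d < dim; ++d) dot += wc[d] * ct[d];
            float p = sigmoid(dot);
            if (report_loss) {
              loss_sum += label == 1.0f
                ? -std::log(std::max((double)p, 1e-12))
                : -std::log(std::max(1.0 - (double)p, 1e-12));
              loss_n += 1.0;
            }
            float g = (p - label) * lrf;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * ct[d];
              ct[d] -= g * wc[d];
            }
          }
          for (int d = 0; d < dim; ++d) wc[d] -= grad[d];
        }
      }
    }
    if (report_loss && epochs > 0) epoch_loss[ep] = loss_sum / std::max(loss_n, 1.0);
  }

  NumericMatrix out(dim, n_nodes);
  for (int v = 0; v < n_nodes; ++v)
    for (int d = 0; d < dim; ++d) out(d, v) = W[(size_t)v * dim + d];
  if (report_loss) out.attr("epoch_loss") = epoch_loss;
  return out;
}
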