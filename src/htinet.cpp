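#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Deterministic, self-contained RNG so walk simulation and embedding
// training reproduce exactly for a given integer seed, independent of R's
// RNG state. splitmix64 whitens the seed, xorshift64* generates the stream.
namespace {

inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    s = splitmix64(x);
    if (s == 0) s = 0x106689D45497FDB5ULL;
  }
  inline uint64_t next() {
    uint64_t x = s;
    x ^= x << 13;
    x ^= x >> 7;
    x ^= x << 17;
    s = x;
    return x * 0x2545F4914F6CDD1DULL;
  }
  inline double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  inline int below(int n) { return (int)(next() % (uint64_t)n); }
};

inline bool has_edge(const IntegerVector& offsets, const IntegerVector& nbrs,
                     int a, int b) {
  // neighbors are sorted within each node: binary search
  int lo = offsets[a], hi = offsets[a + 1];
  const int* base = nbrs.begin();
  return std::binary_search(base + lo, base + hi, b);
}

}  // namespace

// Second-order biased random walks over a CSR adjacency (0-based node
// indices, neighbors sorted per node). One walk per entry of `starts`,
// each of length at most `walk_length` (shorter only on dead ends).
// Transition weights: w/p back to the previous node, w to common
// neighbors of the previous node, w/q otherwise; the first step is a
// plain weighted draw.
// [[Rcpp::export]]
List cpp_simulate_walks(IntegerVector offsets, IntegerVector neighbors,
                        NumericVector weights, IntegerVector starts,
                        int walk_length, double p, double q, double seed) {
  if (walk_length < 2) stop("walk_length must be >= 2");
  if (p <= 0 || q <= 0) stop("p and q must be positive");
  Rng rng((uint64_t)seed);
  int n_walks = starts.size();
  List out(n_walks);
  std::vector<int> walk;
  std::vector<double> cum;
  walk.reserve(walk_length);

  for (int wI = 0; wI < n_walks; ++wI) {
    int u = starts[wI];
    walk.clear();
    walk.push_back(u);
    int prev = -1, cur = u;
    for (int step = 1; step < walk_length; ++step) {
      int lo = offsets[cur], hi = offsets[cur + 1];
      int deg = hi - lo;
      if (deg == 0) break;  // dead end (isolated start)
      double total = 0.0;
      cum.resize(deg);
      for (int j = 0; j < deg; ++j) {
        int x = neighbors[lo + j];
        double w = weights[lo + j];
        if (prev >= 0) {
          if (x == prev) w /= p;
          else if (!has_edge(offsets, neighbors, prev, x)) w /= q;
          // else d(prev, x) == 1: weight unchanged
        }
        total += w;
        cum[j] = total;
      }
      double r = rng.unif() * total;
      int k = (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
      if (k >= deg) k = deg - 1;
      int nxt = neighbors[lo + k];
      walk.push_back(nxt);
      prev = cur;
      cur = nxt;
    }
    out[wI] = IntegerVector(walk.begin(), walk.end());
  }
  return out;
}

// Skip-gram with negative sampling over a walk corpus (word2vec-style):
// dynamic context window, unigram^(3/4) negative-sampling table, linear
// learning-rate decay, single-threaded for exact reproducibility.
// `corpus` is a list of integer vectors of 0-based node indices.
// Returns the input-vector matrix (n_nodes x dim).
// [[Rcpp::export]]
NumericMatrix cpp_train_sgns(List corpus, int n_nodes, int dim, int window,
                             int negative, int epochs, double alpha0,
                             double seed) {
  if (dim < 2) stop("dim must be >= 2");
  if (window < 1 || negative < 1 || epochs < 1) {
    stop("window, negative and epochs must be >= 1");
  }
  int n_sent = corpus.size();
  if (n_sent == 0) stop("empty walk corpus");

  // flatten corpus, count tokens
  std::vector<std::vector<int>> sents(n_sent);
  std::vector<double> cnt(n_nodes, 0.0);
  long long total_tokens = 0;
  for (int s = 0; s < n_sent; ++s) {
    IntegerVector w = corpus[s];
    sents[s].assign(w.begin(), w.end());
    for (int x : sents[s]) {
      if (x < 0 || x >= n_nodes) stop("node index out of range in corpus");
      cnt[x] += 1.0;
      ++total_tokens;
    }
  }

  // unigram^0.75 table for negative sampling
  const int TABLE = 1 << 17;
  std::vector<int> table(TABLE);
  {
    double z = 0.0;
    for (int i = 0; i < n_nodes; ++i) z += std::pow(cnt[i], 0.75);
    double acc = std::pow(cnt[0], 0.75) / z;
    int i = 0;
    for (int t = 0; t < TABLE; ++t) {
      table[t] = i;
      if ((double)(t + 1) / TABLE > acc && i < n_nodes - 1) {
        ++i;
        acc += std::pow(cnt[i], 0.75) / z;
      }
    }
  }

  Rng rng((uint64_t)seed);
  std::vector<double> syn0((size_t)n_nodes * dim);
  std::vector<double> syn1((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (rng.unif() - 0.5) / dim;
  }

  std::vector<double> neu1e(dim);
  const double total_work = (double)total_tokens * epochs;
  long long processed = 0;
  double alpha = alpha0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const std::vector<int>& sen = sents[s];
      int len = (int)sen.size();
      for (int i = 0; i < len; ++i) {
        ++processed;
        if ((processed & 0x3FF) == 0) {
          alpha = alpha0 * (1.0 - (double)processed / (total_work + 1.0));
          if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
          Rcpp::checkUserInterrupt();
        }
        int word = sen[i];
        int b = rng.below(window);  // dynamic window shrink
        for (int j = i - window + b; j <= i + window - b; ++j) {
          if (j == i || j < 0 || j >= len) continue;
          int ctx = sen[j];
          double* v_in = &syn0[(size_t)ctx * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = word;
              label = 1.0;
            } else {
              target = table[rng.below(TABLE)];
              if (target == word) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int c = 0; c < dim; ++c) f += v_in[c] * v_out[c];
            double g;
            if (f > 6.0) g = (label - 1.0) * alpha;
            else if (f < -6.0) g = label * alpha;
            else g = (label - 1.0 / (1.0 + std::exp(-f))) * alpha;
            for (int c = 0; c < dim; ++c) neu1e[c] += g * v_out[c];
            for (int c = 0; c < dim; ++c) v_out[c] += g * v_in[c];
          }
          for (int c = 0; c < dim; ++c) v_in[c] += neu1e[c];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i) {
    for (int c = 0; c < dim; ++c) out(i, c) = syn0[(size_t)i * dim + c];
  }
  return out;
}
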