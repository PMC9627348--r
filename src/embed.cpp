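// Second-order (p/q-biased) random walks and skip-gram with negative
// sampling. Single-threaded with a self-contained xorshift RNG so a given
// seed reproduces walks and embeddings bit-for-bit.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed into xorshift128+ state
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    auto mix = [](uint64_t z) {
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      return z ^ (z >> 31);
    };
    s0 = mix(z);
    s1 = mix(z + 0x9E3779B97F4A7C15ULL);
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  int below(int n) { return (int)(unif() * n); }
};

// is `x` among the sorted neighbors of `node`?
inline bool has_edge(const IntegerVector& off, const IntegerVector& nbr,
                     int node, int x) {
  int lo = off[node], hi = off[node + 1];
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (nbr[mid] < x) lo = mid + 1; else hi = mid;
  }
  return lo < off[node + 1] && nbr[lo] == x;
}

inline double sigmoid(double x) {
  if (x > 8.0) x = 8.0;
  if (x < -8.0) x = -8.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// Biased random walks. `offsets` (n+1) and `neighbors` (0-based, sorted per
// node) give CSR adjacency. Returns a list of 1-based integer walks:
// walks_per_node passes over all start nodes in index order.
// [[Rcpp::export(name = "cpp_sample_walks")]]
List cpp_sample_walks(IntegerVector offsets, IntegerVector neighbors,
                      double p, double q, int walk_length, int walks_per_node,
                      double seed) {
  int n = offsets.size() - 1;
  Rng rng((uint64_t)seed);
  List out(n * walks_per_node);
  int w = 0;
  std::vector<int> walk;
  std::vector<double> cum;
  walk.reserve(walk_length);
  for (int rep = 0; rep < walks_per_node; ++rep) {
    for (int start = 0; start < n; ++start) {
      walk.clear();
      walk.push_back(start);
      int prev = -1, cur = start;
      while ((int)walk.size() < walk_length) {
        int lo = offsets[cur], hi = offsets[cur + 1];
        int deg = hi - lo;
        if (deg == 0) break;  // isolated node: dead end
        int nxt;
        if (prev < 0) {
          nxt = neighbors[lo + rng.below(deg)];
        } else {
          cum.resize(deg);
          double tot = 0.0;
          for (int i = 0; i < deg; ++i) {
            int x = neighbors[lo + i];
            double wgt;
            if (x == prev) wgt = 1.0 / p;
            else if (has_edge(offsets, neighbors, prev, x)) wgt = 1.0;
            else wgt = 1.0 / q;
            tot += wgt;
            cum[i] = tot;
          }
          double u = rng.unif() * tot;
          int i = 0;
          while (i < deg - 1 && cum[i] <= u) ++i;
          nxt = neighbors[lo + i];
        }
        walk.push_back(nxt);
        prev = cur;
        cur = nxt;
      }
      IntegerVector iv(walk.size());
      for (size_t i = 0; i < walk.size(); ++i) iv[i] = walk[i] + 1;
      out[w++] = iv;
    }
  }
  return out;
}

// Skip-gram with negative sampling over a walk corpus (1-based node indices).
// Every in-window (center, context) pair is one positive example; negatives
// are drawn from the unigram noise CDF. Learning rate decays linearly from
// alpha to alpha_min over all pairs. Returns the input (center) vectors,
// vocab x dim.
// [[Rcpp::export(name = "cpp_train_sgns")]]
NumericMatrix cpp_train_sgns(List walks, int vocab_size, int dim, int window,
                             int negatives, int epochs, double alpha,
                             double alpha_min, NumericVector noise_cdf,
                             double seed) {
  Rng rng((uint64_t)seed);
  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // count positive pairs once for the lr schedule
  long long total_pairs = 0;
  int n_walks = walks.size();
  for (int wi = 0; wi < n_walks; ++wi) {
    IntegerVector wk = walks[wi];
    int L = wk.size();
    for (int t = 0; t < L; ++t) {
      int a = std::max(0, t - window), b = std::min(L - 1, t + window);
      total_pairs += (b - a);  // excludes j = 0
    }
  }
  total_pairs *= epochs;

  std::vector<double> neu1e(dim);
  long long done = 0;
  for (int ep = 0; ep < epochs && total_pairs > 0; ++ep) {
    for (int wi = 0; wi < n_walks; ++wi) {
      IntegerVector wk = walks[wi];
      int L = wk.size();
      for (int t = 0; t < L; ++t) {
        int center = wk[t] - 1;
        double* vc = &syn0[(size_t)center * dim];
        int a = std::max(0, t - window), b = std::min(L - 1, t + window);
        for (int s = a; s <= b; ++s) {
          if (s == t) continue;
          double lr = alpha - (alpha - alpha_min) * ((double)done / total_pairs);
          ++done;
          int context = wk[s] - 1;
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d <= negatives; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = context;
              label = 1.0;
            } else {
              double u = rng.unif();
              int lo = 0, hi = vocab_size - 1;
              while (lo < hi) {
                int mid = (lo + hi) / 2;
                if (noise_cdf[mid] < u) lo = mid + 1; else hi = mid;
              }
              target = lo;
              if (target == context) continue;  // skip accidental positive
              label = 0.0;
            }
            double* ut = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += ut[k] * vc[k];
            double g = (label - sigmoid(f)) * lr;
            for (int k = 0; k < dim; ++k) neu1e[k] += g * ut[k];
            for (int k = 0; k < dim; ++k) ut[k] += g * vc[k];
          }
          for (int k = 0; k < dim; ++k) vc[k] += neu1e[k];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int k = 0; k < dim; ++k) out(v, k) = syn0[(size_t)v * dim + k];
  return out;
}
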