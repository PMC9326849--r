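// Skip-gram with negative sampling over walk corpora.
// Single-threaded SGD so a fixed seed gives bit-reproducible vectors.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  uint64_t bounded(uint64_t n) { return next() % n; }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export]]
List sgns_train(List walks, int vocab, int dim, int window,
                         int negatives, int epochs, double alpha0,
                         NumericVector counts, int seed, double sample,
                         IntegerVector node_type) {
  if (vocab <= 0 || dim <= 0) stop("vocab and dim must be positive");
  if (node_type.size() != vocab) stop("node_type must have one entry per node");
  const double alpha_min = 1e-4;

  // noise distribution: unigram counts ^ 0.75, sampled by binary search.
  // With typed (metapath2vec++-style) sampling, node_type holds a type
  // index per node and negatives are drawn within the positive's type;
  // with homogeneous sampling all entries are 0.
  int n_types = 0;
  for (int i = 0; i < vocab; ++i) {
    if (node_type[i] < 0) stop("node_type entries must be >= 0");
    if (node_type[i] + 1 > n_types) n_types = node_type[i] + 1;
  }
  // per-type member list and cumulative weights
  std::vector<std::vector<int> > members(n_types);
  std::vector<std::vector<double> > cums(n_types);
  for (int i = 0; i < vocab; ++i) members[node_type[i]].push_back(i);
  for (int t = 0; t < n_types; ++t) {
    double acc = 0.0;
    cums[t].reserve(members[t].size());
    for (size_t j = 0; j < members[t].size(); ++j) {
      acc += std::pow(counts[members[t][j]], 0.75);
      cums[t].push_back(acc);
    }
  }

  XorShift64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  std::vector<double> syn0(static_cast<size_t>(vocab) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (rng.unif() - 0.5) / dim;
  }

  // pre-extract walks as int vectors
  std::vector<std::vector<int> > ws;
  ws.reserve(walks.size());
  long long total_tokens = 0;
  for (R_xlen_t i = 0; i < walks.size(); ++i) {
    IntegerVector w = walks[i];
    std::vector<int> v(w.begin(), w.end());
    for (size_t j = 0; j < v.size(); ++j) {
      if (v[j] < 0 || v[j] >= vocab) stop("walk token out of vocabulary range");
    }
    total_tokens += static_cast<long long>(v.size());
    ws.push_back(v);
  }
  const long long train_total = total_tokens * epochs;
  long long processed = 0;

  // frequent-token subsampling (word2vec `sample`): occurrences of token w
  // are kept with probability (sqrt(f/s) + 1) * s/f, f its corpus frequency
  std::vector<double> keep(vocab, 1.0);
  if (sample > 0) {
    double total_count = 0.0;
    for (int i = 0; i < vocab; ++i) total_count += counts[i];
    for (int i = 0; i < vocab; ++i) {
      double f = counts[i] / total_count;
      double k = (std::sqrt(f / sample) + 1.0) * sample / f;
      keep[i] = k < 1.0 ? k : 1.0;
    }
  }

  std::vector<double> grad(dim);
  std::vector<int> sent;

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t s = 0; s < ws.size(); ++s) {
      const std::vector<int> &sent_raw = ws[s];
      sent.clear();
      for (size_t j = 0; j < sent_raw.size(); ++j) {
        processed += 1;  // learning-rate schedule counts raw tokens
        if (keep[sent_raw[j]] >= 1.0 || rng.unif() < keep[sent_raw[j]]) {
          sent.push_back(sent_raw[j]);
        }
      }
      const int len = static_cast<int>(sent.size());
      for (int pos = 0; pos < len; ++pos) {
        double alpha = alpha0 * (1.0 - static_cast<double>(processed) / (train_total + 1));
        if (alpha < alpha_min) alpha = alpha_min;
        const int center = sent[pos];
        // randomly reduced window, word2vec-style
        const int b = static_cast<int>(rng.bounded(static_cast<uint64_t>(window)));
        const int lo = std::max(0, pos - window + b);
        const int hi = std::min(len - 1, pos + window - b);
        for (int cpos = lo; cpos <= hi; ++cpos) {
          if (cpos == pos) continue;
          const int context = sent[cpos];
          double *v_in = &syn0[static_cast<size_t>(context) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negatives; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = center;
              label = 1.0;
            } else {
              const std::vector<double> &cum = cums[node_type[center]];
              const std::vector<int> &mem = members[node_type[center]];
              double u = rng.unif() * cum.back();
              size_t j = std::lower_bound(cum.begin(), cum.end(), u) -
                         cum.begin();
              target = mem[j];
              if (target == center) continue;
              label = 0.0;
            }
            double *v_out = &syn1[static_cast<size_t>(target) * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v_in[k] * v_out[k];
            const double g = (label - sigmoid(f)) * alpha;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * v_out[k];
              v_out[k] += g * v_in[k];
            }
          }
          for (int k = 0; k < dim; ++k) v_in[k] += grad[k];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix in(vocab, dim);
  NumericMatrix outm(vocab, dim);
  for (int i = 0; i < vocab; ++i) {
    for (int k = 0; k < dim; ++k) {
      in(i, k) = syn0[static_cast<size_t>(i) * dim + k];
      outm(i, k) = syn1[static_cast<size_t>(i) * dim + k];
    }
  }
  return List::create(Named("input") = in, Named("output") = outm);
}
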