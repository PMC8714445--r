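// Skip-gram with negative sampling, single-threaded and deterministic under
// a fixed seed. Mirrors the classical word2vec training loop: dynamic window
// shrinkage, unigram^0.75 negative-sampling table, linear learning-rate
// decay. Kept minimal on purpose: vocabularies here are dictionary
// components (thousands at most), not web-scale corpora.
#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x > 12.0) return 1.0;
  if (x < -12.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List sentences, int vocab_size,
                             NumericVector counts, int dim, int window,
                             int epochs, int negative, double alpha,
                             int seed) {
  const double alpha_min = alpha * 1e-3;
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<double> syn0(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif(rng) - 0.5) / dim;

  // cumulative unigram^0.75 table for negative sampling
  std::vector<double> cum(vocab_size);
  double z = 0.0;
  for (int v = 0; v < vocab_size; ++v) {
    z += std::pow(counts[v], 0.75);
    cum[v] = z;
  }

  // pre-extract sentences as int vectors
  std::vector<std::vector<int>> sents;
  sents.reserve(sentences.size());
  long long total_words = 0;
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector sv = sentences[s];
    std::vector<int> vec(sv.begin(), sv.end());
    total_words += static_cast<long long>(vec.size());
    sents.push_back(std::move(vec));
  }
  const long long total_train = total_words * epochs;
  long long processed = 0;

  std::vector<double> neu1e(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t s = 0; s < sents.size(); ++s) {
      const std::vector<int>& sent = sents[s];
      const int len = static_cast<int>(sent.size());
      for (int pos = 0; pos < len; ++pos) {
        ++processed;
        double lr = alpha *
          (1.0 - static_cast<double>(processed) / (total_train + 1.0));
        if (lr < alpha_min) lr = alpha_min;
        const int center = sent[pos];
        const int shrink = static_cast<int>(rng() % static_cast<unsigned>(window));
        const int win = window - shrink;
        for (int off = -win; off <= win; ++off) {
          if (off == 0) continue;
          const int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          const int context = sent[cpos];
          double* v_in = &syn0[static_cast<size_t>(center) * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = context;
              label = 1.0;
            } else {
              double r = unif(rng) * z;
              target = static_cast<int>(
                std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
              if (target >= vocab_size) target = vocab_size - 1;
              if (target == context) continue;
              label = 0.0;
            }
            double* v_out = &syn1[static_cast<size_t>(target) * dim];
            double f = 0.0;
            for (int j = 0; j < dim; ++j) f += v_in[j] * v_out[j];
            const double g = (label - sigmoid(f)) * lr;
            for (int j = 0; j < dim; ++j) {
              neu1e[j] += g * v_out[j];
              v_out[j] += g * v_in[j];
            }
          }
          for (int j = 0; j < dim; ++j) v_in[j] += neu1e[j];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int j = 0; j < dim; ++j)
      out(v, j) = syn0[static_cast<size_t>(v) * dim + j];
  return out;
}
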