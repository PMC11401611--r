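#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Skip-gram with negative sampling, in the style of the reference word2vec
// trainer: a dynamic (uniformly shrunk) context window, a 0.75-power unigram
// table for negative draws, and linear learning-rate decay over the total
// number of center-word updates. Single-threaded and driven by its own
// xorshift64* stream so that one seed yields byte-identical vectors.

static inline std::uint64_t xorshift64star(std::uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}

static inline double unif01(std::uint64_t &s) {
  return (xorshift64star(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export(name = ".sgnsTrain")]]
NumericMatrix sgnsTrain(List sentences, IntegerVector vocabCount, int dim,
                        int window, int negative, int epochs, double alpha,
                        double minAlpha, double sample, double seed) {
  const int K = vocabCount.size();
  const int d = dim;
  std::uint64_t rng = static_cast<std::uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL;
  if (rng == 0) rng = 88172645463325252ULL;

  // input (returned) and output vectors
  std::vector<float> syn0(static_cast<size_t>(K) * d);
  std::vector<float> syn1(static_cast<size_t>(K) * d, 0.0f);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = static_cast<float>((unif01(rng) - 0.5) / d);

  // unigram table, counts raised to 0.75
  const int tableSize = 1000000;
  std::vector<int> table(tableSize);
  double trainPow = 0.0;
  for (int k = 0; k < K; ++k) trainPow += std::pow((double)vocabCount[k], 0.75);
  {
    int k = 0;
    double cum = std::pow((double)vocabCount[0], 0.75) / trainPow;
    for (int t = 0; t < tableSize; ++t) {
      table[t] = k;
      if ((t + 1.0) / tableSize > cum && k < K - 1) {
        ++k;
        cum += std::pow((double)vocabCount[k], 0.75) / trainPow;
      }
    }
  }

  const int nSent = sentences.size();
  std::vector<std::vector<int> > sent(nSent);
  long long totalWords = 0;
  for (int s = 0; s < nSent; ++s) {
    IntegerVector iv = sentences[s];
    sent[s].assign(iv.begin(), iv.end());
    totalWords += iv.size();
  }
  const long long totalUpdates = totalWords * (long long)epochs;

  // frequent-word subsampling: keep probability (sqrt(f/s) + 1) * s/f
  // for token frequency f = count/total and threshold s
  std::vector<double> keepProb(K, 1.0);
  if (sample > 0) {
    for (int k = 0; k < K; ++k) {
      double f = (double)vocabCount[k] / (double)totalWords;
      if (f > sample) {
        double p = (std::sqrt(f / sample) + 1.0) * sample / f;
        keepProb[k] = p < 1.0 ? p : 1.0;
      }
    }
  }

  std::vector<float> neu1e(d);
  std::vector<int> kept;
  long long processed = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < nSent; ++s) {
      kept.clear();
      for (size_t t = 0; t < sent[s].size(); ++t) {
        const int tok = sent[s][t];
        if (keepProb[tok] >= 1.0 || unif01(rng) < keepProb[tok])
          kept.push_back(tok);
      }
      processed += (long long)(sent[s].size() - kept.size());
      const std::vector<int> &w = kept;
      const int n = (int)w.size();
      for (int pos = 0; pos < n; ++pos) {
        double lr = alpha * (1.0 - (double)processed / (totalUpdates + 1));
        if (lr < minAlpha) lr = minAlpha;
        ++processed;
        const int reduced = (int)(xorshift64star(rng) % (std::uint64_t)window);
        const int win = window - reduced;
        const int lo = pos - win < 0 ? 0 : pos - win;
        const int hi = pos + win >= n ? n - 1 : pos + win;
        for (int c = lo; c <= hi; ++c) {
          if (c == pos) continue;
          const float *l1 = &syn0[(size_t)w[c] * d];
          std::fill(neu1e.begin(), neu1e.end(), 0.0f);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = w[pos];
              label = 1.0;
            } else {
              target = table[xorshift64star(rng) % (std::uint64_t)tableSize];
              if (target == w[pos]) continue;
              label = 0.0;
            }
            float *l2 = &syn1[(size_t)target * d];
            double f = 0.0;
            for (int j = 0; j < d; ++j) f += (double)l1[j] * l2[j];
            const double g = (label - sigmoid(f)) * lr;
            for (int j = 0; j < d; ++j) neu1e[j] += (float)(g * l2[j]);
            for (int j = 0; j < d; ++j) l2[j] += (float)(g * l1[j]);
          }
          float *l1w = &syn0[(size_t)w[c] * d];
          for (int j = 0; j < d; ++j) l1w[j] += neu1e[j];
        }
      }
    }
  }

  NumericMatrix out(K, d);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < d; ++j) out(k, j) = syn0[(size_t)k * d + j];
  return out;
}
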