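#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Word2vec-style skip-gram trainer with hierarchical softmax.
// Single-threaded on purpose: given one worker and a fixed seed the token
// stream, the reduced-window draws and the weight updates are all
// deterministic, so trained vectors are bit-reproducible.

namespace {

const int EXP_TABLE_SIZE = 1000;
const double MAX_EXP = 6.0;

// word2vec's linear congruential generator; kept for its known-good
// mixing at the cheap per-token call rate.
inline unsigned long long lcg(unsigned long long &state) {
  state = state * 25214903917ULL + 11ULL;
  return state;
}

struct HuffmanTree {
  // per-vocabulary-word path through inner nodes, and binary codes
  std::vector<std::vector<int> > points;
  std::vector<std::vector<char> > codes;
};

// Builds the Huffman coding over vocabulary counts (counts must be sorted
// in non-increasing order). Standard two-pointer construction over the
// count array extended with internal-node slots.
HuffmanTree build_huffman(const std::vector<long long> &cnt) {
  const int V = (int)cnt.size();
  std::vector<long long> count(2 * V + 1, (long long)1e15);
  std::vector<int> binary(2 * V + 1, 0), parent(2 * V + 1, 0);
  for (int i = 0; i < V; ++i) count[i] = cnt[i];

  int pos1 = V - 1, pos2 = V;
  int min1i, min2i;
  for (int a = 0; a < V - 1; ++a) {
    if (pos1 >= 0) {
      if (count[pos1] < count[pos2]) { min1i = pos1--; } else { min1i = pos2++; }
    } else { min1i = pos2++; }
    if (pos1 >= 0) {
      if (count[pos1] < count[pos2]) { min2i = pos1--; } else { min2i = pos2++; }
    } else { min2i = pos2++; }
    count[V + a] = count[min1i] + count[min2i];
    parent[min1i] = V + a;
    parent[min2i] = V + a;
    binary[min2i] = 1;
  }

  // Walk leaf-to-root, then reverse so codes[d] is the branch taken at
  // inner node points[d], top-down; points[0] is the root (inner index V-2).
  HuffmanTree tree;
  tree.points.resize(V);
  tree.codes.resize(V);
  const int root = 2 * V - 2;
  for (int a = 0; a < V; ++a) {
    std::vector<char> code_up;
    std::vector<int> node_up;
    int b = a;
    while (b != root) {
      code_up.push_back((char)binary[b]);
      node_up.push_back(b);
      b = parent[b];
    }
    const int L = (int)code_up.size();
    tree.codes[a].resize(L);
    tree.points[a].resize(L);
    if (L > 0) tree.points[a][0] = V - 2;
    for (int t = 0; t < L; ++t) tree.codes[a][L - 1 - t] = code_up[t];
    for (int t = 1; t < L; ++t) tree.points[a][L - t] = node_up[t] - V;
  }
  return tree;
}

} // namespace

// [[Rcpp::export(name = ".sg_train_cpp")]]
NumericMatrix sg_train_cpp(List sentences, NumericVector counts,
                           int dim, int window, int epochs,
                           double alpha, int seed) {
  const int V = counts.size();
  if (V < 1) stop("empty vocabulary");
  if (dim < 1) stop("dim must be >= 1");
  if (window < 1) stop("window must be >= 1");
  if (epochs < 0) stop("epochs must be >= 0");
  std::vector<long long> cnt(V);
  long long total_words = 0;
  for (int i = 0; i < V; ++i) {
    cnt[i] = (long long)counts[i];
    total_words += cnt[i];
  }
  for (int i = 1; i < V; ++i)
    if (cnt[i] > cnt[i - 1]) stop("counts must be sorted non-increasing");

  // sigmoid lookup table, as in the reference implementation
  std::vector<double> expTable(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    double x = std::exp((i / (double)EXP_TABLE_SIZE * 2 - 1) * MAX_EXP);
    expTable[i] = x / (x + 1);
  }

  HuffmanTree tree = build_huffman(cnt);

  unsigned long long rng = (unsigned long long)seed;
  std::vector<double> syn0((size_t)V * dim);
  std::vector<double> syn1((size_t)(V > 1 ? V - 1 : 1) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    lcg(rng);
    syn0[i] = (((rng & 0xFFFF) / 65536.0) - 0.5) / dim;
  }

  const double starting_alpha = alpha;
  long long word_count = 0;
  const long long train_total = total_words * (long long)epochs + 1;
  std::vector<double> neu1e(dim);

  const int S = sentences.size();
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < S; ++s) {
      IntegerVector sent = sentences[s];
      const int n = sent.size();
      for (int c = 0; c < n; ++c) {
        if (word_count % 10000 == 0) {
          double a = starting_alpha * (1.0 - word_count / (double)train_total);
          if (a < starting_alpha * 0.0001) a = starting_alpha * 0.0001;
          alpha = a;
        }
        ++word_count;
        int word = sent[c];
        int b = (int)(lcg(rng) % (unsigned long long)window);
        for (int j = c - window + b; j <= c + window - b; ++j) {
          if (j == c || j < 0 || j >= n) continue;
          int last = sent[j];
          double *v0 = &syn0[(size_t)last * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          const std::vector<int> &pts = tree.points[word];
          const std::vector<char> &cds = tree.codes[word];
          for (size_t d = 0; d < pts.size(); ++d) {
            double *v1 = &syn1[(size_t)pts[d] * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v0[k] * v1[k];
            if (f <= -MAX_EXP) f = 0.0;
            else if (f >= MAX_EXP) f = 1.0;
            else f = expTable[(int)((f + MAX_EXP) *
                                    (EXP_TABLE_SIZE / MAX_EXP / 2))];
            double g = (1.0 - cds[d] - f) * alpha;
            for (int k = 0; k < dim; ++k) neu1e[k] += g * v1[k];
            for (int k = 0; k < dim; ++k) v1[k] += g * v0[k];
          }
          for (int k = 0; k < dim; ++k) v0[k] += neu1e[k];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(V, dim);
  for (int i = 0; i < V; ++i)
    for (int k = 0; k < dim; ++k)
      out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
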