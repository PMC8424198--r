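// Hierarchical-softmax skip-gram over walk corpora (word2vec-style,
// single-threaded and fully deterministic given the seed). Nodes play the
// role of words and walks the role of sentences; vocabularies here are a
// few hundred nodes, so a binary Huffman tree plus exact sigmoids is fast
// enough without exp tables or threading.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct HuffmanCode {
  std::vector<int> point;  // inner-node rows along root->leaf path
  std::vector<int> code;   // binary branch taken at each inner node
};

// Standard Huffman coding over node frequencies. Inner nodes are numbered
// n..2n-2; syn1 row for inner node v is v - n.
std::vector<HuffmanCode> build_huffman(const std::vector<long long>& count) {
  const int n = static_cast<int>(count.size());
  typedef std::pair<long long, int> Item;  // (count, node id), min-heap
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
  std::vector<long long> cnt(count);
  std::vector<int> parent(2 * n - 1, -1);
  std::vector<int> binary(2 * n - 1, 0);
  cnt.resize(2 * n - 1, 0);
  for (int i = 0; i < n; ++i) pq.push(Item(cnt[i], i));
  int next_id = n;
  while (pq.size() > 1) {
    Item a = pq.top(); pq.pop();
    Item b = pq.top(); pq.pop();
    cnt[next_id] = a.first + b.first;
    parent[a.second] = next_id;
    parent[b.second] = next_id;
    binary[b.second] = 1;
    pq.push(Item(cnt[next_id], next_id));
    ++next_id;
  }
  std::vector<HuffmanCode> codes(n);
  for (int w = 0; w < n; ++w) {
    std::vector<int> pts, bits;
    for (int v = w; parent[v] != -1; v = parent[v]) {
      pts.push_back(parent[v] - n);
      bits.push_back(binary[v]);
    }
    // reverse to root-first order
    codes[w].point.assign(pts.rbegin(), pts.rend());
    codes[w].code.assign(bits.rbegin(), bits.rend());
  }
  return codes;
}

inline double sigmoid(double x) {
  if (x > 40.0) return 1.0;
  if (x < -40.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export(name = ".sg_hs_train")]]
NumericMatrix sg_hs_train(List walks, int n_nodes, int size, int window,
                          int epochs, double alpha, int seed) {
  if (n_nodes < 2) stop("need at least two nodes to train embeddings");
  if (size < 1 || window < 1 || epochs < 1) stop("invalid skip-gram settings");

  std::vector<std::vector<int> > corpus;
  corpus.reserve(walks.size());
  std::vector<long long> count(n_nodes, 0);
  long long total_words = 0;
  for (R_xlen_t s = 0; s < walks.size(); ++s) {
    IntegerVector w = walks[s];
    std::vector<int> sen(w.size());
    for (R_xlen_t i = 0; i < w.size(); ++i) {
      int node = w[i] - 1;  // 1-based from R
      if (node < 0 || node >= n_nodes) stop("walk refers to node outside 1..n_nodes");
      sen[i] = node;
      ++count[node];
    }
    total_words += sen.size();
    corpus.push_back(sen);
  }
  for (int i = 0; i < n_nodes; ++i)
    if (count[i] == 0) stop("node %d never appears in the walk corpus", i + 1);

  std::vector<HuffmanCode> codes = build_huffman(count);

  std::vector<double> syn0(static_cast<size_t>(n_nodes) * size);
  std::vector<double> syn1(static_cast<size_t>(n_nodes - 1) * size, 0.0);
  uint64_t next_random = static_cast<uint64_t>(seed);
  for (size_t i = 0; i < syn0.size(); ++i) {
    next_random = next_random * 25214903917ULL + 11ULL;
    syn0[i] = ((static_cast<double>(next_random & 0xFFFF) / 65536.0) - 0.5) / size;
  }

  const double start_alpha = alpha;
  long long word_count = 0;
  const long long train_total = total_words * static_cast<long long>(epochs);
  double cur_alpha = start_alpha;
  std::vector<double> neu1e(size);

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t s = 0; s < corpus.size(); ++s) {
      const std::vector<int>& sen = corpus[s];
      const int len = static_cast<int>(sen.size());
      for (int pos = 0; pos < len; ++pos) {
        const int word = sen[pos];
        if (word_count % 1000 == 0) {
          cur_alpha = start_alpha *
            (1.0 - static_cast<double>(word_count) / (train_total + 1));
          if (cur_alpha < start_alpha * 1e-4) cur_alpha = start_alpha * 1e-4;
        }
        ++word_count;
        next_random = next_random * 25214903917ULL + 11ULL;
        const int b = static_cast<int>(next_random % window);
        for (int a = b; a < window * 2 + 1 - b; ++a) {
          if (a == window) continue;
          const int c = pos - window + a;
          if (c < 0 || c >= len) continue;
          double* l1 = &syn0[static_cast<size_t>(sen[c]) * size];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          const HuffmanCode& hc = codes[word];
          for (size_t d = 0; d < hc.point.size(); ++d) {
            double* l2 = &syn1[static_cast<size_t>(hc.point[d]) * size];
            double f = 0.0;
            for (int k = 0; k < size; ++k) f += l1[k] * l2[k];
            f = sigmoid(f);
            const double g = (1.0 - hc.code[d] - f) * cur_alpha;
            for (int k = 0; k < size; ++k) neu1e[k] += g * l2[k];
            for (int k = 0; k < size; ++k) l2[k] += g * l1[k];
          }
          for (int k = 0; k < size; ++k) l1[k] += neu1e[k];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, size);
  for (int i = 0; i < n_nodes; ++i)
    for (int k = 0; k < size; ++k)
      out(i, k) = syn0[static_cast<size_t>(i) * size + k];
  return out;
}
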