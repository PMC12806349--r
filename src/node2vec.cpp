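// Biased random walks and skip-gram-with-negative-sampling training for
// node2vec embeddings of chromosomal contact graphs. Single-threaded and
// fully deterministic given the seed arguments (own RNG; R's RNG untouched).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// splitmix64: tiny deterministic RNG, used so that results do not depend on
// the C++ standard library's distribution implementations.
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline double runif01(uint64_t &state) {
  return (splitmix64(state) >> 11) * (1.0 / 9007199254740992.0);
}

static inline uint64_t randint(uint64_t &state, uint64_t n) {
  return splitmix64(state) % n;
}

// weighted draw from cumulative weights (strictly increasing, last = total)
static inline int draw_cum(const std::vector<double> &cum, uint64_t &state) {
  double u = runif01(state) * cum.back();
  return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
}

struct Graph {
  int n;
  std::vector<std::vector<int>> nbr;       // 0-based neighbor lists, sorted
  std::vector<std::vector<double>> wts;
  std::vector<std::vector<double>> cum;    // cumulative weights per node
};

static Graph build(const List &adj, const List &wadj) {
  Graph g;
  g.n = adj.size();
  g.nbr.resize(g.n);
  g.wts.resize(g.n);
  g.cum.resize(g.n);
  for (int i = 0; i < g.n; ++i) {
    IntegerVector a = adj[i];
    NumericVector w = wadj[i];
    g.nbr[i].assign(a.begin(), a.end());
    g.wts[i].assign(w.begin(), w.end());
    g.cum[i].resize(w.size());
    double s = 0.0;
    for (int k = 0; k < (int)w.size(); ++k) { s += w[k]; g.cum[i][k] = s; }
  }
  return g;
}

static inline bool has_edge(const Graph &g, int u, int v) {
  const std::vector<int> &nb = g.nbr[u];
  return std::binary_search(nb.begin(), nb.end(), v);
}

// [[Rcpp::export]]
IntegerMatrix cpp_generate_walks(List adj, List wadj, IntegerVector starts,
                                 int walk_length, int num_walks,
                                 double p, double q, double seed) {
  Graph g = build(adj, wadj);
  int ns = starts.size();
  IntegerMatrix walks(ns * num_walks, walk_length);
  uint64_t state = (uint64_t)seed * 0x9e3779b97f4a7c15ULL + 0x632be59bd9b4e019ULL;
  bool unbiased = (p == 1.0 && q == 1.0);
  std::vector<double> score;
  int row = 0;
  for (int w = 0; w < num_walks; ++w) {
    for (int s = 0; s < ns; ++s, ++row) {
      int cur = starts[s];                 // 0-based
      int prev = -1;
      walks(row, 0) = cur;
      for (int t = 1; t < walk_length; ++t) {
        const std::vector<int> &nb = g.nbr[cur];
        if (nb.empty()) {                  // dead end: stay put
          walks(row, t) = cur;
          continue;
        }
        int nxt;
        if (unbiased || prev < 0) {
          nxt = nb[draw_cum(g.cum[cur], state)];
        } else {
          score.resize(nb.size());
          double tot = 0.0;
          for (size_t k = 0; k < nb.size(); ++k) {
            double f;
            if (nb[k] == prev) f = 1.0 / p;
            else if (has_edge(g, prev, nb[k])) f = 1.0;
            else f = 1.0 / q;
            tot += g.wts[cur][k] * f;
            score[k] = tot;
          }
          double u = runif01(state) * tot;
          nxt = nb[(int)(std::lower_bound(score.begin(), score.end(), u) -
                         score.begin())];
        }
        walks(row, t) = nxt;
        prev = cur;
        cur = nxt;
      }
    }
  }
  return walks;
}

// Precomputed logistic table over [-MAX_EXP, MAX_EXP] (word2vec trick):
// saturated dots round to 0/1, interior values use the table midpoint.
#define EXP_TABLE_SIZE 1000
#define MAX_EXP 6.0f
static inline float fast_sigmoid(float x, const float *table) {
  if (x >= MAX_EXP) return 1.0f;
  if (x <= -MAX_EXP) return 0.0f;
  return table[(int)((x + MAX_EXP) * (EXP_TABLE_SIZE / (2.0f * MAX_EXP)))];
}

// Skip-gram with negative sampling over a walk corpus.
// walks: rows are walks, 0-based node ids. Returns n_nodes x d input vectors.
// Initialisation is a pure function of (seed, node, dim) so that embeddings
// of corresponding nodes start identically across graphs - this keeps
// embedding spaces approximately aligned between runs, which the transfer-
// learning workflow relies on.
// [[Rcpp::export]]
NumericMatrix cpp_train_sgns(IntegerMatrix walks, int n_nodes, int d,
                             int window, int epochs, double lr,
                             int negative, double seed) {
  int n_walks = walks.nrow(), len = walks.ncol();
  float exp_table[EXP_TABLE_SIZE];
  for (int k = 0; k < EXP_TABLE_SIZE; ++k) {
    float x = ((k + 0.5f) / EXP_TABLE_SIZE * 2.0f - 1.0f) * MAX_EXP;
    exp_table[k] = 1.0f / (1.0f + std::exp(-x));
  }
  std::vector<float> W((size_t)n_nodes * d);
  std::vector<float> C((size_t)n_nodes * d, 0.0f);
  for (int u = 0; u < n_nodes; ++u) {
    uint64_t st = (uint64_t)seed * 0x100000001b3ULL + (uint64_t)u * 0xcbf29ce484222325ULL;
    splitmix64(st);
    for (int k = 0; k < d; ++k)
      W[(size_t)u * d + k] = (float)((runif01(st) - 0.5) / d);
  }

  // unigram^0.75 table for negative sampling
  std::vector<double> freq(n_nodes, 0.0);
  for (int i = 0; i < n_walks; ++i)
    for (int j = 0; j < len; ++j) freq[walks(i, j)] += 1.0;
  std::vector<double> negcum(n_nodes);
  double tot = 0.0;
  for (int u = 0; u < n_nodes; ++u) {
    tot += std::pow(freq[u], 0.75);
    negcum[u] = tot;
  }

  uint64_t state = (uint64_t)seed * 0x2545f4914f6cdd1dULL + 0x9e3779b9ULL;
  std::vector<float> grad(d);
  std::vector<int> walk(len);
  double total_steps = (double)epochs * n_walks * len;
  double step = 0.0;
  for (int e = 0; e < epochs; ++e) {
    for (int i = 0; i < n_walks; ++i) {
      for (int j = 0; j < len; ++j) walk[j] = walks(i, j); // contiguous copy
      for (int j = 0; j < len; ++j, step += 1.0) {
        double alpha = lr * (1.0 - step / (total_steps + 1.0));
        if (alpha < lr * 1e-4) alpha = lr * 1e-4;
        int center = walk[j];
        int b = 1 + (int)randint(state, (uint64_t)window); // dynamic window
        int lo = std::max(0, j - b), hi = std::min(len - 1, j + b);
        for (int c = lo; c <= hi; ++c) {
          if (c == j) continue;
          int ctx = walk[c];
          float *__restrict__ wv = &W[(size_t)center * d];
          float *__restrict__ gv = grad.data();
          std::fill(grad.begin(), grad.end(), 0.0f);
          for (int s = 0; s < negative + 1; ++s) {
            int target; float label;
            if (s == 0) { target = ctx; label = 1.0f; }
            else {
              double u = runif01(state) * tot;
              target = (int)(std::lower_bound(negcum.begin(), negcum.end(), u) -
                             negcum.begin());
              if (target == ctx) continue;
              label = 0.0f;
            }
            float *__restrict__ cv = &C[(size_t)target * d];
            float dot = 0.0f;
            for (int k = 0; k < d; ++k) dot += wv[k] * cv[k];
            float g = (float)alpha * (label - fast_sigmoid(dot, exp_table));
            for (int k = 0; k < d; ++k) {
              gv[k] += g * cv[k];
              cv[k] += g * wv[k];
            }
          }
          for (int k = 0; k < d; ++k) wv[k] += gv[k];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, d);
  for (int u = 0; u < n_nodes; ++u)
    for (int k = 0; k < d; ++k) out(u, k) = W[(size_t)u * d + k];
  return out;
}
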