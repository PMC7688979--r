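#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Continuous-time Markov SIR, final-size sampling.
//
// Uses the exact percolation representation of the final outcome: when a
// node u becomes infected it stays infectious for tau_u ~ Exp(mu); each of
// its out-edges transmits iff an independent Exp(beta) clock fires before
// tau_u, i.e. with probability 1 - exp(-beta * tau_u) conditional on tau_u
// (transmissions out of the same node are correlated through tau_u). The
// set of ever-infected nodes is the transmissive reachability set of the
// seed, which has exactly the final-size distribution of the event-driven
// process; only event timing, which the final size does not depend on, is
// discarded.

static int one_run(const std::vector<int> &ptr, const std::vector<int> &adj,
                   int seed, double beta, double mu,
                   std::vector<int> &visited, std::vector<int> &stack,
                   int stamp) {
  int count = 0;
  stack.clear();
  stack.push_back(seed);
  visited[seed] = stamp;
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    ++count;
    int begin = ptr[u], end = ptr[u + 1];
    if (begin == end) continue;
    double tau = exp_rand() / mu;                   // infectious period
    double p = (beta <= 0.0) ? 0.0 : 1.0 - std::exp(-beta * tau);
    if (p <= 0.0) continue;
    for (int e = begin; e < end; ++e) {
      int v = adj[e];
      if (visited[v] != stamp && unif_rand() < p) {
        visited[v] = stamp;
        stack.push_back(v);
      }
    }
  }
  return count;
}

static void build_csr(const List &adjlist, std::vector<int> &ptr,
                      std::vector<int> &adj) {
  int n = adjlist.size();
  ptr.assign(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adjlist[i];
    ptr[i + 1] = ptr[i] + nb.size();
  }
  adj.resize(ptr[n]);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adjlist[i];
    for (int k = 0; k < nb.size(); ++k) adj[ptr[i] + k] = nb[k] - 1;
  }
}

// [[Rcpp::export]]
IntegerVector sir_sizes_cpp(List adjlist, int seed_node, double beta,
                            double mu, int nruns) {
  std::vector<int> ptr, adj;
  build_csr(adjlist, ptr, adj);
  int n = adjlist.size();
  std::vector<int> visited(n, 0), stack;
  stack.reserve(n);
  IntegerVector out(nruns);
  RNGScope scope;
  for (int r = 0; r < nruns; ++r)
    out[r] = one_run(ptr, adj, seed_node - 1, beta, mu, visited, stack, r + 1);
  return out;
}

// One run per entry of seed_nodes (1-based), e.g. for the variability scan.
// [[Rcpp::export]]
IntegerVector sir_sizes_seeds_cpp(List adjlist, IntegerVector seed_nodes,
                                  double beta, double mu) {
  std::vector<int> ptr, adj;
  build_csr(adjlist, ptr, adj);
  int n = adjlist.size();
  std::vector<int> visited(n, 0), stack;
  stack.reserve(n);
  IntegerVector out(seed_nodes.size());
  RNGScope scope;
  for (int r = 0; r < seed_nodes.size(); ++r)
    out[r] = one_run(ptr, adj, seed_nodes[r] - 1, beta, mu, visited, stack,
                     r + 1);
  return out;
}

// Exact expected final size by enumerating the embedded jump chain.
//
// State = (ever-infected bitmask, currently-infectious bitmask). From a
// state, each recovery (rate mu per infectious node) and each transmission
// along an edge from an infectious to a susceptible node (rate beta)
// happens next with probability proportional to its rate. Memoized
// recursion over at most 3^n states; n <= 12 enforced by the caller.

struct ExactCtx {
  std::vector<int> ptr, adj;
  double beta, mu;
  std::unordered_map<uint32_t, double> memo;
};

static double exact_rec(ExactCtx &c, uint32_t ever, uint32_t inf) {
  if (inf == 0) return (double)__builtin_popcount(ever);
  uint32_t key = (ever << 12) | inf;
  auto it = c.memo.find(key);
  if (it != c.memo.end()) return it->second;

  int n_inf = __builtin_popcount(inf);
  // count susceptible targets of transmission
  double total = c.mu * n_inf;
  for (int u = 0; u < 12; ++u) {
    if (!(inf & (1u << u))) continue;
    for (int e = c.ptr[u]; e < c.ptr[u + 1]; ++e)
      if (!(ever & (1u << c.adj[e]))) total += c.beta;
  }
  double val = 0.0;
  for (int u = 0; u < 12; ++u) {
    if (!(inf & (1u << u))) continue;
    val += (c.mu / total) * exact_rec(c, ever, inf & ~(1u << u));
    for (int e = c.ptr[u]; e < c.ptr[u + 1]; ++e) {
      uint32_t vbit = 1u << c.adj[e];
      if (!(ever & vbit))
        val += (c.beta / total) * exact_rec(c, ever | vbit, inf | vbit);
    }
  }
  c.memo[key] = val;
  return val;
}

// [[Rcpp::export]]
double exact_expected_spread_cpp(List adjlist, int seed_node, double beta,
                                 double mu) {
  int n = adjlist.size();
  if (n > 12) stop("exact enumeration limited to graphs with <= 12 nodes");
  ExactCtx c;
  build_csr(adjlist, c.ptr, c.adj);
  c.beta = beta;
  c.mu = mu;
  if (beta <= 0.0) return 1.0;
  uint32_t s = 1u << (seed_node - 1);
  return exact_rec(c, s, s);
}
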