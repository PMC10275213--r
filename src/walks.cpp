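#include <Rcpp.h>
using namespace Rcpp;

// Self-avoiding random walks from s to t on a cost-weighted digraph.
// At each step the next class is chosen uniformly among the unvisited
// out-neighbours; walks that dead-end or fail to reach t are resampled.
// Because this sampling law does not weight simple paths uniformly, each
// accepted path also returns an importance weight equal to the product of
// the branching factors along it (the inverse of its sampling
// probability), which debiases averages toward the uniform-over-paths
// mean that exhaustive enumeration computes.
//
// adj: 0-based adjacency list; cost: dense kappa x kappa step costs.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_sample_paths(List adj, NumericMatrix cost, int s, int t, int m,
                      double max_attempts) {
  int kappa = adj.size();
  std::vector<std::vector<int>> nb(kappa);
  for (int i = 0; i < kappa; ++i) nb[i] = as<std::vector<int>>(adj[i]);
  NumericVector lengths(m);
  NumericVector weights(m);
  std::vector<char> visited(kappa);
  std::vector<int> avail;
  avail.reserve(kappa);
  int accepted = 0;
  double attempts = 0;
  while (accepted < m && attempts < max_attempts) {
    attempts += 1;
    std::fill(visited.begin(), visited.end(), 0);
    int v = s;
    visited[s] = 1;
    double len = 0.0, logw = 0.0;
    bool done = false, dead = false;
    while (!done && !dead) {
      avail.clear();
      for (int w : nb[v]) if (!visited[w]) avail.push_back(w);
      if (avail.empty()) { dead = true; break; }
      int pick = (int)(unif_rand() * avail.size());
      if (pick >= (int)avail.size()) pick = avail.size() - 1;
      int w = avail[pick];
      logw += std::log((double)avail.size());
      len += cost(v, w);
      if (w == t) { done = true; }
      else { visited[w] = 1; v = w; }
    }
    if (done) {
      lengths[accepted] = len;
      weights[accepted] = std::exp(logw);
      ++accepted;
    }
  }
  if (accepted < m) {
    lengths = head(lengths, accepted);
    weights = head(weights, accepted);
  }
  return List::create(_["lengths"] = lengths, _["weights"] = weights,
                      _["attempts"] = attempts);
}

// Exhaustive enumeration of simple directed paths s -> t with total step
// costs (iterative DFS). The target is terminal: paths never pass
// through t. Returns the running sum, sum of squares and count so the
// caller can form means and Monte-Carlo standard errors.
// [[Rcpp::export]]
List cpp_enumerate_paths(List adj, NumericMatrix cost, int s, int t,
                         double max_paths) {
  int kappa = adj.size();
  std::vector<std::vector<int>> nb(kappa);
  for (int i = 0; i < kappa; ++i) nb[i] = as<std::vector<int>>(adj[i]);
  std::vector<char> visited(kappa, 0);
  double sum = 0, sumsq = 0, count = 0;
  bool truncated = false;
  std::vector<int> stack_v, stack_i;
  std::vector<double> stack_len;
  stack_v.push_back(s); stack_i.push_back(0); stack_len.push_back(0.0);
  visited[s] = 1;
  while (!stack_v.empty()) {
    size_t top = stack_v.size() - 1;
    int v = stack_v[top];
    if (stack_i[top] >= (int)nb[v].size()) {
      visited[v] = 0;
      stack_v.pop_back(); stack_i.pop_back(); stack_len.pop_back();
      continue;
    }
    int w = nb[v][stack_i[top]++];
    if (visited[w]) continue;
    double len2 = stack_len[top] + cost(v, w);
    if (w == t) {
      sum += len2; sumsq += len2 * len2; count += 1;
      if (count >= max_paths) { truncated = true; break; }
    } else {
      visited[w] = 1;
      stack_v.push_back(w); stack_i.push_back(0); stack_len.push_back(len2);
    }
  }
  return List::create(_["sum"] = sum, _["sumsq"] = sumsq,
                      _["count"] = count, _["truncated"] = truncated);
}
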