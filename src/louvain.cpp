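#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weighted Louvain modularity optimization with a configurable resolution
// parameter.  The implementation follows the classic two-phase scheme
// (greedy local moves, then community aggregation) and adds a fine-level
// refinement sweep after every aggregation round so the optimizer does not
// get stuck behind a coarse merge.  Node sweep order at the finest level is
// supplied by the caller (a seeded permutation); moves are accepted only on
// a strict modularity gain and equal-gain candidate targets resolve to the
// lowest community id, which makes the whole procedure deterministic.

namespace {

struct Graph {
  int n;
  std::vector<std::vector<std::pair<int, double> > > adj;  // no self loops
  std::vector<double> self;  // self-loop weight, counted once
  std::vector<double> deg;   // weighted degree incl. 2 * self
  double m2;                 // total degree = 2m
};

Graph build_graph(int n, const std::vector<int>& from, const std::vector<int>& to,
                  const std::vector<double>& w) {
  Graph g;
  g.n = n;
  g.adj.assign(n, std::vector<std::pair<int, double> >());
  g.self.assign(n, 0.0);
  g.deg.assign(n, 0.0);
  for (size_t e = 0; e < from.size(); ++e) {
    int u = from[e], v = to[e];
    double ww = w[e];
    if (u == v) {
      g.self[u] += ww;
    } else {
      g.adj[u].push_back(std::make_pair(v, ww));
      g.adj[v].push_back(std::make_pair(u, ww));
    }
  }
  g.m2 = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = 2.0 * g.self[i];
    for (size_t j = 0; j < g.adj[i].size(); ++j) d += g.adj[i][j].second;
    g.deg[i] = d;
    g.m2 += d;
  }
  return g;
}

// One full local-moving phase; comm is updated in place.
// Returns true when at least one node changed community.
bool local_move(const Graph& g, std::vector<int>& comm, double gamma,
                const std::vector<int>& order) {
  if (g.m2 <= 0.0) return false;
  const double m2 = g.m2;
  std::vector<double> tot(g.n, 0.0);
  for (int i = 0; i < g.n; ++i) tot[comm[i]] += g.deg[i];

  std::vector<double> wcomm(g.n, 0.0);
  std::vector<int> touched;
  touched.reserve(64);
  bool any = false, improved = true;
  const double eps = 1e-12;
  while (improved) {
    improved = false;
    for (int oi = 0; oi < g.n; ++oi) {
      int i = order[oi];
      int ci = comm[i];
      touched.clear();
      for (size_t j = 0; j < g.adj[i].size(); ++j) {
        int cj = comm[g.adj[i][j].first];
        if (wcomm[cj] == 0.0) touched.push_back(cj);
        wcomm[cj] += g.adj[i][j].second;
      }
      tot[ci] -= g.deg[i];
      double stay = wcomm[ci] - gamma * tot[ci] * g.deg[i] / m2;
      int best = ci;
      double bestgain = stay;
      for (size_t t = 0; t < touched.size(); ++t) {
        int c = touched[t];
        if (c == ci) continue;
        double gain = wcomm[c] - gamma * tot[c] * g.deg[i] / m2;
        if (gain > bestgain + eps ||
            (std::fabs(gain - bestgain) <= eps && best != ci && c < best)) {
          best = c;
          bestgain = gain;
        }
      }
      tot[best] += g.deg[i];
      if (best != ci) {
        comm[i] = best;
        improved = true;
        any = true;
      }
      for (size_t t = 0; t < touched.size(); ++t) wcomm[touched[t]] = 0.0;
      if (wcomm[ci] != 0.0) wcomm[ci] = 0.0;
    }
  }
  return any;
}

int compact_labels(std::vector<int>& comm) {
  std::vector<int> map(comm.size(), -1);
  int next = 0;
  for (size_t i = 0; i < comm.size(); ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = next++;
    comm[i] = map[comm[i]];
  }
  return next;
}

Graph aggregate(const Graph& g, const std::vector<int>& comm, int ncomm) {
  // accumulate edges between communities; self-loops gather intra weight
  std::vector<std::vector<std::pair<int, double> > > acc(ncomm);
  std::vector<double> self(ncomm, 0.0);
  for (int i = 0; i < g.n; ++i) {
    self[comm[i]] += g.self[i];
    for (size_t j = 0; j < g.adj[i].size(); ++j) {
      int v = g.adj[i][j].first;
      if (v < i) continue;  // undirected edge once
      int cu = comm[i], cv = comm[v];
      if (cu == cv) self[cu] += g.adj[i][j].second;
      else acc[std::min(cu, cv)].push_back(std::make_pair(std::max(cu, cv), g.adj[i][j].second));
    }
  }
  std::vector<int> from, to;
  std::vector<double> w;
  std::vector<double> buf(ncomm, 0.0);
  std::vector<int> seen;
  for (int c = 0; c < ncomm; ++c) {
    seen.clear();
    for (size_t j = 0; j < acc[c].size(); ++j) {
      int v = acc[c][j].first;
      if (buf[v] == 0.0) seen.push_back(v);
      buf[v] += acc[c][j].second;
    }
    for (size_t t = 0; t < seen.size(); ++t) {
      from.push_back(c);
      to.push_back(seen[t]);
      w.push_back(buf[seen[t]]);
      buf[seen[t]] = 0.0;
    }
  }
  for (int c = 0; c < ncomm; ++c) {
    from.push_back(c);
    to.push_back(c);
    w.push_back(self[c]);
  }
  return build_graph(ncomm, from, to, w);
}

double modularity_of(const Graph& g, const std::vector<int>& comm, double gamma) {
  if (g.m2 <= 0.0) return 0.0;
  double m = g.m2 / 2.0;
  int ncomm = 0;
  for (int i = 0; i < g.n; ++i) ncomm = std::max(ncomm, comm[i] + 1);
  std::vector<double> ein(ncomm, 0.0), dtot(ncomm, 0.0);
  for (int i = 0; i < g.n; ++i) {
    dtot[comm[i]] += g.deg[i];
    ein[comm[i]] += g.self[i];
    for (size_t j = 0; j < g.adj[i].size(); ++j) {
      int v = g.adj[i][j].first;
      if (v < i) continue;
      if (comm[i] == comm[v]) ein[comm[i]] += g.adj[i][j].second;
    }
  }
  double q = 0.0;
  for (int c = 0; c < ncomm; ++c) {
    double frac = dtot[c] / g.m2;
    q += ein[c] / m - gamma * frac * frac;
  }
  return q;
}

}  // namespace

// [[Rcpp::export]]
List cpp_louvain(int n, IntegerVector from, IntegerVector to, NumericVector weight,
                 double resolution, IntegerVector order) {
  std::vector<int> f(from.size()), t(to.size());
  std::vector<double> w(weight.size());
  for (int e = 0; e < from.size(); ++e) {
    f[e] = from[e] - 1;
    t[e] = to[e] - 1;
    w[e] = weight[e];
  }
  Graph g0 = build_graph(n, f, t, w);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = order[i] - 1;

  std::vector<int> comm(n);
  for (int i = 0; i < n; ++i) comm[i] = i;

  if (g0.m2 > 0.0) {
    local_move(g0, comm, resolution, ord);
    int ncomm = compact_labels(comm);
    // alternate coarse aggregation with fine-level refinement until stable
    for (int iter = 0; iter < 1000; ++iter) {
      Graph ga = aggregate(g0, comm, ncomm);
      std::vector<int> cagg(ga.n);
      std::vector<int> oagg(ga.n);
      for (int i = 0; i < ga.n; ++i) { cagg[i] = i; oagg[i] = i; }
      bool moved_coarse = local_move(ga, cagg, resolution, oagg);
      if (moved_coarse) {
        for (int i = 0; i < n; ++i) comm[i] = cagg[comm[i]];
        ncomm = compact_labels(comm);
      }
      bool moved_fine = local_move(g0, comm, resolution, ord);
      if (moved_fine) ncomm = compact_labels(comm);
      if (!moved_coarse && !moved_fine) break;
    }
  }
  compact_labels(comm);
  double q = modularity_of(g0, comm, resolution);
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) labels[i] = comm[i] + 1;
  return List::create(_["labels"] = labels, _["modularity"] = q);
}

// [[Rcpp::export]]
double cpp_modularity(int n, IntegerVector from, IntegerVector to, NumericVector weight,
                      IntegerVector labels, double resolution) {
  std::vector<int> f(from.size()), t(to.size());
  std::vector<double> w(weight.size());
  for (int e = 0; e < from.size(); ++e) {
    f[e] = from[e] - 1;
    t[e] = to[e] - 1;
    w[e] = weight[e];
  }
  Graph g = build_graph(n, f, t, w);
  std::vector<int> comm(n);
  for (int i = 0; i < n; ++i) comm[i] = labels[i] - 1;
  return modularity_of(g, comm, resolution);
}
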