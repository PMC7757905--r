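// Inner push-relabel flow routine of the capacity-releasing diffusion over
// hyperedges. All flows, degrees and capacities are integers; node levels are
// capped at h and never decrease within one run. Hyperedge flows start at 0
// each run (every inner call is a fresh flow problem).
//
// A node v is active when its excess ex(v) = max(m(v) - d(v), 0) reaches
// min_{e ∋ v}(|e| - 1) and its level is below h. Active nodes are processed
// lowest level first, FIFO among equal levels. The node scans its incident
// hyperedges in incidence order and pushes through the first eligible one
// (>= alpha strictly-lower-level co-members, positive residual capacity,
// ex(v) >= |e| - 1); when no eligible edge exists or the push quantity is 0,
// the node is relabeled.

#include <Rcpp.h>
#include <climits>
#include <deque>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".inner_diffusion_cpp")]]
List inner_diffusion_cpp(IntegerVector edge_ptr, IntegerVector edge_nodes,
                         IntegerVector node_ptr, IntegerVector node_edges,
                         IntegerVector d, IntegerVector m0, IntegerVector ew,
                         int C, int h, int alpha, bool record) {
  const int n = d.size();
  const int ne = edge_ptr.size() - 1;
  std::vector<long long> m(m0.begin(), m0.end());
  std::vector<long long> flow(ne, 0);
  std::vector<int> level(n, 0);
  std::vector<bool> in_queue(n, false);

  // activation threshold: smallest |e|-1 over incident edges
  std::vector<int> thr(n, INT_MAX);
  for (int v = 0; v < n; ++v) {
    for (int p = node_ptr[v]; p < node_ptr[v + 1]; ++p) {
      int sz = edge_ptr[node_edges[p] + 1] - edge_ptr[node_edges[p]];
      if (sz - 1 < thr[v]) thr[v] = sz - 1;
    }
  }

  std::vector<std::deque<int> > bucket(h + 1);
  int curmin = 0;
  auto excess = [&](int v) -> long long {
    long long e = m[v] - (long long)d[v];
    return e > 0 ? e : 0;
  };
  for (int v = 0; v < n; ++v) {
    if (thr[v] != INT_MAX && excess(v) >= thr[v] && h > 0) {
      bucket[0].push_back(v);
      in_queue[v] = true;
    }
  }

  std::vector<int> tr_event, tr_node, tr_edge, tr_level;
  std::vector<double> tr_psi;
  long long n_push = 0, n_relabel = 0;

  // hard bound: each step either raises a level (<= n*h total) or adds >= 1
  // unit to some edge flow (<= sum of capacities); a generous multiple guards
  // against implementation bugs rather than algorithmic non-termination
  long long cap_sum = 0;
  for (int e = 0; e < ne; ++e) cap_sum += (long long)C * ew[e];
  long long max_steps = 10 + 4 * (cap_sum + (long long)n * (h + 1));

  long long steps = 0;
  while (true) {
    while (curmin <= h && bucket[curmin].empty()) ++curmin;
    if (curmin > h) break;
    if (++steps > max_steps)
      stop("inner diffusion exceeded its step bound (internal error)");
    int v = bucket[curmin].front();
    bucket[curmin].pop_front();
    in_queue[v] = false;
    long long exv = excess(v);
    if (exv < thr[v] || level[v] >= h) continue; // defensive; should not occur

    // find first eligible incident hyperedge
    int chosen = -1;
    for (int p = node_ptr[v]; p < node_ptr[v + 1]; ++p) {
      int e = node_edges[p];
      int sz = edge_ptr[e + 1] - edge_ptr[e];
      if (exv < sz - 1) continue;
      long long lc = level[v] < C ? level[v] : C;
      long long resid = lc * (long long)ew[e] - flow[e];
      if (resid <= 0) continue;
      int below = 0;
      for (int q = edge_ptr[e]; q < edge_ptr[e + 1]; ++q) {
        int u = edge_nodes[q];
        if (u != v && level[u] < level[v]) ++below;
      }
      if (below >= alpha) { chosen = e; break; }
    }

    bool pushed = false;
    if (chosen >= 0) {
      int e = chosen;
      int sz = edge_ptr[e + 1] - edge_ptr[e];
      long long lc = level[v] < C ? level[v] : C;
      long long psi = exv / (sz - 1);
      long long resid = lc * (long long)ew[e] - flow[e];
      if (resid < psi) psi = resid;
      for (int q = edge_ptr[e]; q < edge_ptr[e + 1]; ++q) {
        int u = edge_nodes[q];
        if (u == v) continue;
        long long room = 2LL * d[u] - m[u];
        if (room < psi) psi = room;
      }
      if (psi > 0) {
        pushed = true;
        ++n_push;
        flow[e] += psi;
        m[v] -= (long long)(sz - 1) * psi;
        for (int q = edge_ptr[e]; q < edge_ptr[e + 1]; ++q) {
          int u = edge_nodes[q];
          if (u == v) continue;
          m[u] += psi;
          if (!in_queue[u] && excess(u) >= thr[u] && level[u] < h) {
            bucket[level[u]].push_back(u);
            in_queue[u] = true;
            if (level[u] < curmin) curmin = level[u];
          }
        }
        if (record) {
          tr_event.push_back(1); tr_node.push_back(v); tr_edge.push_back(e);
          tr_psi.push_back((double)psi); tr_level.push_back(level[v]);
        }
        if (excess(v) >= thr[v]) { // still active: back of its level's queue
          bucket[level[v]].push_back(v);
          in_queue[v] = true;
        }
      }
    }
    if (!pushed) {
      ++n_relabel;
      ++level[v];
      if (record) {
        tr_event.push_back(2); tr_node.push_back(v); tr_edge.push_back(-1);
        tr_psi.push_back(0.0); tr_level.push_back(level[v]);
      }
      if (level[v] < h) {
        bucket[level[v]].push_back(v);
        in_queue[v] = true;
      }
    }
  }

  NumericVector m_out(n), flow_out(ne);
  for (int v = 0; v < n; ++v) m_out[v] = (double)m[v];
  for (int e = 0; e < ne; ++e) flow_out[e] = (double)flow[e];
  List out = List::create(
    _["m"] = m_out,
    _["edge_flow"] = flow_out,
    _["level"] = IntegerVector(level.begin(), level.end()),
    _["n_pushes"] = (double)n_push,
    _["n_relabels"] = (double)n_relabel);
  if (record) {
    out["trace"] = DataFrame::create(
      _["event"] = IntegerVector(tr_event.begin(), tr_event.end()),
      _["node"] = IntegerVector(tr_node.begin(), tr_node.end()),
      _["edge"] = IntegerVector(tr_edge.begin(), tr_edge.end()),
      _["psi"] = NumericVector(tr_psi.begin(), tr_psi.end()),
      _["level"] = IntegerVector(tr_level.begin(), tr_level.end()));
  }
  return out;
}
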