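#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include <vector>
using namespace Rcpp;

// Approximate personalized PageRank push on an undirected weighted graph
// given in CSC form (symmetric, so columns double as rows).
//
// Recursion approximated: p = (1 - c) * r0 + c * T' p, with T = D^-1 A.
// One push at u moves (1 - c) * r(u) into the score and spreads c * r(u)
// along u's transition row into the residuals of its neighbours. Termination
// when r(u) <= eps * deg(u) for every u, which bounds the per-node error of
// the score vector by eps * deg(u) (undirected-walk reversibility).
//
// Push order: largest residual-to-degree ratio first, ties broken by the
// smaller state index; the score and residual stay sparse (hash maps), so
// work and memory scale with the touched neighbourhood, not with |VM|.
// [[Rcpp::export]]
List ppr_push_cpp(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                  NumericVector deg,
                  IntegerVector s_idx, NumericVector s_val,
                  IntegerVector r_idx, NumericVector r_val,
                  double eps, double c) {
  std::unordered_map<int, double> score, resid;
  for (int k = 0; k < s_idx.size(); ++k) score[s_idx[k]] = s_val[k];
  for (int k = 0; k < r_idx.size(); ++k) resid[r_idx[k]] = r_val[k];

  struct Entry { double ratio; int idx; };
  struct Cmp {
    bool operator()(const Entry &a, const Entry &b) const {
      if (a.ratio != b.ratio) return a.ratio < b.ratio;  // max-heap on ratio
      return a.idx > b.idx;                              // then min index
    }
  };
  std::priority_queue<Entry, std::vector<Entry>, Cmp> heap;
  for (auto &kv : resid)
    if (deg[kv.first] > 0 && kv.second > eps * deg[kv.first])
      heap.push({kv.second / deg[kv.first], kv.first});

  const long long max_push = 200000000LL;
  long long n_push = 0;
  while (!heap.empty()) {
    int u = heap.top().idx;
    heap.pop();
    double du = deg[u];
    if (du <= 0) continue;
    auto it = resid.find(u);
    if (it == resid.end()) continue;
    double ru = it->second;
    if (ru <= eps * du) continue;  // stale heap entry
    if (++n_push > max_push)
      stop("PPR push did not terminate within the operation budget");
    score[u] += (1.0 - c) * ru;
    it->second = 0.0;
    double spread = c * ru / du;
    for (int k = Ap[u]; k < Ap[u + 1]; ++k) {
      int v = Ai[k];
      double add = spread * Ax[k];
      double rv = (resid[v] += add);
      if (deg[v] > 0 && rv > eps * deg[v]) heap.push({rv / deg[v], v});
    }
  }

  std::vector<int> si, ri;
  std::vector<double> sv, rv;
  for (auto &kv : score) if (kv.second > 0) { si.push_back(kv.first); sv.push_back(kv.second); }
  for (auto &kv : resid) if (kv.second > 0) { ri.push_back(kv.first); rv.push_back(kv.second); }
  return List::create(_["score_idx"] = si, _["score_val"] = sv,
                      _["resid_idx"] = ri, _["resid_val"] = rv,
                      _["n_push"] = (double)n_push);
}
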