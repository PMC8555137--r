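#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exhaustive branch-and-bound over rooted subtrees of a small graph.
//
// Enumerates every subtree containing `root` by frontier-edge expansion with
// a ban discipline (after exploring branches that include edge e, e is
// banned for the remaining branches at that level), which generates each
// subtree exactly once. A tree is a "solution" when it contains all
// terminals and every leaf is a terminal (leaf-minimality); supertrees of a
// complete tree can never be leaf-minimal, so recursion stops at
// completion. Objective of a complete tree:
//   f = 2*alpha * sum(len) + (1-2*alpha) * sum_t dist(root, t)
// which only grows along a branch, giving the lower bound used for pruning.

struct Search {
  int n, m, K;
  const int *efrom, *eto;
  const double *elen;
  double alpha;
  std::vector<int> isTerm, isAnchor;
  std::vector<char> inTree, banned;
  std::vector<double> dist;
  std::vector<int> treeEdges;
  std::vector<int> deg;
  double sumLen = 0.0, sumTermDist = 0.0;
  int nTermIn = 0;
  int rootNode;

  bool enumerateAll;
  double bound;           // admission bound (enumerate) / current best (opt)
  double bestObj = R_PosInf;
  std::vector<int> bestEdges;
  std::vector<std::vector<int> > members;
  std::vector<double> memberObjs;
  long nodesVisited = 0;
  long nodeLimit;

  double lb() const {
    return 2.0 * alpha * sumLen + (1.0 - 2.0 * alpha) * sumTermDist;
  }

  bool leafMinimal() const {
    for (int v = 0; v < n; ++v) {
      if (!inTree[v] || v == rootNode) continue;
      if (deg[v] == 1 && !isTerm[v]) return false;
    }
    return true;
  }

  // lexicographic tie-break on sorted edge-index lists
  static bool lexLess(const std::vector<int> &a, const std::vector<int> &b) {
    return std::lexicographical_compare(a.begin(), a.end(),
                                        b.begin(), b.end());
  }

  void record(double obj) {
    std::vector<int> ed(treeEdges);
    std::sort(ed.begin(), ed.end());
    if (enumerateAll) {
      if (leafMinimal()) {
        members.push_back(ed);
        memberObjs.push_back(obj);
      }
      if (obj < bestObj - 1e-12 ||
          (std::abs(obj - bestObj) <= 1e-12 &&
           (ed.size() < bestEdges.size() ||
            (ed.size() == bestEdges.size() && lexLess(ed, bestEdges))))) {
        if (leafMinimal()) { bestObj = obj; bestEdges = ed; }
      }
    } else {
      if (!leafMinimal()) return;
      bool better = obj < bestObj - 1e-12;
      bool tie = std::abs(obj - bestObj) <= 1e-12;
      if (better ||
          (tie && (ed.size() < bestEdges.size() ||
                   (ed.size() == bestEdges.size() && lexLess(ed, bestEdges))))) {
        bestObj = obj;
        bestEdges = ed;
        bound = std::min(bound, bestObj);
      }
    }
  }

  void rec() {
    if (++nodesVisited > nodeLimit)
      stop("search space too large for exhaustive enumeration");
    double cur = lb();
    if (cur > bound + 1e-9) return;
    if (nTermIn == K) { record(cur); return; }
    // frontier: unbanned edges with exactly one endpoint in the tree
    std::vector<int> frontier;
    for (int e = 0; e < m; ++e) {
      if (banned[e]) continue;
      bool a = inTree[efrom[e]], b = inTree[eto[e]];
      if (a != b) frontier.push_back(e);
    }
    std::vector<int> localBans;
    for (size_t i = 0; i < frontier.size(); ++i) {
      int e = frontier[i];
      if (banned[e]) continue;
      int u = inTree[efrom[e]] ? efrom[e] : eto[e];
      int v = inTree[efrom[e]] ? eto[e] : efrom[e];
      // anchors may only enter through their zero-length root edge:
      // otherwise adding the virtual root's edge to every in-tree anchor
      // would close a cycle and the tree is not a valid solution. Skip
      // without banning — the edge stays usable in the other direction.
      if (isAnchor[v] && u != rootNode) continue;
      inTree[v] = 1;
      dist[v] = dist[u] + elen[e];
      deg[u]++; deg[v]++;
      sumLen += elen[e];
      bool term = isTerm[v];
      if (term) { nTermIn++; sumTermDist += dist[v]; }
      treeEdges.push_back(e);
      rec();
      treeEdges.pop_back();
      if (term) { nTermIn--; sumTermDist -= dist[v]; }
      sumLen -= elen[e];
      deg[u]--; deg[v]--;
      inTree[v] = 0;
      banned[e] = 1;
      localBans.push_back(e);
    }
    for (size_t i = 0; i < localBans.size(); ++i) banned[localBans[i]] = 0;
  }
};

// [[Rcpp::export(name = ".tree_search_cpp")]]
List tree_search_cpp(int n, IntegerVector efrom, IntegerVector eto,
                     NumericVector elen, int root, IntegerVector terminals,
                     IntegerVector anchors, double alpha, double bound,
                     bool enumerate_all, double node_limit) {
  Search s;
  s.n = n;
  s.m = efrom.size();
  s.efrom = efrom.begin();
  s.eto = eto.begin();
  s.elen = elen.begin();
  s.alpha = alpha;
  s.K = terminals.size();
  s.rootNode = root;
  s.enumerateAll = enumerate_all;
  s.bound = bound;
  s.nodeLimit = (long)node_limit;
  s.isTerm.assign(n, 0);
  for (int i = 0; i < s.K; ++i) s.isTerm[terminals[i]] = 1;
  s.isAnchor.assign(n, 0);
  for (int i = 0; i < anchors.size(); ++i) s.isAnchor[anchors[i]] = 1;
  s.inTree.assign(n, 0);
  s.banned.assign(s.m, 0);
  s.dist.assign(n, 0.0);
  s.deg.assign(n, 0);
  s.inTree[root] = 1;
  if (s.isTerm[root]) { s.nTermIn = 1; }  // root never a terminal in practice
  s.rec();
  List out = List::create(
    _["objective"] = s.bestObj,
    _["edges"] = wrap(s.bestEdges),
    _["visited"] = (double)s.nodesVisited);
  if (enumerate_all) {
    out["members"] = wrap(s.members);
    out["member_objectives"] = wrap(s.memberObjs);
  }
  return out;
}
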