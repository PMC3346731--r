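#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

// Minimum-cost cophylogenetic reconciliation, cost only.
//
// Mirrors the R dynamic programme in reconcile.R exactly: events at
// internal mimic nodes are codivergence, duplication, or switch (a
// duplication one of whose daughters colonises any non-ancestral model
// position, charged duplication+switch); one loss is charged per internal
// model node a lineage passes through without a mimic divergence.
//
// Node numbering follows ape: tips 1..ntip, root ntip+1 (converted to
// 0-based internally). Both trees must be rooted and fully resolved.

static const double BIG = 1e15;

struct Tree {
  int ntip, nn;
  std::vector<int> par;
  std::vector<std::array<int, 2>> kids;
  std::vector<int> nkids;
  std::vector<int> post;  // postorder
  void build(const IntegerMatrix& edge, int ntip_) {
    ntip = ntip_;
    int maxn = 0;
    for (int i = 0; i < edge.nrow(); ++i) {
      maxn = std::max(maxn, std::max(edge(i, 0), edge(i, 1)));
    }
    nn = maxn;
    par.assign(nn, -1);
    nkids.assign(nn, 0);
    kids.assign(nn, {{-1, -1}});
    for (int i = 0; i < edge.nrow(); ++i) {
      int a = edge(i, 0) - 1, b = edge(i, 1) - 1;
      par[b] = a;
      if (nkids[a] >= 2) stop("trees must be fully resolved (binary)");
      kids[a][nkids[a]++] = b;
    }
    // iterative postorder from the root (ntip, 0-based)
    post.clear();
    std::vector<int> stack;
    stack.push_back(ntip);
    std::vector<int> order;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      order.push_back(v);
      for (int j = 0; j < nkids[v]; ++j) stack.push_back(kids[v][j]);
    }
    post.assign(order.rbegin(), order.rend());
  }
  bool is_int(int v) const { return nkids[v] > 0; }
};

// [[Rcpp::export]]
double dp_min_cost(IntegerMatrix edgeP, int ntipP,
                   IntegerMatrix edgeM, int ntipM,
                   IntegerMatrix assoc, NumericVector costs) {
  Tree P, M;
  P.build(edgeP, ntipP);
  M.build(edgeM, ntipM);
  const double cc = costs[0], cd = costs[1], cs = costs[2], cl = costs[3];
  const int nm = M.nn, np = P.nn;

  // model geometry: subtree membership and ancestor sets
  std::vector<std::vector<char>> insub(nm, std::vector<char>(nm, 0));
  for (int idx = 0; idx < nm; ++idx) {
    int v = M.post[idx];
    insub[v][v] = 1;
    for (int j = 0; j < M.nkids[v]; ++j) {
      int c = M.kids[v][j];
      for (int y = 0; y < nm; ++y) insub[v][y] |= insub[c][y];
    }
  }
  std::vector<std::vector<char>> banned(nm, std::vector<char>(nm, 0));
  for (int h = 0; h < nm; ++h) {
    banned[h][h] = 1;
    for (int a = M.par[h]; a >= 0; a = M.par[a]) banned[h][a] = 1;
  }

  std::vector<std::vector<double>> C(np, std::vector<double>(nm, BIG));
  std::vector<std::vector<double>> B(np, std::vector<double>(nm, BIG));

  for (int r = 0; r < assoc.nrow(); ++r) {
    C[assoc(r, 0) - 1][assoc(r, 1) - 1] = 0.0;
  }

  for (int pi = 0; pi < np; ++pi) {
    int p = P.post[pi];
    if (P.is_int(p)) {
      int k1 = P.kids[p][0], k2 = P.kids[p][1];
      const std::vector<double>&b1 = B[k1], &b2 = B[k2];
      const std::vector<double>&c1 = C[k1], &c2 = C[k2];
      for (int h = 0; h < nm; ++h) {
        double best = BIG;
        if (M.is_int(h)) {
          int hl = M.kids[h][0], hr = M.kids[h][1];
          best = std::min(best, cc + b1[hl] + b2[hr]);
          best = std::min(best, cc + b1[hr] + b2[hl]);
        }
        best = std::min(best, cd + b1[h] + b2[h]);
        double m1 = BIG, m2 = BIG;
        for (int y = 0; y < nm; ++y) {
          if (!banned[h][y]) {
            m1 = std::min(m1, c2[y]);
            m2 = std::min(m2, c1[y]);
          }
        }
        best = std::min(best, cd + cs + b1[h] + m1);
        best = std::min(best, cd + cs + b2[h] + m2);
        C[p][h] = best;
      }
    }
    // entry table for p
    for (int xi = 0; xi < nm; ++xi) {
      int x = M.post[xi];
      if (M.is_int(x)) {
        double m = BIG;
        for (int j = 0; j < M.nkids[x]; ++j) m = std::min(m, B[p][M.kids[x][j]]);
        B[p][x] = std::min(C[p][x], cl + m);
      } else {
        B[p][x] = C[p][x];
      }
    }
  }

  int rootP = ntipP;  // 0-based
  double best = BIG;
  for (int h = 0; h < nm; ++h) best = std::min(best, C[rootP][h]);
  return best;
}
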