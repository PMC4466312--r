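// Breadth-first simultaneous atom-chain matching between a candidate and a
// template, grown from a paired anchor bond. Topology-only compatibility:
// any heavy element may map onto any heavy element; same-element pairings
// are preferred when several neighbours are available. The mapping is
// injective and connectivity-consistent by construction. This is the hot
// loop of template alignment (called for every candidate-anchor x template
// x template-anchor combination), hence compiled.

#include <Rcpp.h>
#include <deque>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export(name = ".matchChainsCpp")]]
List matchChainsCpp(List candAdj, IntegerVector candElem, IntegerVector candRank,
                    List tmplAdj, IntegerVector tmplElem, IntegerVector tmplRank,
                    int ck, int cl, int ti, int tj) {
  const int nc = candAdj.size(), nt = tmplAdj.size();
  std::vector<int> c2t(nc + 1, 0), t2c(nt + 1, 0);
  std::deque<std::pair<int, int> > q;
  c2t[ck] = ti; t2c[ti] = ck;
  c2t[cl] = tj; t2c[tj] = cl;
  q.push_back(std::make_pair(ck, ti));
  q.push_back(std::make_pair(cl, tj));
  int matched = 2;
  int elemId = (candElem[ck - 1] == tmplElem[ti - 1]) +
               (candElem[cl - 1] == tmplElem[tj - 1]);
  while (!q.empty()) {
    const int c = q.front().first, t = q.front().second;
    q.pop_front();
    IntegerVector cn = candAdj[c - 1];
    IntegerVector tn = tmplAdj[t - 1];
    std::vector<int> cun, tun;
    for (int k = 0; k < cn.size(); ++k) if (!c2t[cn[k]]) cun.push_back(cn[k]);
    for (int k = 0; k < tn.size(); ++k) if (!t2c[tn[k]]) tun.push_back(tn[k]);
    if (cun.empty() || tun.empty()) continue;
    std::sort(cun.begin(), cun.end(), [&](int a, int b) {
      if (candRank[a - 1] != candRank[b - 1])
        return candRank[a - 1] > candRank[b - 1];
      return a < b;
    });
    std::sort(tun.begin(), tun.end(), [&](int a, int b) {
      if (tmplRank[a - 1] != tmplRank[b - 1])
        return tmplRank[a - 1] > tmplRank[b - 1];
      return a < b;
    });
    std::vector<bool> used(tun.size(), false);
    for (size_t ci = 0; ci < cun.size(); ++ci) {
      const int cc = cun[ci];
      if (c2t[cc]) continue;
      int pick = -1;
      for (size_t u = 0; u < tun.size(); ++u) {
        if (used[u] || t2c[tun[u]]) continue;
        if (tmplElem[tun[u] - 1] == candElem[cc - 1]) { pick = (int)u; break; }
      }
      if (pick < 0)
        for (size_t u = 0; u < tun.size(); ++u)
          if (!used[u] && !t2c[tun[u]]) { pick = (int)u; break; }
      if (pick < 0) break;
      used[pick] = true;
      const int tt = tun[pick];
      c2t[cc] = tt; t2c[tt] = cc;
      ++matched;
      if (candElem[cc - 1] == tmplElem[tt - 1]) ++elemId;
      q.push_back(std::make_pair(cc, tt));
    }
  }
  IntegerVector mapping(nc, NA_INTEGER);
  for (int k = 1; k <= nc; ++k) if (c2t[k]) mapping[k - 1] = c2t[k];
  return List::create(_["mapping"] = mapping,
                      _["matched"] = matched,
                      _["elemIdentical"] = elemId);
}
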