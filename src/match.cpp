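// Subgraph-isomorphism (monomorphism) engine: VF2-style backtracking with
// rarest-element-first candidate ordering. Atoms match on element, aromatic
// flag and charge (the latter two switchable), plus an optional minimum
// hydrogen-count constraint on query atoms; bonds match single/double/triple
// exactly and aromatic-to-aromatic (a documented flag relaxes the
// kekule/aromatic boundary). Used both for search confirmation and for the
// 512 fragment evaluations behind the fingerprint descriptor.

#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <set>
#include <vector>
using namespace Rcpp;

struct CGraph {
  int n;
  std::vector<int> el, arom, charge, minh, toth;
  std::vector<int> bi, bj, bord, barom;     // bonds, 0-based endpoints
  std::vector<std::vector<int>> nbr, nbond; // adjacency
  std::vector<int> deg;

  explicit CGraph(const List& g) {
    IntegerVector e = g["el"], a = g["arom"], q = g["charge"],
                  mh = g["minh"], th = g["toth"],
                  i1 = g["bi"], j1 = g["bj"], bo = g["bord"], ba = g["barom"];
    n = e.size();
    el.assign(e.begin(), e.end());
    arom.assign(a.begin(), a.end());
    charge.assign(q.begin(), q.end());
    minh.assign(mh.begin(), mh.end());
    toth.assign(th.begin(), th.end());
    bi.assign(i1.begin(), i1.end());
    bj.assign(j1.begin(), j1.end());
    bord.assign(bo.begin(), bo.end());
    barom.assign(ba.begin(), ba.end());
    nbr.assign(n, {});
    nbond.assign(n, {});
    for (size_t b = 0; b < bi.size(); ++b) {
      nbr[bi[b]].push_back(bj[b]); nbond[bi[b]].push_back((int)b);
      nbr[bj[b]].push_back(bi[b]); nbond[bj[b]].push_back((int)b);
    }
    deg.resize(n);
    for (int a2 = 0; a2 < n; ++a2) deg[a2] = (int)nbr[a2].size();
  }

  int bond_between(int a, int b) const {
    for (size_t k = 0; k < nbr[a].size(); ++k)
      if (nbr[a][k] == b) return nbond[a][k];
    return -1;
  }
};

struct Matcher {
  const CGraph& q;
  const CGraph& t;
  bool arom_strict, charge_strict, counting;
  long cap;                       // stop once this many images are found
  std::vector<int> order;         // query visit order (connected extension)
  std::vector<int> qmap;          // query -> target
  std::vector<char> used;
  std::set<std::vector<int>> images;
  bool found = false;

  Matcher(const CGraph& q_, const CGraph& t_, bool as, bool cs,
          bool count, long cap_)
      : q(q_), t(t_), arom_strict(as), charge_strict(cs),
        counting(count), cap(cap_) {
    build_order();
    qmap.assign(q.n, -1);
    used.assign(t.n, 0);
  }

  bool atom_ok(int qa, int ta) const {
    if (q.el[qa] != t.el[ta]) return false;
    if (arom_strict && q.arom[qa] != t.arom[ta]) return false;
    if (charge_strict && q.charge[qa] != t.charge[ta]) return false;
    if (q.minh[qa] >= 0 && t.toth[ta] < q.minh[qa]) return false;
    if (q.deg[qa] > t.deg[ta]) return false;
    return true;
  }

  bool bond_ok(int qb, int tb) const {
    bool qa = q.barom[qb], ta = t.barom[tb];
    if (arom_strict) {
      if (qa != ta) return false;
      return qa || q.bord[qb] == t.bord[tb];
    }
    if (qa) return ta || t.bord[tb] <= 2;
    if (q.bord[qb] == 3) return !ta && t.bord[tb] == 3;
    return ta ? q.bord[qb] <= 2 : q.bord[qb] == t.bord[tb];
  }

  void build_order() {
    // element rarity in the target
    std::vector<int> tcount(200, 0);
    for (int a = 0; a < t.n; ++a)
      if (t.el[a] < 200) tcount[t.el[a]]++;
    std::vector<char> placed(q.n, 0);
    order.reserve(q.n);
    while ((int)order.size() < q.n) {
      // next component seed: rarest element, ties by index
      int seed = -1;
      for (int a = 0; a < q.n; ++a) {
        if (placed[a]) continue;
        if (seed < 0) { seed = a; continue; }
        int ca = q.el[a] < 200 ? tcount[q.el[a]] : 0;
        int cs = q.el[seed] < 200 ? tcount[q.el[seed]] : 0;
        if (ca < cs) seed = a;
      }
      order.push_back(seed); placed[seed] = 1;
      // grow by connected extension, rarest-element frontier first
      for (;;) {
        int best = -1, bestc = INT_MAX;
        for (size_t k = 0; k < order.size(); ++k) {
          for (int v : q.nbr[order[k]]) {
            if (placed[v]) continue;
            int c = q.el[v] < 200 ? tcount[q.el[v]] : 0;
            if (c < bestc) { bestc = c; best = v; }
          }
        }
        if (best < 0) break;
        order.push_back(best); placed[best] = 1;
      }
    }
  }

  bool feasible(int qa, int ta) {
    if (!atom_ok(qa, ta)) return false;
    for (size_t k = 0; k < q.nbr[qa].size(); ++k) {
      int qn = q.nbr[qa][k];
      if (qmap[qn] < 0) continue;
      int tb = t.bond_between(ta, qmap[qn]);
      if (tb < 0 || !bond_ok(q.nbond[qa][k], tb)) return false;
    }
    return true;
  }

  bool run(size_t k) {
    if ((long)images.size() >= cap && counting) return true;
    if (k == order.size()) {
      if (!counting) { found = true; return true; }
      std::vector<int> img;
      img.reserve(q.n);
      for (int m : qmap) img.push_back(m);
      std::sort(img.begin(), img.end());
      images.insert(img);
      return (long)images.size() >= cap;
    }
    int qa = order[k];
    // anchor on a mapped neighbor when available
    int anchor = -1;
    for (int qn : q.nbr[qa]) if (qmap[qn] >= 0) { anchor = qn; break; }
    if (anchor >= 0) {
      for (int ta : t.nbr[qmap[anchor]]) {
        if (used[ta] || !feasible(qa, ta)) continue;
        qmap[qa] = ta; used[ta] = 1;
        if (run(k + 1)) { if (!counting) return true; }
        qmap[qa] = -1; used[ta] = 0;
        if (counting && (long)images.size() >= cap) return true;
      }
    } else {
      for (int ta = 0; ta < t.n; ++ta) {
        if (used[ta] || !feasible(qa, ta)) continue;
        qmap[qa] = ta; used[ta] = 1;
        if (run(k + 1)) { if (!counting) return true; }
        qmap[qa] = -1; used[ta] = 0;
        if (counting && (long)images.size() >= cap) return true;
      }
    }
    return !counting && found;
  }
};

// [[Rcpp::export]]
bool cpp_is_substructure(List query, List target, bool aromatic_strict,
                         bool charge_strict) {
  CGraph q(query), t(target);
  if (q.n > t.n || q.bi.size() > t.bi.size()) return false;
  Matcher m(q, t, aromatic_strict, charge_strict, false, 1);
  m.run(0);
  return m.found;
}

// [[Rcpp::export]]
int cpp_count_matches(List query, List target, bool aromatic_strict,
                      bool charge_strict, int cap) {
  CGraph q(query), t(target);
  if (q.n > t.n || q.bi.size() > t.bi.size()) return 0;
  Matcher m(q, t, aromatic_strict, charge_strict, true, cap);
  m.run(0);
  return (int)m.images.size();
}

// Evaluate all dictionary fragments against one molecule. Every fragment is
// evaluated exactly once; the only short-circuit is a provably sound
// element/size pre-check (an embedding maps distinct atoms to distinct atoms
// of equal element and distinct bonds to distinct bonds).
// [[Rcpp::export]]
IntegerVector cpp_descriptor(List fragments, IntegerVector min_count,
                             List mol, bool aromatic_strict,
                             bool charge_strict) {
  CGraph t(mol);
  std::vector<int> tcount(200, 0);
  int tarom = 0;
  for (int a = 0; a < t.n; ++a) {
    if (t.el[a] < 200) tcount[t.el[a]]++;
    if (t.arom[a]) tarom++;
  }
  int nf = fragments.size();
  IntegerVector bits(nf);
  for (int f = 0; f < nf; ++f) {
    CGraph q(List(fragments[f]));
    bool possible = q.n <= t.n && q.bi.size() <= t.bi.size();
    if (possible) {
      std::vector<int> qcount(200, 0);
      int qarom = 0;
      for (int a = 0; a < q.n; ++a) {
        if (q.el[a] < 200) qcount[q.el[a]]++;
        if (q.arom[a]) qarom++;
      }
      for (int e = 0; e < 200 && possible; ++e)
        if (qcount[e] > tcount[e]) possible = false;
      if (aromatic_strict && qarom > tarom) possible = false;
    }
    if (!possible) { bits[f] = 0; continue; }
    int need = min_count[f];
    if (need <= 1) {
      Matcher m(q, t, aromatic_strict, charge_strict, false, 1);
      m.run(0);
      bits[f] = m.found ? 1 : 0;
    } else {
      Matcher m(q, t, aromatic_strict, charge_strict, true, need);
      m.run(0);
      bits[f] = ((int)m.images.size() >= need) ? 1 : 0;
    }
  }
  return bits;
}
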