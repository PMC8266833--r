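// Hybrid pool/particle stochastic simulation engine.
//
// Freely diffusing chemicals are integer pools; sequence-bound molecules are
// individually tracked particles (BoundUnit) carrying a template reference,
// a reading position and the binding site they originated from.  Reaction
// channels are selected with an exact SSA using one of three interchangeable
// structures: linear scan (direct), binary partial-sum tree, or
// composition-rejection groups.  Propensities are refreshed through a
// dependency graph keyed on free pools, bound classes and site families.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <limits>
#include <map>
#include <random>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: single seedable 64-bit stream per engine; all stochastic choices
// (waiting time, channel, site, unit, rejection draws) consume it in a fixed
// documented order, which is the reproducibility contract.
struct Rng {
  std::mt19937_64 gen;
  void reseed(uint64_t s) { gen.seed(s); }
  double unif() {  // [0, 1)
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
  double unif_pos() {  // (0, 1)
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
  int below(int n) {  // uniform integer in [0, n)
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

// ---------------------------------------------------------------------------
// Reaction-selection store.  Holds the authoritative propensity vector and a
// strategy-specific structure kept in sync through set().  Totals are
// refreshed from scratch periodically to bound floating-point drift.
struct Store {
  enum { DIRECT = 0, TREE = 1, CR = 2 };
  int strat = DIRECT;
  std::vector<double> av;
  double tot = 0.0;
  long long npos = 0;
  long long nupd = 0;
  static constexpr long long REFRESH_EVERY = 1000000;

  // tree
  std::vector<double> tree;
  int tbase = 0;

  // composition-rejection
  struct Group { std::vector<int> m; double sum = 0.0; };
  std::map<int, Group> groups;
  std::vector<int> g_of, i_of;
  static constexpr int G_NONE = INT_MIN;

  void build(int strategy, const std::vector<double>& a) {
    strat = strategy;
    av = a;
    int R = static_cast<int>(av.size());
    tot = 0.0; npos = 0; nupd = 0;
    for (double v : av) { tot += v; if (v > 0) ++npos; }
    if (strat == TREE) {
      tbase = 1;
      while (tbase < R) tbase <<= 1;
      if (tbase < 1) tbase = 1;
      tree.assign(2 * tbase, 0.0);
      for (int i = 0; i < R; ++i) tree[tbase + i] = av[i];
      for (int i = tbase - 1; i >= 1; --i) tree[i] = tree[2 * i] + tree[2 * i + 1];
    } else if (strat == CR) {
      groups.clear();
      g_of.assign(R, G_NONE);
      i_of.assign(R, -1);
      for (int i = 0; i < R; ++i) cr_insert(i, av[i]);
    }
  }

  void cr_insert(int ch, double v) {
    if (v <= 0) { g_of[ch] = G_NONE; return; }
    int g = std::ilogb(v);
    Group& G = groups[g];
    g_of[ch] = g;
    i_of[ch] = static_cast<int>(G.m.size());
    G.m.push_back(ch);
    G.sum += v;
  }

  void cr_remove(int ch, double old) {
    int g = g_of[ch];
    if (g == G_NONE) return;
    Group& G = groups[g];
    int last = G.m.back();
    G.m[i_of[ch]] = last;
    i_of[last] = i_of[ch];
    G.m.pop_back();
    G.sum -= old;
    if (G.m.empty()) groups.erase(g);
    g_of[ch] = G_NONE;
  }

  void set(int ch, double v) {
    double old = av[ch];
    if (old == v) return;
    av[ch] = v;
    tot += v - old;
    npos += (v > 0 ? 1 : 0) - (old > 0 ? 1 : 0);
    if (strat == TREE) {
      int node = tbase + ch;
      tree[node] = v;
      for (node >>= 1; node >= 1; node >>= 1)
        tree[node] = tree[2 * node] + tree[2 * node + 1];
    } else if (strat == CR) {
      int g = (v > 0) ? std::ilogb(v) : G_NONE;
      if (g == g_of[ch]) {
        groups[g].sum += v - old;
      } else {
        cr_remove(ch, old);
        cr_insert(ch, v);
      }
    }
    if (++nupd % REFRESH_EVERY == 0) refresh_sums();
  }

  void refresh_sums() {
    tot = 0.0; npos = 0;
    for (double v : av) { tot += v; if (v > 0) ++npos; }
    if (strat == TREE) {
      for (int i = tbase - 1; i >= 1; --i) tree[i] = tree[2 * i] + tree[2 * i + 1];
    } else if (strat == CR) {
      for (auto& kv : groups) {
        kv.second.sum = 0.0;
        for (int ch : kv.second.m) kv.second.sum += av[ch];
      }
    }
  }

  // Deterministic selection given a single uniform for DIRECT/TREE; CR also
  // consumes rejection draws.  Returns -1 when no channel has positive rate.
  int select(Rng& rng) {
    if (npos == 0) return -1;
    double u = rng.unif();
    if (strat == DIRECT) return select_direct(u);
    if (strat == TREE) return select_tree(u);
    return select_cr(u, rng);
  }

  int select_direct(double u) const {
    double thr = u * tot, cum = 0.0;
    int lastpos = -1, R = static_cast<int>(av.size());
    for (int i = 0; i < R; ++i) {
      if (av[i] > 0) lastpos = i;
      cum += av[i];
      if (cum >= thr && av[i] > 0) return i;
    }
    return lastpos;  // floating-point drift fallback
  }

  int select_tree(double u) const {
    double thr = u * tot;
    int node = 1;
    while (node < tbase) {
      int left = 2 * node;
      if (tree[left] >= thr) node = left;
      else { thr -= tree[left]; node = left + 1; }
    }
    int ch = node - tbase;
    int R = static_cast<int>(av.size());
    if (ch >= R) ch = R - 1;
    while (ch > 0 && av[ch] <= 0) --ch;       // fp edge: walk to a live channel
    while (ch < R - 1 && av[ch] <= 0) ++ch;
    return av[ch] > 0 ? ch : -1;
  }

  int select_cr(double u, Rng& rng) {
    double thr = u * tot, cum = 0.0;
    const Group* pick = nullptr;
    int gexp = 0;
    for (auto& kv : groups) {
      cum += kv.second.sum;
      pick = &kv.second; gexp = kv.first;
      if (cum >= thr) break;
    }
    if (!pick || pick->m.empty()) return -1;
    double cap = std::ldexp(1.0, gexp + 1);
    for (int iter = 0; iter < 100000; ++iter) {
      int j = pick->m[rng.below(static_cast<int>(pick->m.size()))];
      if (rng.unif() * cap < av[j]) return j;
    }
    return pick->m[0];  // unreachable in practice: acceptance prob >= 1/2
  }
};

// ---------------------------------------------------------------------------
// Model state.

struct Free { std::string name; long long count = 0; bool buffered = false; };

struct Site {
  int fam = -1, seq = -1, first = 0, last = 0, offset = 0;
  double kon = 0.0, koff = 0.0;
  long long occupied = 0;
};

struct Family { std::string name; std::vector<int> sites; double kon_avail = 0.0; };

struct Seqn {
  std::string name;
  std::string letters;
  long long copies = 0;
  std::unordered_map<int, std::vector<int>> switches;   // position -> switch ids
  std::vector<std::pair<int, double>> famkon;           // family -> sum of kon of its sites here
};

struct SwitchT { std::string name; int in_cls = -1, out_cls = -1; };

struct Unit {
  int seq = -1, pos = 0, site = -1;
  bool on_origin = false;
  int cls = -1, idx = -1;
  int ff_which = -1, ff_idx = -1;
  int tf_part = -1, tf_idx = -1;
};

struct FamFilter { int fam = -1; std::vector<int> members; double koff_sum = 0.0; };

struct TemplFilter {
  int len = 0;
  std::vector<std::vector<int>> parts;
  std::vector<std::string> part_motif;
  std::unordered_map<std::string, int> motif2part;
};

struct BClass {
  std::string name;
  std::vector<int> members;
  std::vector<FamFilter> ffs;
  bool has_tf = false;
  TemplFilter tf;
};

struct ChemRxn {
  std::string name;
  std::vector<std::pair<int, long long>> rf, pf;  // (free id, stoichiometry)
  int rb = -1, pb = -1;                           // bound reactant / product class
  double kf = 0.0, kb = 0.0;
};

struct BindRxn { std::string name; int fc = -1, bc = -1, fam = -1; };

struct TransRxn { std::string name; int mob = -1, post = -1, step = 1; double rate = 0.0; };

struct LoadRxn {
  std::string name;
  int loader = -1, len = 1;
  std::vector<std::string> motif;
  std::vector<int> loaded, post;
  std::vector<double> rate;
  std::vector<std::vector<int>> byp;
};

struct RelRxn {
  std::string name;
  int cls = -1;
  double rate = 0.0;
  std::vector<int> freed;
  std::vector<int> t_fam, t_first, t_last, t_prod;
  bool warn_unmatched = false;
};

enum ChType { CH_CHEMF = 0, CH_CHEMR, CH_BINDF, CH_BINDR, CH_TRANS, CH_LOAD, CH_REL };
struct Chan { int type, rx, sub; };

enum EvKind { EV_ADD = 0, EV_SET = 1, EV_REMOVE_FREE = 2 };
struct TimedEv { double time; int kind; int target; long long amount; };

// ---------------------------------------------------------------------------
struct Engine {
  std::vector<Free> frees;
  std::vector<Seqn> seqs;
  std::vector<BClass> classes;
  std::vector<Site> sites;
  std::vector<Family> fams;
  std::vector<SwitchT> sws;
  std::vector<Unit> units;
  std::vector<int> unit_free;

  std::vector<ChemRxn> chems;
  std::vector<BindRxn> binds;
  std::vector<TransRxn> transs;
  std::vector<LoadRxn> loads;
  std::vector<RelRxn> rels;
  std::vector<TimedEv> events;

  std::unordered_map<std::string, std::pair<int, int>> species;  // kind: 0 free, 1 seq, 2 class, 3 switch
  std::unordered_map<std::string, std::pair<int, int>> rxns;     // rtype: 0 chem, 1 bind, 2 trans, 3 load, 4 rel
  std::unordered_map<std::string, int> famidx;

  bool finalized = false;
  bool store_built = false;
  Rng rng;
  Store store;

  std::vector<Chan> chans;
  std::vector<std::vector<int>> dep_free, dep_cls, dep_fam;
  std::vector<int> stamp;
  int cur_stamp = 0;
  std::vector<int> t_free, t_cls, t_fam;

  long long created = 0, destroyed = 0, live = 0;

  // -- registration -------------------------------------------------------
  void need_open(const char* what) {
    if (finalized) stop("cannot add %s: system already finalized", what);
  }
  void reg_species(const std::string& n, int kind, int id) {
    if (species.count(n)) stop("duplicate species name '%s'", n.c_str());
    species[n] = {kind, id};
  }
  void reg_rxn(const std::string& n, int rt, int id) {
    if (rxns.count(n)) stop("duplicate reaction name '%s'", n.c_str());
    rxns[n] = {rt, id};
  }
  std::pair<int, int> find_species(const std::string& n) {
    auto it = species.find(n);
    if (it == species.end()) stop("unknown species '%s'", n.c_str());
    return it->second;
  }
  int free_id(const std::string& n) {
    auto p = find_species(n);
    if (p.first != 0) stop("'%s' is not a free chemical", n.c_str());
    return p.second;
  }
  int seq_id(const std::string& n) {
    auto p = find_species(n);
    if (p.first != 1) stop("'%s' is not a sequence", n.c_str());
    return p.second;
  }
  int cls_id(const std::string& n) {
    auto p = find_species(n);
    if (p.first != 2) stop("'%s' is not a bound chemical", n.c_str());
    return p.second;
  }
  int sw_id(const std::string& n) {
    auto p = find_species(n);
    if (p.first != 3) stop("'%s' is not a switch", n.c_str());
    return p.second;
  }
  int fam_id(const std::string& n) {
    auto it = famidx.find(n);
    if (it == famidx.end()) stop("unknown site family '%s'", n.c_str());
    return it->second;
  }

  // -- filter-aware particle bookkeeping ----------------------------------
  void add_to_class(int uid, int cid) {
    Unit& u = units[uid];
    BClass& c = classes[cid];
    u.cls = cid;
    u.idx = static_cast<int>(c.members.size());
    c.members.push_back(uid);
    u.ff_which = -1; u.tf_part = -1;
    if (u.on_origin && u.site >= 0) {
      int f = sites[u.site].fam;
      for (size_t k = 0; k < c.ffs.size(); ++k) {
        if (c.ffs[k].fam == f) {
          u.ff_which = static_cast<int>(k);
          u.ff_idx = static_cast<int>(c.ffs[k].members.size());
          c.ffs[k].members.push_back(uid);
          c.ffs[k].koff_sum += sites[u.site].koff;
          break;
        }
      }
    }
    if (c.has_tf) {
      const std::string& L = seqs[u.seq].letters;
      if (u.pos >= 0 && u.pos + c.tf.len <= static_cast<int>(L.size())) {
        std::string m = L.substr(u.pos, c.tf.len);
        auto it = c.tf.motif2part.find(m);
        int p;
        if (it == c.tf.motif2part.end()) {
          p = static_cast<int>(c.tf.parts.size());
          c.tf.motif2part[m] = p;
          c.tf.parts.emplace_back();
          c.tf.part_motif.push_back(m);
        } else p = it->second;
        u.tf_part = p;
        u.tf_idx = static_cast<int>(c.tf.parts[p].size());
        c.tf.parts[p].push_back(uid);
      }
    }
  }

  void remove_from_class(int uid) {
    Unit& u = units[uid];
    BClass& c = classes[u.cls];
    int last = c.members.back();
    c.members[u.idx] = last;
    units[last].idx = u.idx;
    c.members.pop_back();
    if (u.ff_which >= 0) {
      FamFilter& ff = c.ffs[u.ff_which];
      int lb = ff.members.back();
      ff.members[u.ff_idx] = lb;
      units[lb].ff_idx = u.ff_idx;
      ff.members.pop_back();
      ff.koff_sum -= sites[u.site].koff;
      u.ff_which = -1;
    }
    if (u.tf_part >= 0) {
      auto& part = c.tf.parts[u.tf_part];
      int lb = part.back();
      part[u.tf_idx] = lb;
      units[lb].tf_idx = u.tf_idx;
      part.pop_back();
      u.tf_part = -1;
    }
    u.cls = -1;
  }

  int new_unit() {
    int id;
    if (!unit_free.empty()) { id = unit_free.back(); unit_free.pop_back(); }
    else { id = static_cast<int>(units.size()); units.push_back(Unit()); }
    ++created; ++live;
    return id;
  }

  void leave_origin(int uid) {  // occupancy released when a unit quits its site
    Unit& u = units[uid];
    if (!u.on_origin) return;
    Site& s = sites[u.site];
    --s.occupied;
    fams[s.fam].kon_avail += s.kon;
    touch_fam(s.fam);
    u.on_origin = false;
  }

  void destroy_unit(int uid) {
    Unit& u = units[uid];
    if (u.cls >= 0) remove_from_class(uid);
    leave_origin(uid);
    u.site = -1; u.seq = -1;
    unit_free.push_back(uid);
    ++destroyed; --live;
  }

  // -- touched components -------------------------------------------------
  void touch_free(int i) { t_free.push_back(i); }
  void touch_cls(int i) { t_cls.push_back(i); }
  void touch_fam(int i) { t_fam.push_back(i); }

  void refresh_touched() {
    if (store_built) {
      ++cur_stamp;
      auto handle = [&](const std::vector<int>& v) {
        for (int ch : v) {
          if (stamp[ch] != cur_stamp) {
            stamp[ch] = cur_stamp;
            store.set(ch, prop(chans[ch]));
          }
        }
      };
      for (int f : t_free) handle(dep_free[f]);
      for (int c : t_cls) handle(dep_cls[c]);
      for (int f : t_fam) handle(dep_fam[f]);
    }
    t_free.clear(); t_cls.clear(); t_fam.clear();
  }

  // -- propensities -------------------------------------------------------
  static double fallfac(long long n, long long k) {
    if (n < k) return 0.0;
    double p = 1.0;
    for (long long i = 0; i < k; ++i) p *= static_cast<double>(n - i);
    // high-stoichiometry channels (stacked regeneration) can overflow; a
    // huge finite propensity keeps selection arithmetic well defined and
    // fires the channel essentially immediately, which is the intent
    if (!std::isfinite(p)) return std::numeric_limits<double>::max() / 1e9;
    return p;
  }

  double prop(const Chan& ch) {
    switch (ch.type) {
      case CH_CHEMF: {
        const ChemRxn& r = chems[ch.rx];
        double p = r.kf;
        for (auto& q : r.rf) p *= fallfac(frees[q.first].count, q.second);
        if (r.rb >= 0) p *= static_cast<double>(classes[r.rb].members.size());
        return p;
      }
      case CH_CHEMR: {
        const ChemRxn& r = chems[ch.rx];
        double p = r.kb;
        for (auto& q : r.pf) p *= fallfac(frees[q.first].count, q.second);
        if (r.pb >= 0) p *= static_cast<double>(classes[r.pb].members.size());
        return p;
      }
      case CH_BINDF: {
        const BindRxn& b = binds[ch.rx];
        double s = fams[b.fam].kon_avail;
        return s > 0 ? frees[b.fc].count * s : 0.0;
      }
      case CH_BINDR: {
        const BindRxn& b = binds[ch.rx];
        const BClass& c = classes[b.bc];
        for (auto& ff : c.ffs)
          if (ff.fam == b.fam) return ff.koff_sum > 0 ? ff.koff_sum : 0.0;
        return 0.0;
      }
      case CH_TRANS: {
        const TransRxn& t = transs[ch.rx];
        return t.rate * static_cast<double>(classes[t.mob].members.size());
      }
      case CH_LOAD: {
        const LoadRxn& l = loads[ch.rx];
        const BClass& c = classes[l.loader];
        auto it = c.tf.motif2part.find(l.motif[ch.sub]);
        if (it == c.tf.motif2part.end()) return 0.0;
        double n = static_cast<double>(c.tf.parts[it->second].size());
        return l.rate[ch.sub] * static_cast<double>(frees[l.loaded[ch.sub]].count) * n;
      }
      case CH_REL: {
        const RelRxn& r = rels[ch.rx];
        return r.rate * static_cast<double>(classes[r.cls].members.size());
      }
    }
    return 0.0;
  }

  // -- firing semantics ---------------------------------------------------
  // RNG order within a firing: site/partition choice first, then unit choice.
  void fire_bind_f(int bi) {
    BindRxn& b = binds[bi];
    Family& F = fams[b.fam];
    double thr = rng.unif() * F.kon_avail, cum = 0.0;
    int pick = -1, lastavail = -1;
    for (int sid : F.sites) {
      Site& s = sites[sid];
      long long avail = seqs[s.seq].copies - s.occupied;
      if (avail > 0) {
        lastavail = sid;
        cum += s.kon * avail;
        if (cum >= thr) { pick = sid; break; }
      }
    }
    if (pick < 0) pick = lastavail;
    if (pick < 0) stop("impossible reaction: no available site in family '%s'", F.name.c_str());
    Site& s = sites[pick];
    if (!frees[b.fc].buffered) { --frees[b.fc].count; touch_free(b.fc); }
    ++s.occupied;
    F.kon_avail -= s.kon;
    touch_fam(b.fam);
    int uid = new_unit();
    Unit& u = units[uid];
    u.seq = s.seq; u.pos = s.offset; u.site = pick; u.on_origin = true;
    add_to_class(uid, b.bc);
    touch_cls(b.bc);
  }

  void fire_bind_r(int bi) {
    BindRxn& b = binds[bi];
    BClass& c = classes[b.bc];
    FamFilter* ff = nullptr;
    for (auto& f : c.ffs) if (f.fam == b.fam) { ff = &f; break; }
    if (!ff || ff->members.empty())
      stop("impossible reaction: no unit of '%s' still on a '%s' site",
           c.name.c_str(), fams[b.fam].name.c_str());
    double thr = rng.unif() * ff->koff_sum, cum = 0.0;
    int uid = ff->members.back();
    for (int m : ff->members) {
      cum += sites[units[m].site].koff;
      if (cum >= thr) { uid = m; break; }
    }
    destroy_unit(uid);
    if (!frees[b.fc].buffered) { ++frees[b.fc].count; touch_free(b.fc); }
    touch_cls(b.bc);
  }

  void apply_switches(int uid) {
    Unit& u = units[uid];
    auto it = seqs[u.seq].switches.find(u.pos);
    if (it == seqs[u.seq].switches.end()) return;
    for (int swid : it->second) {
      if (sws[swid].in_cls == u.cls) {
        remove_from_class(uid);
        add_to_class(uid, sws[swid].out_cls);
        touch_cls(sws[swid].out_cls);
        break;
      }
    }
  }

  void fire_trans(int ti) {
    TransRxn& t = transs[ti];
    BClass& c = classes[t.mob];
    if (c.members.empty()) stop("impossible reaction: class '%s' empty", c.name.c_str());
    int uid = c.members[rng.below(static_cast<int>(c.members.size()))];
    remove_from_class(uid);
    leave_origin(uid);
    Unit& u = units[uid];
    int len = static_cast<int>(seqs[u.seq].letters.size());
    u.pos = std::min(u.pos + t.step, len);
    add_to_class(uid, t.post);
    touch_cls(t.mob);
    touch_cls(t.post);
    apply_switches(uid);
  }

  void fire_load(int li, int sub) {
    LoadRxn& l = loads[li];
    BClass& c = classes[l.loader];
    auto it = c.tf.motif2part.find(l.motif[sub]);
    if (it == c.tf.motif2part.end() || c.tf.parts[it->second].empty())
      stop("impossible reaction: no unit of '%s' reading motif '%s'",
           c.name.c_str(), l.motif[sub].c_str());
    auto& part = c.tf.parts[it->second];
    int uid = part[rng.below(static_cast<int>(part.size()))];
    int lid = l.loaded[sub];
    if (!frees[lid].buffered) { --frees[lid].count; touch_free(lid); }
    for (int b : l.byp[sub])
      if (!frees[b].buffered) { ++frees[b].count; touch_free(b); }
    remove_from_class(uid);
    add_to_class(uid, l.post[sub]);
    touch_cls(l.loader);
    touch_cls(l.post[sub]);
  }

  void fire_rel(int ri) {
    RelRxn& r = rels[ri];
    BClass& c = classes[r.cls];
    if (c.members.empty()) stop("impossible reaction: class '%s' empty", c.name.c_str());
    int uid = c.members[rng.below(static_cast<int>(c.members.size()))];
    Unit& u = units[uid];
    int prod = -1;
    if (u.site >= 0) {
      int f = sites[u.site].fam;
      for (size_t k = 0; k < r.t_fam.size(); ++k) {
        if (r.t_fam[k] == f && u.pos >= r.t_first[k] && u.pos < r.t_last[k]) {
          prod = r.t_prod[k];
          break;
        }
      }
    }
    if (prod >= 0) {
      Seqn& ps = seqs[prod];
      ++ps.copies;
      for (auto& pr : ps.famkon) {
        fams[pr.first].kon_avail += pr.second;
        touch_fam(pr.first);
      }
    } else if (r.warn_unmatched) {
      Rf_warning("release '%s': position %d (origin family %s) matches no product interval",
                 r.name.c_str(), u.pos,
                 u.site >= 0 ? fams[sites[u.site].fam].name.c_str() : "<none>");
    } else {
      stop("release '%s': position %d (origin family %s) matches no product interval",
           r.name.c_str(), u.pos,
           u.site >= 0 ? fams[sites[u.site].fam].name.c_str() : "<none>");
    }
    for (int fid : r.freed)
      if (!frees[fid].buffered) { ++frees[fid].count; touch_free(fid); }
    destroy_unit(uid);
    touch_cls(r.cls);
  }

  void fire_chem(int ci, bool fwd) {
    ChemRxn& r = chems[ci];
    auto& cons = fwd ? r.rf : r.pf;
    auto& prod = fwd ? r.pf : r.rf;
    int bcons = fwd ? r.rb : r.pb;
    int bprod = fwd ? r.pb : r.rb;
    for (auto& q : cons) {
      Free& f = frees[q.first];
      if (!f.buffered) {
        f.count -= q.second;
        if (f.count < 0) stop("negative count for '%s'", f.name.c_str());
        touch_free(q.first);
      }
    }
    for (auto& q : prod) {
      Free& f = frees[q.first];
      if (!f.buffered) { f.count += q.second; touch_free(q.first); }
    }
    if (bcons >= 0) {
      BClass& c = classes[bcons];
      if (c.members.empty()) stop("impossible reaction: class '%s' empty", c.name.c_str());
      int uid = c.members[rng.below(static_cast<int>(c.members.size()))];
      if (bprod >= 0) {
        remove_from_class(uid);
        add_to_class(uid, bprod);
        touch_cls(bprod);
      } else {
        destroy_unit(uid);
      }
      touch_cls(bcons);
    }
  }

  void fire_channel(const Chan& ch) {
    switch (ch.type) {
      case CH_CHEMF: fire_chem(ch.rx, true); break;
      case CH_CHEMR: fire_chem(ch.rx, false); break;
      case CH_BINDF: fire_bind_f(ch.rx); break;
      case CH_BINDR: fire_bind_r(ch.rx); break;
      case CH_TRANS: fire_trans(ch.rx); break;
      case CH_LOAD: fire_load(ch.rx, ch.sub); break;
      case CH_REL: fire_rel(ch.rx); break;
    }
  }

  void apply_event_now(int kind, int target, long long amount) {
    Free& f = frees[target];
    switch (kind) {
      case EV_ADD: f.count += amount; break;
      case EV_SET: f.count = amount; break;
      case EV_REMOVE_FREE: f.count = std::max(0LL, f.count - amount); break;
      default: stop("unknown event kind");
    }
    touch_free(target);
  }

  // -- finalization -------------------------------------------------------
  void finalize() {
    if (finalized) stop("system already finalized");
    // per-sequence family kon sums (for copy-number changes)
    for (auto& s : seqs) s.famkon.clear();
    for (size_t fid = 0; fid < fams.size(); ++fid) {
      std::unordered_map<int, double> per_seq;
      for (int sid : fams[fid].sites) per_seq[sites[sid].seq] += sites[sid].kon;
      for (auto& kv : per_seq)
        seqs[kv.first].famkon.push_back({static_cast<int>(fid), kv.second});
    }
    // availability sums
    for (auto& F : fams) {
      F.kon_avail = 0.0;
      for (int sid : F.sites)
        F.kon_avail += sites[sid].kon * static_cast<double>(seqs[sites[sid].seq].copies);
    }
    // family filters for unbinding
    for (auto& b : binds) {
      BClass& c = classes[b.bc];
      bool found = false;
      for (auto& ff : c.ffs) if (ff.fam == b.fam) { found = true; break; }
      if (!found) {
        FamFilter ff; ff.fam = b.fam;
        c.ffs.push_back(ff);
      }
    }
    // template filters for loading; one motif length per class
    for (auto& l : loads) {
      BClass& c = classes[l.loader];
      if (c.has_tf && c.tf.len != l.len)
        stop("bound chemical '%s' has loadings with conflicting motif lengths", c.name.c_str());
      if (!c.has_tf) { c.has_tf = true; c.tf.len = l.len; }
      for (auto& m : l.motif) {
        if (static_cast<int>(m.size()) != l.len)
          stop("loading '%s': motif '%s' does not have length %d", l.name.c_str(), m.c_str(), l.len);
        if (!c.tf.motif2part.count(m)) {
          c.tf.motif2part[m] = static_cast<int>(c.tf.parts.size());
          c.tf.parts.emplace_back();
          c.tf.part_motif.push_back(m);
        }
      }
    }
    // reversible bound-reaction validation
    for (auto& r : chems) {
      if (r.pb >= 0 && r.rb < 0)
        stop("reaction '%s': a bound product requires a bound reactant", r.name.c_str());
      if (r.kb > 0 && r.rb >= 0 && r.pb < 0)
        stop("reaction '%s': reversible reactions destroying a bound unit are not allowed",
             r.name.c_str());
    }
    // release tables: intervals for one family must be disjoint
    for (auto& r : rels) {
      for (size_t i = 0; i < r.t_fam.size(); ++i)
        for (size_t j = i + 1; j < r.t_fam.size(); ++j)
          if (r.t_fam[i] == r.t_fam[j] &&
              r.t_first[i] < r.t_last[j] && r.t_first[j] < r.t_last[i])
            stop("release '%s': overlapping product intervals for family '%s'",
                 r.name.c_str(), fams[r.t_fam[i]].name.c_str());
    }
    // channels, in deterministic registration order
    chans.clear();
    for (size_t i = 0; i < chems.size(); ++i) {
      chans.push_back({CH_CHEMF, static_cast<int>(i), 0});
      if (chems[i].kb > 0) chans.push_back({CH_CHEMR, static_cast<int>(i), 0});
    }
    for (size_t i = 0; i < binds.size(); ++i) {
      chans.push_back({CH_BINDF, static_cast<int>(i), 0});
      chans.push_back({CH_BINDR, static_cast<int>(i), 0});
    }
    for (size_t i = 0; i < transs.size(); ++i)
      chans.push_back({CH_TRANS, static_cast<int>(i), 0});
    for (size_t i = 0; i < loads.size(); ++i)
      for (size_t m = 0; m < loads[i].motif.size(); ++m)
        chans.push_back({CH_LOAD, static_cast<int>(i), static_cast<int>(m)});
    for (size_t i = 0; i < rels.size(); ++i)
      chans.push_back({CH_REL, static_cast<int>(i), 0});
    // dependency graph
    dep_free.assign(frees.size(), {});
    dep_cls.assign(classes.size(), {});
    dep_fam.assign(fams.size(), {});
    for (size_t ci = 0; ci < chans.size(); ++ci) {
      const Chan& ch = chans[ci];
      int i = static_cast<int>(ci);
      switch (ch.type) {
        case CH_CHEMF: {
          const ChemRxn& r = chems[ch.rx];
          for (auto& q : r.rf) dep_free[q.first].push_back(i);
          if (r.rb >= 0) dep_cls[r.rb].push_back(i);
          break;
        }
        case CH_CHEMR: {
          const ChemRxn& r = chems[ch.rx];
          for (auto& q : r.pf) dep_free[q.first].push_back(i);
          if (r.pb >= 0) dep_cls[r.pb].push_back(i);
          break;
        }
        case CH_BINDF: {
          const BindRxn& b = binds[ch.rx];
          dep_free[b.fc].push_back(i);
          dep_fam[b.fam].push_back(i);
          break;
        }
        case CH_BINDR: dep_cls[binds[ch.rx].bc].push_back(i); break;
        case CH_TRANS: dep_cls[transs[ch.rx].mob].push_back(i); break;
        case CH_LOAD: {
          const LoadRxn& l = loads[ch.rx];
          dep_free[l.loaded[ch.sub]].push_back(i);
          dep_cls[l.loader].push_back(i);
          break;
        }
        case CH_REL: dep_cls[rels[ch.rx].cls].push_back(i); break;
      }
    }
    stamp.assign(chans.size(), 0);
    cur_stamp = 0;
    // events sorted by time (stable: ties keep registration order)
    std::stable_sort(events.begin(), events.end(),
                     [](const TimedEv& a, const TimedEv& b) { return a.time < b.time; });
    finalized = true;
  }

  void build_store(int strategy) {
    std::vector<double> a(chans.size());
    for (size_t i = 0; i < chans.size(); ++i) a[i] = prop(chans[i]);
    store.build(strategy, a);
    store_built = true;
    std::fill(stamp.begin(), stamp.end(), 0);
    cur_stamp = 0;
  }

  // -- consistency audit: recompute bookkeeping from scratch ---------------
  void check_scratch(bool check_props) {
    // live units from class membership
    std::vector<long long> occ(sites.size(), 0);
    long long nlive = 0;
    for (size_t c = 0; c < classes.size(); ++c) {
      const BClass& cl = classes[c];
      for (size_t k = 0; k < cl.members.size(); ++k) {
        const Unit& u = units[cl.members[k]];
        if (u.cls != static_cast<int>(c) || u.idx != static_cast<int>(k))
          stop("particle index inconsistency in class '%s'", cl.name.c_str());
        if (u.on_origin) {
          if (u.site < 0) stop("on-origin unit without origin site");
          ++occ[u.site];
        }
        ++nlive;
      }
    }
    if (nlive != live || live != created - destroyed)
      stop("particle conservation violated: live=%lld tracked=%lld created-destroyed=%lld",
           nlive, live, created - destroyed);
    for (size_t s = 0; s < sites.size(); ++s)
      if (occ[s] != sites[s].occupied)
        stop("site occupancy mismatch: stored %lld recomputed %lld",
             sites[s].occupied, occ[s]);
    // family availability sums
    for (auto& F : fams) {
      double sum = 0.0;
      for (int sid : F.sites)
        sum += sites[sid].kon *
               static_cast<double>(seqs[sites[sid].seq].copies - sites[sid].occupied);
      if (std::abs(sum - F.kon_avail) > 1e-9 * std::max(1.0, std::abs(sum)))
        stop("family '%s' availability drift: stored %g recomputed %g",
             F.name.c_str(), F.kon_avail, sum);
    }
    // filters
    for (auto& cl : classes) {
      for (auto& ff : cl.ffs) {
        long long nmatch = 0;
        double ks = 0.0;
        for (int uid : cl.members) {
          const Unit& u = units[uid];
          if (u.on_origin && u.site >= 0 && sites[u.site].fam == ff.fam) {
            ++nmatch;
            ks += sites[u.site].koff;
          }
        }
        if (nmatch != static_cast<long long>(ff.members.size()))
          stop("family filter of '%s' has %d members, scratch recomputation gives %lld",
               cl.name.c_str(), static_cast<int>(ff.members.size()), nmatch);
        for (int uid : ff.members) {
          const Unit& u = units[uid];
          if (!(u.on_origin && u.site >= 0 && sites[u.site].fam == ff.fam))
            stop("family filter of '%s' contains a non-qualifying unit", cl.name.c_str());
        }
        if (std::abs(ks - ff.koff_sum) > 1e-9 * std::max(1.0, std::abs(ks)))
          stop("family filter koff sum drift in '%s'", cl.name.c_str());
      }
      if (cl.has_tf) {
        std::unordered_map<std::string, long long> want;
        for (int uid : cl.members) {
          const Unit& u = units[uid];
          const std::string& L = seqs[u.seq].letters;
          if (u.pos >= 0 && u.pos + cl.tf.len <= static_cast<int>(L.size()))
            ++want[L.substr(u.pos, cl.tf.len)];
        }
        long long tot_in_parts = 0;
        for (size_t p = 0; p < cl.tf.parts.size(); ++p) {
          for (int uid : cl.tf.parts[p]) {
            const Unit& u = units[uid];
            const std::string& L = seqs[u.seq].letters;
            if (!(u.pos + cl.tf.len <= static_cast<int>(L.size()) &&
                  L.compare(u.pos, cl.tf.len, cl.tf.part_motif[p]) == 0))
              stop("template filter of '%s': unit in partition '%s' reads another motif",
                   cl.name.c_str(), cl.tf.part_motif[p].c_str());
          }
          tot_in_parts += static_cast<long long>(cl.tf.parts[p].size());
          long long w = want.count(cl.tf.part_motif[p]) ? want[cl.tf.part_motif[p]] : 0;
          if (w != static_cast<long long>(cl.tf.parts[p].size()))
            stop("template filter of '%s': partition '%s' has %d members, scratch gives %lld",
                 cl.name.c_str(), cl.tf.part_motif[p].c_str(),
                 static_cast<int>(cl.tf.parts[p].size()), w);
        }
        long long wtot = 0;
        for (auto& kv : want) wtot += kv.second;
        if (wtot != tot_in_parts)
          stop("template filter of '%s': partitions miss readable units", cl.name.c_str());
      }
    }
    // propensity store vs full recomputation
    if (check_props && store_built) {
      for (size_t i = 0; i < chans.size(); ++i) {
        double want = prop(chans[i]);
        if (std::abs(want - store.av[i]) > 1e-9 * std::max(1.0, std::abs(want)))
          stop("dependency-graph propensity mismatch on channel %d: stored %g scratch %g",
               static_cast<int>(i), store.av[i], want);
      }
    }
  }
};

// ---------------------------------------------------------------------------
// Rcpp interface

typedef XPtr<Engine> EngPtr;

static Engine* get(SEXP p) {
  EngPtr x(p);
  return x.get();
}

// [[Rcpp::export]]
SEXP eng_new() {
  return EngPtr(new Engine(), true);
}

// [[Rcpp::export]]
void eng_add_free(SEXP p, std::string name, double count, bool buffered) {
  Engine* e = get(p);
  e->need_open("free chemical");
  if (count < 0) stop("initial count of '%s' must be non-negative", name.c_str());
  Free f;
  f.name = name;
  f.count = static_cast<long long>(count);
  f.buffered = buffered;
  e->reg_species(name, 0, static_cast<int>(e->frees.size()));
  e->frees.push_back(f);
}

// [[Rcpp::export]]
void eng_add_seq(SEXP p, std::string name, std::string letters, double copies) {
  Engine* e = get(p);
  e->need_open("sequence");
  if (copies < 0) stop("copies of '%s' must be non-negative", name.c_str());
  Seqn s;
  s.name = name;
  s.letters = letters;
  s.copies = static_cast<long long>(copies);
  e->reg_species(name, 1, static_cast<int>(e->seqs.size()));
  e->seqs.push_back(s);
}

// [[Rcpp::export]]
void eng_add_bound(SEXP p, std::string name) {
  Engine* e = get(p);
  e->need_open("bound chemical");
  BClass c;
  c.name = name;
  e->reg_species(name, 2, static_cast<int>(e->classes.size()));
  e->classes.push_back(c);
}

// [[Rcpp::export]]
void eng_add_switch(SEXP p, std::string name, std::string input, std::string output) {
  Engine* e = get(p);
  e->need_open("switch");
  SwitchT s;
  s.name = name;
  s.in_cls = e->cls_id(input);
  s.out_cls = e->cls_id(output);
  if (s.in_cls == s.out_cls) stop("switch '%s': input and output class must differ", name.c_str());
  e->reg_species(name, 3, static_cast<int>(e->sws.size()));
  e->sws.push_back(s);
}

// [[Rcpp::export]]
int eng_add_site(SEXP p, std::string family, std::string sequence, int first, int last,
                 double kon, double koff, int offset) {
  Engine* e = get(p);
  e->need_open("binding site");
  int sq = e->seq_id(sequence);
  int len = static_cast<int>(e->seqs[sq].letters.size());
  if (first < 0 || first >= last || last > len)
    stop("binding site [%d,%d) out of bounds for sequence '%s' of length %d",
         first, last, sequence.c_str(), len);
  if (kon < 0 || koff < 0) stop("binding rates must be non-negative");
  if (offset < 0 || offset > len) stop("reading offset out of bounds");
  int fid;
  auto it = e->famidx.find(family);
  if (it == e->famidx.end()) {
    fid = static_cast<int>(e->fams.size());
    e->famidx[family] = fid;
    Family F;
    F.name = family;
    e->fams.push_back(F);
  } else fid = it->second;
  Site s;
  s.fam = fid; s.seq = sq; s.first = first; s.last = last;
  s.kon = kon; s.koff = koff; s.offset = offset;
  int sid = static_cast<int>(e->sites.size());
  e->sites.push_back(s);
  e->fams[fid].sites.push_back(sid);
  return sid;
}

// [[Rcpp::export]]
void eng_add_switch_site(SEXP p, std::string sequence, int position, std::string sw) {
  Engine* e = get(p);
  e->need_open("switch site");
  int sq = e->seq_id(sequence);
  if (position < 0 || position >= static_cast<int>(e->seqs[sq].letters.size()))
    stop("switch site position %d out of bounds for '%s'", position, sequence.c_str());
  e->seqs[sq].switches[position].push_back(e->sw_id(sw));
}

// [[Rcpp::export]]
void eng_add_chem(SEXP p, std::string name,
                  std::vector<std::string> rnames, std::vector<double> rstoich,
                  std::vector<std::string> pnames, std::vector<double> pstoich,
                  double kf, double kb) {
  Engine* e = get(p);
  e->need_open("chemical reaction");
  if (kf < 0 || kb < 0) stop("rate constants must be non-negative");
  ChemRxn r;
  r.name = name; r.kf = kf; r.kb = kb;
  for (size_t i = 0; i < rnames.size(); ++i) {
    auto sp = e->find_species(rnames[i]);
    long long st = static_cast<long long>(rstoich[i]);
    if (st < 1) stop("reaction '%s': stoichiometry must be >= 1", name.c_str());
    if (sp.first == 0) r.rf.push_back({sp.second, st});
    else if (sp.first == 2) {
      if (r.rb >= 0) stop("reaction '%s': at most one bound reactant", name.c_str());
      if (st != 1) stop("reaction '%s': bound reactant stoichiometry must be 1", name.c_str());
      r.rb = sp.second;
    } else stop("reaction '%s': '%s' cannot be a reactant", name.c_str(), rnames[i].c_str());
  }
  for (size_t i = 0; i < pnames.size(); ++i) {
    auto sp = e->find_species(pnames[i]);
    long long st = static_cast<long long>(pstoich[i]);
    if (st < 1) stop("reaction '%s': stoichiometry must be >= 1", name.c_str());
    if (sp.first == 0) r.pf.push_back({sp.second, st});
    else if (sp.first == 2) {
      if (r.pb >= 0) stop("reaction '%s': at most one bound product", name.c_str());
      if (st != 1) stop("reaction '%s': bound product stoichiometry must be 1", name.c_str());
      r.pb = sp.second;
    } else stop("reaction '%s': '%s' cannot be a product", name.c_str(), pnames[i].c_str());
  }
  e->reg_rxn(name, 0, static_cast<int>(e->chems.size()));
  e->chems.push_back(r);
}

// [[Rcpp::export]]
void eng_add_binding(SEXP p, std::string name, std::string free_form,
                     std::string bound_form, std::string family) {
  Engine* e = get(p);
  e->need_open("sequence binding");
  BindRxn b;
  b.name = name;
  b.fc = e->free_id(free_form);
  b.bc = e->cls_id(bound_form);
  b.fam = e->fam_id(family);
  e->reg_rxn(name, 1, static_cast<int>(e->binds.size()));
  e->binds.push_back(b);
}

// [[Rcpp::export]]
void eng_add_transloc(SEXP p, std::string name, std::string mobile, std::string post,
                      int step, double rate) {
  Engine* e = get(p);
  e->need_open("translocation");
  if (step < 1) stop("translocation '%s': step must be >= 1", name.c_str());
  if (rate < 0) stop("translocation '%s': rate must be non-negative", name.c_str());
  TransRxn t;
  t.name = name;
  t.mob = e->cls_id(mobile);
  t.post = e->cls_id(post);
  t.step = step;
  t.rate = rate;
  e->reg_rxn(name, 2, static_cast<int>(e->transs.size()));
  e->transs.push_back(t);
}

// [[Rcpp::export]]
void eng_add_loading(SEXP p, std::string name, std::string loader,
                     std::vector<std::string> motifs, std::vector<std::string> loaded,
                     std::vector<double> rates, std::vector<std::string> posts,
                     List byproducts) {
  Engine* e = get(p);
  e->need_open("loading");
  if (motifs.empty()) stop("loading '%s': empty motif table", name.c_str());
  LoadRxn l;
  l.name = name;
  l.loader = e->cls_id(loader);
  l.len = static_cast<int>(motifs[0].size());
  for (size_t i = 0; i < motifs.size(); ++i) {
    if (static_cast<int>(motifs[i].size()) != l.len)
      stop("loading '%s': motifs of unequal length", name.c_str());
    if (rates[i] < 0) stop("loading '%s': rates must be non-negative", name.c_str());
    l.motif.push_back(motifs[i]);
    l.loaded.push_back(e->free_id(loaded[i]));
    l.rate.push_back(rates[i]);
    l.post.push_back(e->cls_id(posts[i]));
    std::vector<int> bp;
    std::vector<std::string> bnames = as<std::vector<std::string>>(byproducts[i]);
    for (auto& bn : bnames) bp.push_back(e->free_id(bn));
    l.byp.push_back(bp);
  }
  e->reg_rxn(name, 3, static_cast<int>(e->loads.size()));
  e->loads.push_back(l);
}

// [[Rcpp::export]]
void eng_add_release(SEXP p, std::string name, std::string cls, double rate,
                     std::vector<std::string> freed,
                     std::vector<std::string> fam, std::vector<int> first,
                     std::vector<int> last, std::vector<std::string> product,
                     bool warn_unmatched) {
  Engine* e = get(p);
  e->need_open("release");
  if (rate < 0) stop("release '%s': rate must be non-negative", name.c_str());
  RelRxn r;
  r.name = name;
  r.cls = e->cls_id(cls);
  r.rate = rate;
  r.warn_unmatched = warn_unmatched;
  for (auto& f : freed) r.freed.push_back(e->free_id(f));
  for (size_t i = 0; i < fam.size(); ++i) {
    if (first[i] >= last[i]) stop("release '%s': empty product interval", name.c_str());
    r.t_fam.push_back(e->fam_id(fam[i]));
    r.t_first.push_back(first[i]);
    r.t_last.push_back(last[i]);
    r.t_prod.push_back(e->seq_id(product[i]));
  }
  e->reg_rxn(name, 4, static_cast<int>(e->rels.size()));
  e->rels.push_back(r);
}

// [[Rcpp::export]]
void eng_add_event(SEXP p, double time, std::string kind, std::string target, double amount) {
  Engine* e = get(p);
  e->need_open("event");
  if (time < 0) stop("event times must be non-negative");
  TimedEv ev;
  ev.time = time;
  if (kind == "ADD") ev.kind = EV_ADD;
  else if (kind == "SET") ev.kind = EV_SET;
  else if (kind == "REMOVE_FREE") ev.kind = EV_REMOVE_FREE;
  else stop("unknown event kind '%s'", kind.c_str());
  ev.target = e->free_id(target);
  ev.amount = static_cast<long long>(amount);
  e->events.push_back(ev);
}

// [[Rcpp::export]]
void eng_finalize(SEXP p) { get(p)->finalize(); }

// [[Rcpp::export]]
void eng_seed(SEXP p, double seed) {
  get(p)->rng.reseed(static_cast<uint64_t>(seed));
}

// [[Rcpp::export]]
List eng_counts(SEXP p) {
  Engine* e = get(p);
  NumericVector fc(e->frees.size()), sc(e->seqs.size()), bc(e->classes.size());
  CharacterVector fn(e->frees.size()), sn(e->seqs.size()), bn(e->classes.size());
  for (size_t i = 0; i < e->frees.size(); ++i) {
    fc[i] = static_cast<double>(e->frees[i].count);
    fn[i] = e->frees[i].name;
  }
  for (size_t i = 0; i < e->seqs.size(); ++i) {
    sc[i] = static_cast<double>(e->seqs[i].copies);
    sn[i] = e->seqs[i].name;
  }
  for (size_t i = 0; i < e->classes.size(); ++i) {
    bc[i] = static_cast<double>(e->classes[i].members.size());
    bn[i] = e->classes[i].name;
  }
  fc.names() = fn; sc.names() = sn; bc.names() = bn;
  return List::create(_["free"] = fc, _["sequences"] = sc, _["bound"] = bc);
}

// [[Rcpp::export]]
double eng_count(SEXP p, std::string name) {
  Engine* e = get(p);
  auto sp = e->find_species(name);
  if (sp.first == 0) return static_cast<double>(e->frees[sp.second].count);
  if (sp.first == 1) return static_cast<double>(e->seqs[sp.second].copies);
  if (sp.first == 2) return static_cast<double>(e->classes[sp.second].members.size());
  stop("'%s' has no molecule count", name.c_str());
}

// [[Rcpp::export]]
void eng_set_count(SEXP p, std::string name, double value) {
  Engine* e = get(p);
  if (value < 0) stop("counts must be non-negative");
  auto sp = e->find_species(name);
  long long v = static_cast<long long>(value);
  if (sp.first == 0) {
    e->frees[sp.second].count = v;
    e->touch_free(sp.second);
  } else if (sp.first == 1) {
    Seqn& s = e->seqs[sp.second];
    for (auto& pr : s.famkon) {
      for (int sid : e->fams[pr.first].sites)
        if (e->sites[sid].seq == sp.second && e->sites[sid].occupied > v)
          stop("cannot set copies of '%s' below current site occupancy", name.c_str());
    }
    long long delta = v - s.copies;
    s.copies = v;
    for (auto& pr : s.famkon) {
      e->fams[pr.first].kon_avail += pr.second * static_cast<double>(delta);
      e->touch_fam(pr.first);
    }
  } else stop("cannot set the count of '%s'", name.c_str());
  e->refresh_touched();
}

// [[Rcpp::export]]
double eng_available(SEXP p, std::string family) {
  Engine* e = get(p);
  Family& F = e->fams[e->fam_id(family)];
  long long avail = 0;
  for (int sid : F.sites)
    avail += e->seqs[e->sites[sid].seq].copies - e->sites[sid].occupied;
  return static_cast<double>(avail);
}

// [[Rcpp::export]]
List eng_propensity(SEXP p, std::string name) {
  Engine* e = get(p);
  if (!e->finalized) stop("system not finalized");
  auto it = e->rxns.find(name);
  if (it == e->rxns.end()) stop("unknown reaction '%s'", name.c_str());
  int rt = it->second.first, id = it->second.second;
  switch (rt) {
    case 0: {
      Chan f{CH_CHEMF, id, 0}, b{CH_CHEMR, id, 0};
      return List::create(_["forward"] = e->prop(f),
                          _["backward"] = e->chems[id].kb > 0 ? e->prop(b) : 0.0);
    }
    case 1: {
      Chan f{CH_BINDF, id, 0}, b{CH_BINDR, id, 0};
      return List::create(_["forward"] = e->prop(f), _["reverse"] = e->prop(b));
    }
    case 2: {
      Chan c{CH_TRANS, id, 0};
      return List::create(_["rate"] = e->prop(c));
    }
    case 3: {
      LoadRxn& l = e->loads[id];
      NumericVector per(l.motif.size());
      CharacterVector nm(l.motif.size());
      double tot = 0.0;
      for (size_t m = 0; m < l.motif.size(); ++m) {
        Chan c{CH_LOAD, id, static_cast<int>(m)};
        per[m] = e->prop(c);
        nm[m] = l.motif[m];
        tot += per[m];
      }
      per.names() = nm;
      return List::create(_["total"] = tot, _["per_motif"] = per);
    }
    default: {
      Chan c{CH_REL, id, 0};
      return List::create(_["rate"] = e->prop(c));
    }
  }
}

// [[Rcpp::export]]
void eng_fire(SEXP p, std::string name, std::string direction, std::string motif) {
  Engine* e = get(p);
  if (!e->finalized) stop("system not finalized");
  auto it = e->rxns.find(name);
  if (it == e->rxns.end()) stop("unknown reaction '%s'", name.c_str());
  int rt = it->second.first, id = it->second.second;
  bool fwd = (direction != "reverse" && direction != "backward");
  Chan ch;
  switch (rt) {
    case 0: ch = {fwd ? CH_CHEMF : CH_CHEMR, id, 0}; break;
    case 1: ch = {fwd ? CH_BINDF : CH_BINDR, id, 0}; break;
    case 2: ch = {CH_TRANS, id, 0}; break;
    case 3: {
      LoadRxn& l = e->loads[id];
      int sub = -1;
      for (size_t m = 0; m < l.motif.size(); ++m)
        if (l.motif[m] == motif) { sub = static_cast<int>(m); break; }
      if (sub < 0) stop("loading '%s' has no motif '%s'", name.c_str(), motif.c_str());
      ch = {CH_LOAD, id, sub};
      break;
    }
    default: ch = {CH_REL, id, 0};
  }
  if (e->prop(ch) <= 0)
    stop("impossible reaction: '%s' has zero propensity", name.c_str());
  e->fire_channel(ch);
  e->refresh_touched();
}

// [[Rcpp::export]]
void eng_apply_event(SEXP p, std::string kind, std::string target, double amount) {
  Engine* e = get(p);
  int k;
  if (kind == "ADD") k = EV_ADD;
  else if (kind == "SET") k = EV_SET;
  else if (kind == "REMOVE_FREE") k = EV_REMOVE_FREE;
  else stop("unknown event kind '%s'", kind.c_str());
  e->apply_event_now(k, e->free_id(target), static_cast<long long>(amount));
  e->refresh_touched();
}

// [[Rcpp::export]]
DataFrame eng_members(SEXP p, std::string cls) {
  Engine* e = get(p);
  BClass& c = e->classes[e->cls_id(cls)];
  int n = static_cast<int>(c.members.size());
  CharacterVector sq(n), fam(n);
  IntegerVector pos(n);
  LogicalVector orig(n);
  for (int i = 0; i < n; ++i) {
    const Unit& u = e->units[c.members[i]];
    sq[i] = e->seqs[u.seq].name;
    pos[i] = u.pos;
    if (u.site >= 0) fam[i] = e->fams[e->sites[u.site].fam].name;
    else fam[i] = NA_STRING;
    orig[i] = u.on_origin;
  }
  return DataFrame::create(_["sequence"] = sq, _["position"] = pos,
                           _["origin_family"] = fam, _["on_origin_site"] = orig,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List eng_sample_member(SEXP p, std::string cls) {
  Engine* e = get(p);
  BClass& c = e->classes[e->cls_id(cls)];
  if (c.members.empty())
    stop("impossible reaction: bound chemical '%s' has no members", cls.c_str());
  int i = e->rng.below(static_cast<int>(c.members.size()));
  const Unit& u = e->units[c.members[i]];
  return List::create(
      _["index"] = i + 1, _["sequence"] = e->seqs[u.seq].name, _["position"] = u.pos,
      _["origin_family"] = u.site >= 0
          ? CharacterVector::create(e->fams[e->sites[u.site].fam].name)
          : CharacterVector::create(NA_STRING),
      _["on_origin_site"] = u.on_origin);
}

// [[Rcpp::export]]
void eng_reassign(SEXP p, std::string from, std::string to, int index) {
  Engine* e = get(p);
  BClass& c = e->classes[e->cls_id(from)];
  int cto = e->cls_id(to);
  if (c.members.empty()) stop("bound chemical '%s' has no members", from.c_str());
  int i;
  if (index == 0) i = e->rng.below(static_cast<int>(c.members.size()));
  else if (index >= 1 && index <= static_cast<int>(c.members.size())) i = index - 1;
  else stop("member index %d out of range for '%s'", index, from.c_str());
  int uid = c.members[i];
  e->remove_from_class(uid);
  e->add_to_class(uid, cto);
  e->touch_cls(e->cls_id(from));
  e->touch_cls(cto);
  e->refresh_touched();
}

// [[Rcpp::export]]
List eng_stats(SEXP p) {
  Engine* e = get(p);
  return List::create(_["created"] = static_cast<double>(e->created),
                      _["destroyed"] = static_cast<double>(e->destroyed),
                      _["live"] = static_cast<double>(e->live),
                      _["n_channels"] = static_cast<int>(e->chans.size()),
                      _["n_reactions"] = static_cast<int>(
                          e->chems.size() + e->binds.size() + e->transs.size() +
                          e->loads.size() + e->rels.size()));
}

// [[Rcpp::export]]
bool eng_check(SEXP p) {
  Engine* e = get(p);
  e->check_scratch(e->store_built);
  return true;
}

// [[Rcpp::export]]
int eng_species_kind(SEXP p, std::string name) {
  return get(p)->find_species(name).first;
}

// Main SSA loop.  Events interleave exactly: when t + tau crosses the next
// event time we advance to the event, apply it, discard tau and redraw
// (valid by memorylessness of the exponential clock).
// [[Rcpp::export]]
List eng_run(SEXP p, double t_end, double seed, std::string solver, double log_period,
             std::vector<std::string> observables, double max_events, double check_every) {
  Engine* e = get(p);
  if (!e->finalized) stop("system not finalized");
  if (t_end <= 0) stop("t_end must be positive");
  if (log_period <= 0) stop("log_period must be positive");
  int strat = Store::DIRECT;
  if (solver == "tree") strat = Store::TREE;
  else if (solver == "cr") strat = Store::CR;
  else if (solver != "direct") stop("unknown solver '%s'", solver.c_str());

  // resolve observables
  int nobs = static_cast<int>(observables.size());
  std::vector<int> okind(nobs), oid(nobs);
  for (int i = 0; i < nobs; ++i) {
    auto sp = e->find_species(observables[i]);
    if (sp.first > 2) stop("cannot observe '%s'", observables[i].c_str());
    okind[i] = sp.first;
    oid[i] = sp.second;
  }

  e->rng.reseed(static_cast<uint64_t>(seed));
  e->t_free.clear(); e->t_cls.clear(); e->t_fam.clear();
  e->build_store(strat);

  std::vector<double> times;
  std::vector<std::vector<double>> series(nobs);
  auto record = [&](double t) {
    times.push_back(t);
    for (int i = 0; i < nobs; ++i) {
      double v = 0;
      if (okind[i] == 0) v = static_cast<double>(e->frees[oid[i]].count);
      else if (okind[i] == 1) v = static_cast<double>(e->seqs[oid[i]].copies);
      else v = static_cast<double>(e->classes[oid[i]].members.size());
      series[i].push_back(v);
    }
  };

  double t = 0.0;
  double next_log = log_period;
  record(0.0);
  auto log_until = [&](double tq) {
    while (next_log < tq && next_log <= t_end) {
      record(next_log);
      next_log += log_period;
    }
  };

  size_t evi = 0;
  long long nfire = 0;
  long long maxev = max_events > 0 ? static_cast<long long>(max_events) : -1;
  long long checkev = check_every > 0 ? static_cast<long long>(check_every) : -1;
  const double INF = std::numeric_limits<double>::infinity();
  int stop_mode = 0;  // 0: reached t_end; 1: system quiet; 2: max_events

  for (;;) {
    if (maxev >= 0 && nfire >= maxev) { stop_mode = 2; break; }
    double t_event = evi < e->events.size() ? e->events[evi].time : INF;
    if (e->store.npos == 0) {
      if (t_event <= t_end) {
        log_until(t_event);
        t = t_event;
        while (evi < e->events.size() && e->events[evi].time <= t) {
          e->apply_event_now(e->events[evi].kind, e->events[evi].target,
                             e->events[evi].amount);
          ++evi;
        }
        e->refresh_touched();
        continue;
      }
      stop_mode = 1;
      break;
    }
    double tau = -std::log(e->rng.unif_pos()) / e->store.tot;
    double tnext = t + tau;
    if (t_event <= t_end && tnext >= t_event) {
      log_until(t_event);
      t = t_event;
      while (evi < e->events.size() && e->events[evi].time <= t) {
        e->apply_event_now(e->events[evi].kind, e->events[evi].target,
                           e->events[evi].amount);
        ++evi;
      }
      e->refresh_touched();
      continue;
    }
    if (tnext > t_end) break;
    int ch = e->store.select(e->rng);
    if (ch < 0) continue;  // drift left a stale total; npos refresh next loop
    log_until(tnext);
    t = tnext;
    e->fire_channel(e->chans[ch]);
    ++nfire;
    e->refresh_touched();
    if (checkev > 0 && nfire % checkev == 0) e->check_scratch(true);
    if (nfire % 1048576 == 0) Rcpp::checkUserInterrupt();
  }

  // Close the trajectory.  While the system stays active, periodic rows run
  // to t_end; once it goes quiet the state is constant, so a single final
  // row at t_end stands in for the remaining periods; a max_events stop
  // closes at the time actually reached.
  double t_final = t;
  if (stop_mode == 0) {
    log_until(t_end + 1e-12);
    if (times.empty() || times.back() < t_end) record(t_end);
  } else {
    double t_close = stop_mode == 1 ? t_end : std::min(t, t_end);
    if (times.empty() || times.back() < t_close) record(t_close);
  }

  NumericVector tv(times.begin(), times.end());
  NumericMatrix m(static_cast<int>(times.size()), nobs);
  for (int j = 0; j < nobs; ++j)
    for (size_t i = 0; i < times.size(); ++i)
      m(static_cast<int>(i), j) = series[j][i];
  colnames(m) = wrap(observables);
  return List::create(_["time"] = tv, _["counts"] = m,
                      _["event_count"] = static_cast<double>(nfire),
                      _["t_final"] = t_final);
}

// ---------------------------------------------------------------------------
// Standalone selection helpers (share the Store implementation with the run
// loop so tests exercise the same code paths).

// [[Rcpp::export]]
int cpp_select_direct(std::vector<double> entries, double u) {
  Store s;
  s.build(Store::DIRECT, entries);
  if (s.npos == 0) return NA_INTEGER;
  return s.select_direct(u) + 1;
}

// [[Rcpp::export]]
int cpp_select_tree(std::vector<double> entries, double u) {
  Store s;
  s.build(Store::TREE, entries);
  if (s.npos == 0) return NA_INTEGER;
  return s.select_tree(u) + 1;
}

// [[Rcpp::export]]
IntegerVector cpp_sample_selections(std::vector<double> entries, double n, double seed,
                                    std::string strategy) {
  int strat = Store::DIRECT;
  if (strategy == "tree") strat = Store::TREE;
  else if (strategy == "cr") strat = Store::CR;
  else if (strategy != "direct") stop("unknown strategy '%s'", strategy.c_str());
  Store s;
  s.build(strat, entries);
  Rng rng;
  rng.reseed(static_cast<uint64_t>(seed));
  long long N = static_cast<long long>(n);
  IntegerVector out(N);
  for (long long i = 0; i < N; ++i) {
    int ch = s.select(rng);
    out[i] = ch < 0 ? NA_INTEGER : ch + 1;
  }
  return out;
}

// [[Rcpp::export]]
int cpp_cr_exponent(double a) {
  if (a <= 0) stop("propensity must be positive");
  return std::ilogb(a);
}
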