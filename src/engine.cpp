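// MCMC engine over ancestral recombination graphs.
//
// State layout: nodes live in slots (alive flag); tips occupy slots
// 0..ntips-1 and never move.  Kinds: 0 tip, 1 coalescent, 2 recombination.
// A recombination node carries a breakpoint b in [1, L-1]: sites < b route
// to parent slot 0, sites >= b to parent slot 1 (0-based sites, half-open
// intervals).  Heights are in expected substitutions per site.
//
// The data likelihood is cached per marginal-tree interval; a proposal
// reports the site ranges it can affect and only intervals intersecting
// those ranges (or whose boundaries changed) are recomputed.
//
// All randomness comes from R's RNG (unif_rand/exp_rand), so a fixed
// R-side seed makes runs bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------- intervals

struct Iv { int s, e; };
typedef std::vector<Iv> IvSet;

static IvSet iv_norm(IvSet v) {
  IvSet out;
  v.erase(std::remove_if(v.begin(), v.end(), [](const Iv& i) { return i.s >= i.e; }), v.end());
  if (v.empty()) return out;
  std::sort(v.begin(), v.end(), [](const Iv& a, const Iv& b) { return a.s < b.s; });
  out.push_back(v[0]);
  for (size_t i = 1; i < v.size(); ++i) {
    if (v[i].s <= out.back().e) {
      out.back().e = std::max(out.back().e, v[i].e);
    } else {
      out.push_back(v[i]);
    }
  }
  return out;
}

static IvSet iv_union(const IvSet& a, const IvSet& b) {
  IvSet v(a);
  v.insert(v.end(), b.begin(), b.end());
  return iv_norm(v);
}

static IvSet iv_left(const IvSet& m, int b) {
  IvSet out;
  for (const Iv& i : m) if (i.s < b) out.push_back({i.s, std::min(i.e, b)});
  return out;
}

static IvSet iv_right(const IvSet& m, int b) {
  IvSet out;
  for (const Iv& i : m) if (i.e > b) out.push_back({std::max(i.s, b), i.e});
  return out;
}

static bool iv_overlaps_range(const IvSet& m, int s, int e) {
  for (const Iv& i : m) if (i.s < e && s < i.e) return true;
  return false;
}

static int iv_min(const IvSet& m) { return m.empty() ? -1 : m.front().s; }
static int iv_max(const IvSet& m) { return m.empty() ? -1 : m.back().e - 1; }
static int iv_span(const IvSet& m) { return m.empty() ? 0 : iv_max(m) - iv_min(m); }

// ---------------------------------------------------------------- model

// order A C G T; purines at 0, 2
struct Model {
  double pi[4];
  bool f84;
  double kappa;     // F84 transition-excess parameter
  double aRraw, aYraw; // TN93 rates (relative to transversion 1)
  double aR, aY, bb; // normalized rates

  void derive() {
    double piR = pi[0] + pi[2], piY = pi[1] + pi[3];
    double AR = f84 ? 1.0 + kappa / piR : aRraw;
    double AY = f84 ? 1.0 + kappa / piY : aYraw;
    double mu = 2 * pi[0] * pi[2] * AR + 2 * pi[1] * pi[3] * AY + 2 * piR * piY;
    aR = AR / mu; aY = AY / mu; bb = 1.0 / mu;
  }

  // row-major P[from*4 + to]
  void pmat(double t, double* P) const {
    double piR = pi[0] + pi[2], piY = pi[1] + pi[3];
    double e2 = std::exp(-bb * t);
    double e3 = std::exp(-(piR * aR + piY * bb) * t);
    double e4 = std::exp(-(piY * aY + piR * bb) * t);
    double A = pi[0], C = pi[1], G = pi[2], T = pi[3];
    P[0 * 4 + 0] = A + A * piY / piR * e2 + G / piR * e3;
    P[0 * 4 + 2] = G + G * piY / piR * e2 - G / piR * e3;
    P[2 * 4 + 2] = G + G * piY / piR * e2 + A / piR * e3;
    P[2 * 4 + 0] = A + A * piY / piR * e2 - A / piR * e3;
    P[0 * 4 + 1] = P[2 * 4 + 1] = C * (1 - e2);
    P[0 * 4 + 3] = P[2 * 4 + 3] = T * (1 - e2);
    P[1 * 4 + 1] = C + C * piR / piY * e2 + T / piY * e4;
    P[1 * 4 + 3] = T + T * piR / piY * e2 - T / piY * e4;
    P[3 * 4 + 3] = T + T * piR / piY * e2 + C / piY * e4;
    P[3 * 4 + 1] = C + C * piR / piY * e2 - C / piY * e4;
    P[1 * 4 + 0] = P[3 * 4 + 0] = A * (1 - e2);
    P[1 * 4 + 2] = P[3 * 4 + 2] = G * (1 - e2);
  }
};

// ---------------------------------------------------------------- priors

struct Priors {
  bool th_sampled, rho_sampled, sub_sampled;
  double th_lo, th_hi, rho_lo, rho_hi, kap_lo, kap_hi;
};

// ---------------------------------------------------------------- state

struct Node {
  double h;
  int kind;    // 0 tip 1 coal 2 recomb
  int ch[2];   // -1 none
  int pa[2];
  int bp;      // -1 none
  bool alive;
};

struct State {
  std::vector<Node> nd;
  std::vector<IvSet> mat;   // child-side ancestral material per node
  int ntips, L;
  double theta, rho, growth;
  Model mod;
  // likelihood cache over the marginal-interval partition
  std::vector<int> ivStart;
  std::vector<double> ivLL;
  double ll, lp;

  int root() const {
    for (size_t i = 0; i < nd.size(); ++i) {
      if (nd[i].alive && nd[i].pa[0] < 0 && nd[i].pa[1] < 0) return (int)i;
    }
    return -1;
  }
};

static int alloc_node(State& S) {
  for (size_t i = S.ntips; i < S.nd.size(); ++i) {
    if (!S.nd[i].alive) {
      S.nd[i] = Node{0.0, 1, {-1, -1}, {-1, -1}, -1, true};
      S.mat[i].clear();
      return (int)i;
    }
  }
  S.nd.push_back(Node{0.0, 1, {-1, -1}, {-1, -1}, -1, true});
  S.mat.push_back(IvSet());
  return (int)S.nd.size() - 1;
}

static void kill_node(State& S, int id) {
  S.nd[id].alive = false;
  S.nd[id].ch[0] = S.nd[id].ch[1] = S.nd[id].pa[0] = S.nd[id].pa[1] = -1;
  S.mat[id].clear();
}

// material on the edge from `u` through its parent slot `slot`
static IvSet edge_material(const State& S, int u, int slot) {
  if (S.nd[u].kind == 2) {
    return slot == 0 ? iv_left(S.mat[u], S.nd[u].bp) : iv_right(S.mat[u], S.nd[u].bp);
  }
  return S.mat[u];
}

// child slot of `parent` that corresponds to the edge from `child` through
// the child's parent slot `cslot` (disambiguates parallel edges)
static int child_slot_of(const State& S, int parent, int child, int cslot) {
  const Node& P = S.nd[parent];
  if (P.ch[0] == child && P.ch[1] == child) return cslot;
  if (P.ch[0] == child) return 0;
  if (P.ch[1] == child) return 1;
  return -1;
}

// parent slot of `child` pointing at `parent` (unique in valid states)
static int pa_slot_of(const State& S, int child, int parent) {
  if (S.nd[child].pa[0] == parent) return 0;
  if (S.nd[child].pa[1] == parent) return 1;
  return -1;
}

typedef std::pair<int, int> Edge; // (node, parent slot)

static void edges_list(const State& S, std::vector<Edge>& out) {
  out.clear();
  for (size_t i = 0; i < S.nd.size(); ++i) {
    if (!S.nd[i].alive) continue;
    int nslots = (S.nd[i].kind == 2) ? 2 : 1;
    for (int s = 0; s < nslots; ++s) {
      if (S.nd[i].pa[s] >= 0) out.push_back({(int)i, s});
    }
  }
}

// ordered alive node ids by (height, id); tips first automatically
static void height_order(const State& S, std::vector<int>& ord) {
  ord.clear();
  for (size_t i = 0; i < S.nd.size(); ++i) if (S.nd[i].alive) ord.push_back((int)i);
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (S.nd[a].h != S.nd[b].h) return S.nd[a].h < S.nd[b].h;
    return a < b;
  });
}

static void annotate(State& S) {
  std::vector<int> ord;
  height_order(S, ord);
  for (int id : ord) {
    const Node& N = S.nd[id];
    if (N.kind == 0) {
      S.mat[id] = IvSet{{0, S.L}};
    } else if (N.kind == 2) {
      // material arriving on the single child-side edge (split if the
      // child is itself a recombination node)
      int u = N.ch[0];
      S.mat[id] = edge_material(S, u, pa_slot_of(S, u, id));
    } else {
      IvSet m;
      int c0 = N.ch[0], c1 = N.ch[1];
      // iterate each child's slots pointing here (covers both-children-equal)
      std::vector<int> uniq;
      uniq.push_back(c0);
      if (c1 != c0) uniq.push_back(c1);
      for (int u : uniq) {
        int nslots = (S.nd[u].kind == 2) ? 2 : 1;
        for (int s = 0; s < nslots; ++s) {
          if (S.nd[u].pa[s] == id) m = iv_union(m, edge_material(S, u, s));
        }
      }
      S.mat[id] = m;
    }
  }
}

// ---------------------------------------------------------------- prior

// log theta(t) = log theta0 - g t
static double log_prior_arg(const State& S) {
  std::vector<int> ord;
  height_order(S, ord);
  double lp = 0.0, t0 = 0.0;
  int k = S.ntips;
  double spanSum = (double)S.ntips * (S.L - 1);
  double recConst = (S.L > 1) ? (S.rho / S.theta) / (S.L - 1) : 0.0;
  double g = S.growth;
  for (int id : ord) {
    const Node& N = S.nd[id];
    if (N.kind == 0) continue;
    // the process stops at the grand MRCA: any event after the lineage
    // count first reaches 1 lies outside the state space
    if (k <= 1) return NEG_INF;
    double t1 = N.h, dt = t1 - t0;
    double coalInt = (g == 0.0)
      ? (double)k * (k - 1) / S.theta * dt
      : (double)k * (k - 1) / (S.theta * g) * (std::exp(g * t1) - std::exp(g * t0));
    lp -= coalInt + recConst * spanSum * dt;
    if (N.kind == 1) {
      lp += std::log(2.0) - (std::log(S.theta) - g * t1);
      // remove entering edges, add own edge
      std::vector<int> uniq;
      uniq.push_back(N.ch[0]);
      if (N.ch[1] != N.ch[0]) uniq.push_back(N.ch[1]);
      for (int u : uniq) {
        int nslots = (S.nd[u].kind == 2) ? 2 : 1;
        for (int s = 0; s < nslots; ++s) {
          if (S.nd[u].pa[s] == id) spanSum -= iv_span(edge_material(S, u, s));
        }
      }
      if (N.pa[0] >= 0) spanSum += iv_span(S.mat[id]);
      k -= 1;
    } else {
      const IvSet& m = S.mat[id];
      int mn = iv_min(m), mx = iv_max(m);
      if (!(mn >= 0 && mn < N.bp && N.bp <= mx)) return NEG_INF;
      if (recConst <= 0.0) return NEG_INF;
      lp += std::log(recConst);
      spanSum -= iv_span(m);
      spanSum += iv_span(iv_left(m, N.bp)) + iv_span(iv_right(m, N.bp));
      k += 1;
    }
    t0 = t1;
  }
  return lp;
}

static double log_prior_params(const State& S, const Priors& pr) {
  double lp = 0.0;
  if (pr.th_sampled) {
    if (S.theta < pr.th_lo || S.theta > pr.th_hi) return NEG_INF;
    lp += -std::log(S.theta) - std::log(std::log(pr.th_hi / pr.th_lo));
  }
  if (pr.rho_sampled) {
    if (S.rho < pr.rho_lo || S.rho > pr.rho_hi) return NEG_INF;
    lp += -std::log(S.rho) - std::log(std::log(pr.rho_hi / pr.rho_lo));
  }
  if (pr.sub_sampled) {
    if (S.mod.f84) {
      if (S.mod.kappa < pr.kap_lo || S.mod.kappa > pr.kap_hi) return NEG_INF;
      lp += -std::log(pr.kap_hi - pr.kap_lo);
    } else {
      for (double a : {S.mod.aRraw, S.mod.aYraw}) {
        if (a < pr.kap_lo || a > pr.kap_hi) return NEG_INF;
        lp += -std::log(a) - std::log(std::log(pr.kap_hi / pr.kap_lo));
      }
    }
  }
  return lp;
}

static double log_prior_total(const State& S, const Priors& pr) {
  double a = log_prior_params(S, pr);
  if (a == NEG_INF) return NEG_INF;
  double b = log_prior_arg(S);
  if (b == NEG_INF) return NEG_INF;
  return a + b;
}

// ---------------------------------------------------------------- alignment

struct Align {
  int n, L, P;
  std::vector<int> sitePat;  // per site, 0-based pattern id
  std::vector<int> pat;      // pat[p * n + row], codes 0..3, 4 missing
  double invCounts[4];       // invariant-column correction counts
  bool hasInv;
};

// ---------------------------------------------------------------- likelihood

struct Workspace {
  std::vector<char> active;
  std::vector<int> childCount;
  // suppressed marginal tree
  std::vector<int> keep;       // ARG ids, height order (tips first)
  std::vector<int> tpar;       // index into keep, -1 for root
  std::vector<double> pmats;   // 16 per keep node (edge to its tree parent)
  std::vector<int> kidx;       // ARG id -> keep index
  std::vector<double> acc;     // partial likelihoods, 4 per keep node
  std::vector<double> slog;    // per-node log scaling factors
  std::vector<int> patCount;   // per pattern scratch
  std::vector<int> patList;
};

static int route_parent(const State& S, int id, int site) {
  const Node& N = S.nd[id];
  if (N.kind == 2) return site < N.bp ? N.pa[0] : N.pa[1];
  return N.pa[0];
}

// build the unary-suppressed marginal tree at `site`
static void marginal_tree(const State& S, int site, Workspace& W) {
  size_t n = S.nd.size();
  W.active.assign(n, 0);
  W.childCount.assign(n, 0);
  for (int tip = 0; tip < S.ntips; ++tip) {
    int id = tip;
    W.active[id] = 1;
    for (;;) {
      int p = route_parent(S, id, site);
      if (p < 0) break;
      W.childCount[p]++;
      if (W.active[p]) break;
      W.active[p] = 1;
      id = p;
    }
  }
  W.keep.clear();
  for (int tip = 0; tip < S.ntips; ++tip) W.keep.push_back(tip);
  std::vector<int> internals;
  for (size_t i = S.ntips; i < n; ++i) {
    if (W.active[i] && W.childCount[i] == 2) internals.push_back((int)i);
  }
  std::sort(internals.begin(), internals.end(), [&](int a, int b) {
    if (S.nd[a].h != S.nd[b].h) return S.nd[a].h < S.nd[b].h;
    return a < b;
  });
  for (int id : internals) W.keep.push_back(id);
  W.kidx.assign(n, -1);
  for (size_t i = 0; i < W.keep.size(); ++i) W.kidx[W.keep[i]] = (int)i;
  W.tpar.assign(W.keep.size(), -1);
  W.pmats.resize(16 * W.keep.size());
  for (size_t i = 0; i < W.keep.size(); ++i) {
    int id = W.keep[i];
    int p = route_parent(S, id, site);
    while (p >= 0 && W.kidx[p] < 0) p = route_parent(S, p, site);
    if (p >= 0) {
      W.tpar[i] = W.kidx[p];
      double bl = S.nd[p].h - S.nd[id].h;
      S.mod.pmat(bl, &W.pmats[16 * i]);
    }
  }
}

// log-likelihood of one site pattern on the current W tree.
// keep is height-ordered, so children are always visited before parents;
// each node's P(t)-transformed partial is multiplied into its tree parent.
static double pattern_loglik(const State& S, const int* col, Workspace& W) {
  size_t m = W.keep.size();
  W.acc.assign(4 * m, 1.0);
  W.slog.assign(m, 0.0);
  for (int i = 0; i < S.ntips; ++i) {
    double* v = &W.acc[4 * i];
    int code = col[i];
    if (code < 4) { v[0] = v[1] = v[2] = v[3] = 0.0; v[code] = 1.0; }
  }
  for (size_t i = 0; i < m; ++i) {
    const double* src = &W.acc[4 * i];
    int pidx = W.tpar[i];
    if (pidx < 0) { // root of the marginal tree
      double tot = 0.0;
      for (int x = 0; x < 4; ++x) tot += S.mod.pi[x] * src[x];
      if (!(tot > 0.0)) return NEG_INF;
      return std::log(tot) + W.slog[i];
    }
    const double* P = &W.pmats[16 * i];
    double* pv = &W.acc[4 * pidx];
    double mx = 0.0;
    for (int x = 0; x < 4; ++x) {
      double s = P[4 * x] * src[0] + P[4 * x + 1] * src[1] +
                 P[4 * x + 2] * src[2] + P[4 * x + 3] * src[3];
      pv[x] *= s;
      if (pv[x] > mx) mx = pv[x];
    }
    W.slog[pidx] += W.slog[i];
    if (mx > 0.0 && mx < 1e-240) {
      for (int x = 0; x < 4; ++x) pv[x] /= mx;
      W.slog[pidx] += std::log(mx);
    }
  }
  return NEG_INF; // unreachable in valid trees
}

static double interval_loglik(const State& S, const Align& A, int a, int b, Workspace& W) {
  marginal_tree(S, a, W);
  // distinct patterns in [a, b)
  if ((int)W.patCount.size() < A.P) W.patCount.assign(A.P, 0);
  W.patList.clear();
  for (int s = a; s < b; ++s) {
    int p = A.sitePat[s];
    if (W.patCount[p] == 0) W.patList.push_back(p);
    W.patCount[p]++;
  }
  double out = 0.0;
  for (int p : W.patList) {
    double l = pattern_loglik(S, &A.pat[(size_t)p * A.n], W);
    out += W.patCount[p] * l;
    W.patCount[p] = 0;
  }
  if (A.hasInv) {
    double w = (double)(b - a) / (double)A.L;
    for (int base = 0; base < 4; ++base) {
      if (A.invCounts[base] <= 0) continue;
      std::vector<int> cc(S.ntips, base);
      out += A.invCounts[base] * w * pattern_loglik(S, cc.data(), W);
    }
  }
  return out;
}

// rebuild the interval cache; reuse entries whose boundaries are unchanged
// and which do not intersect the dirty ranges
static void refresh_likelihood(State& S, const Align& A, const IvSet& dirty,
                               bool forceAll, Workspace& W) {
  std::vector<int> starts;
  starts.push_back(0);
  for (size_t i = 0; i < S.nd.size(); ++i) {
    if (S.nd[i].alive && S.nd[i].kind == 2) starts.push_back(S.nd[i].bp);
  }
  std::sort(starts.begin(), starts.end());
  starts.erase(std::unique(starts.begin(), starts.end()), starts.end());
  std::vector<double> newLL(starts.size());
  size_t oi = 0;
  double tot = 0.0;
  for (size_t i = 0; i < starts.size(); ++i) {
    int a = starts[i];
    int b = (i + 1 < starts.size()) ? starts[i + 1] : S.L;
    bool reuse = false;
    double val = 0.0;
    if (!forceAll && !iv_overlaps_range(dirty, a, b)) {
      while (oi < S.ivStart.size() && S.ivStart[oi] < a) ++oi;
      if (oi < S.ivStart.size() && S.ivStart[oi] == a) {
        int oldb = (oi + 1 < S.ivStart.size()) ? S.ivStart[oi + 1] : S.L;
        if (oldb == b) { reuse = true; val = S.ivLL[oi]; }
      }
    }
    if (!reuse) val = interval_loglik(S, A, a, b, W);
    newLL[i] = val;
    tot += val;
  }
  S.ivStart = starts;
  S.ivLL = newLL;
  S.ll = tot;
}

static double loglik_scratch(const State& S, const Align& A, Workspace& W) {
  std::vector<int> starts;
  starts.push_back(0);
  for (size_t i = 0; i < S.nd.size(); ++i) {
    if (S.nd[i].alive && S.nd[i].kind == 2) starts.push_back(S.nd[i].bp);
  }
  std::sort(starts.begin(), starts.end());
  starts.erase(std::unique(starts.begin(), starts.end()), starts.end());
  double tot = 0.0;
  for (size_t i = 0; i < starts.size(); ++i) {
    int a = starts[i];
    int b = (i + 1 < starts.size()) ? starts[i + 1] : S.L;
    tot += interval_loglik(S, A, a, b, W);
  }
  return tot;
}

// ---------------------------------------------------------------- tuning

struct Tuning {
  double win_height;   // node-height window
  double f_root;       // root-scale log window
  double f_arg;        // arg-scale log window
  double f_scalar;     // scalar multiplier log window
  double geom_p;       // breakpoint-shift geometric parameter
};

// ---------------------------------------------------------------- kernels

enum Kernel {
  K_HEIGHT = 0, K_ROOT_SCALE, K_REGRAFT, K_BIRTH, K_DEATH, K_BPSHIFT,
  K_ARG_SCALE, K_THETA, K_RHO, K_SUB1, K_SUB2, K_COUNT
};

struct Proposal {
  double logHR;
  IvSet dirty;
  bool structural;  // material must be re-annotated
  bool fullDirty;   // recompute entire likelihood
};

// fold h into (lo, hi) by reflection; hi may be +inf
static double reflect(double h, double lo, double hi) {
  if (!std::isfinite(hi)) {
    if (h < lo) h = 2 * lo - h;
    return h;
  }
  double Wd = hi - lo;
  if (Wd <= 0) return lo;
  double span2 = 2 * Wd;
  double y = h - lo;
  y -= std::floor(y / span2) * span2; // y in [0, 2W)
  return lo + (y <= Wd ? y : span2 - y);
}

static bool kern_height(State& S, const Tuning& tu, Proposal& pr) {
  std::vector<int> internals;
  for (size_t i = 0; i < S.nd.size(); ++i) {
    if (S.nd[i].alive && S.nd[i].kind != 0) internals.push_back((int)i);
  }
  if (internals.empty()) return false;
  int v = internals[(int)(unif_rand() * internals.size())];
  Node& N = S.nd[v];
  double lo = 0.0, hi = std::numeric_limits<double>::infinity();
  for (int s = 0; s < 2; ++s) {
    if (N.ch[s] >= 0) lo = std::max(lo, S.nd[N.ch[s]].h);
    if (N.pa[s] >= 0) hi = std::min(hi, S.nd[N.pa[s]].h);
  }
  double h2 = reflect(N.h + (unif_rand() * 2 - 1) * tu.win_height, lo, hi);
  N.h = h2;
  pr.logHR = 0.0;
  pr.structural = false;
  pr.fullDirty = false;
  if (N.kind == 1) {
    // dirty where the node is binary in the marginal tree
    IvSet m0 = edge_material(S, N.ch[0], pa_slot_of(S, N.ch[0], v));
    if (N.ch[0] == N.ch[1]) {
      // both child slots from one recombination node: always unary
      pr.dirty.clear();
    } else {
      IvSet m1 = edge_material(S, N.ch[1], pa_slot_of(S, N.ch[1], v));
      IvSet inter;
      for (const Iv& i : m0) {
        for (const Iv& j : m1) {
          int s = std::max(i.s, j.s), e = std::min(i.e, j.e);
          if (s < e) inter.push_back({s, e});
        }
      }
      pr.dirty = iv_norm(inter);
    }
  } else {
    pr.dirty.clear(); // recombination nodes are unary in every marginal tree
  }
  return true;
}

static IvSet binary_sites(const State& S, int v) {
  const Node& N = S.nd[v];
  if (N.kind != 1 || N.ch[0] == N.ch[1]) return IvSet();
  IvSet m0 = edge_material(S, N.ch[0], pa_slot_of(S, N.ch[0], v));
  IvSet m1 = edge_material(S, N.ch[1], pa_slot_of(S, N.ch[1], v));
  IvSet inter;
  for (const Iv& i : m0) {
    for (const Iv& j : m1) {
      int s = std::max(i.s, j.s), e = std::min(i.e, j.e);
      if (s < e) inter.push_back({s, e});
    }
  }
  return iv_norm(inter);
}

static bool kern_root_scale(State& S, const Tuning& tu, Proposal& pr) {
  int r = S.root();
  Node& N = S.nd[r];
  double m = std::exp(tu.f_root * (unif_rand() - 0.5));
  double h2 = N.h * m;
  double lo = 0.0;
  for (int s = 0; s < 2; ++s) if (N.ch[s] >= 0) lo = std::max(lo, S.nd[N.ch[s]].h);
  if (h2 <= lo) return false;
  pr.dirty = binary_sites(S, r);
  N.h = h2;
  pr.logHR = std::log(m);
  pr.structural = false;
  pr.fullDirty = false;
  return true;
}

static bool kern_arg_scale(State& S, const Tuning& tu, Proposal& pr) {
  double m = std::exp(tu.f_arg * (unif_rand() - 0.5));
  int d = 0;
  for (size_t i = 0; i < S.nd.size(); ++i) {
    if (S.nd[i].alive && S.nd[i].kind != 0) { S.nd[i].h *= m; ++d; }
  }
  pr.logHR = d * std::log(m);
  pr.structural = false;
  pr.fullDirty = true;
  return true;
}

static bool kern_birth(State& S, const Tuning& tu, Proposal& pr) {
  std::vector<Edge> E;
  edges_list(S, E);
  if (E.empty()) return false;
  Edge e = E[(int)(unif_rand() * E.size())];
  int u = e.first, su = e.second;
  int p = S.nd[u].pa[su];
  IvSet me = edge_material(S, u, su);
  int span = iv_span(me);
  if (span <= 0) return false;
  int mn = iv_min(me);
  int b = mn + 1 + (int)(unif_rand() * span);
  if (b > mn + span) b = mn + span;
  int bit = unif_rand() < 0.5 ? 0 : 1;
  double hu = S.nd[u].h, hp = S.nd[p].h;
  double hr = hu + unif_rand() * (hp - hu);
  double lambda = S.theta;
  double hc = hr + exp_rand() * lambda;
  int rootId = S.root();
  double rootH = S.nd[rootId].h;
  // target edges crossing hc
  std::vector<Edge> T;
  bool aboveRoot = hc > rootH;
  if (!aboveRoot) {
    for (const Edge& t : E) {
      double hx = S.nd[t.first].h, hy = S.nd[S.nd[t.first].pa[t.second]].h;
      if (hx < hc && hc < hy) T.push_back(t);
    }
    if (T.empty()) return false;
  }
  int k = aboveRoot ? 1 : (int)T.size();
  int choice = aboveRoot ? -1 : (int)(unif_rand() * k);
  bool trivial = (!aboveRoot && T[choice].first == u && T[choice].second == su);
  double lqb = -std::log((double)E.size()) - std::log((double)span)
    - std::log(hp - hu) - std::log(lambda) - (hc - hr) / lambda
    - std::log((double)k);
  if (!trivial) lqb += std::log(0.5);

  int r = alloc_node(S);
  int c = alloc_node(S);
  S.nd[r] = Node{hr, 2, {u, -1}, {-1, -1}, b, true};
  S.nd[c] = Node{hc, 1, {-1, -1}, {-1, -1}, -1, true};
  int pcs = child_slot_of(S, p, u, su);
  S.nd[u].pa[su] = r;
  if (trivial) {
    S.nd[r].pa[0] = c;
    S.nd[r].pa[1] = c;
    S.nd[c].ch[0] = r;
    S.nd[c].ch[1] = r;
    S.nd[c].pa[0] = p;
    S.nd[p].ch[pcs] = c;
  } else {
    S.nd[r].pa[1 - bit] = p;
    S.nd[p].ch[pcs] = r;
    S.nd[r].pa[bit] = c;
    if (aboveRoot) {
      S.nd[c].ch[0] = rootId;
      S.nd[c].ch[1] = r;
      S.nd[rootId].pa[0] = c;
    } else {
      int x = T[choice].first, sx = T[choice].second;
      int y = S.nd[x].pa[sx];
      int ycs = child_slot_of(S, y, x, sx);
      S.nd[x].pa[sx] = c;
      S.nd[y].ch[ycs] = c;
      S.nd[c].ch[0] = x;
      S.nd[c].ch[1] = r;
      S.nd[c].pa[0] = y;
    }
  }
  int R2 = 0;
  for (size_t i = 0; i < S.nd.size(); ++i) {
    if (S.nd[i].alive && S.nd[i].kind == 2) ++R2;
  }
  double lqd = -std::log((double)R2) - (trivial ? 0.0 : std::log(2.0));
  pr.logHR = lqd - lqb;
  pr.dirty = (bit == 1) ? iv_right(me, b) : iv_left(me, b);
  pr.structural = true;
  pr.fullDirty = false;
  return true;
}

static bool kern_death(State& S, const Tuning& tu, Proposal& pr) {
  std::vector<int> recs;
  for (size_t i = 0; i < S.nd.size(); ++i) {
    if (S.nd[i].alive && S.nd[i].kind == 2) recs.push_back((int)i);
  }
  if (recs.empty()) return false;
  int RA = (int)recs.size();
  int r = recs[(int)(unif_rand() * RA)];
  int slot = unif_rand() < 0.5 ? 0 : 1;
  int c = S.nd[r].pa[slot];
  if (S.nd[c].kind != 1) return false;
  bool trivial = (S.nd[r].pa[0] == S.nd[r].pa[1]);
  int u = S.nd[r].ch[0];
  int su = pa_slot_of(S, u, r);
  int b = S.nd[r].bp;
  double hr = S.nd[r].h, hc = S.nd[c].h, hu = S.nd[u].h;
  double lambda = S.theta;
  pr.dirty = edge_material(S, r, slot);
  double hpe; // height of the restored edge's top
  if (trivial) {
    int y = S.nd[c].pa[0];
    if (y < 0) return false; // trivial recombination at the grand root
    int ycs = child_slot_of(S, y, c, 0);
    S.nd[u].pa[su] = y;
    S.nd[y].ch[ycs] = u;
    kill_node(S, r);
    kill_node(S, c);
    hpe = S.nd[y].h;
  } else {
    int p = S.nd[r].pa[1 - slot];
    int crs = (S.nd[c].ch[0] == r) ? 0 : 1;      // c's child slot holding r
    if (S.nd[c].ch[crs] != r) return false;
    int x = S.nd[c].ch[1 - crs];
    if (x == r) return false; // should have been classed trivial
    int y = S.nd[c].pa[0];
    if (y < 0 && S.nd[x].kind != 1) return false; // new root must be coalescent
    int pcs = child_slot_of(S, p, r, 1 - slot);
    S.nd[u].pa[su] = p;
    S.nd[p].ch[pcs] = u;
    int sx = pa_slot_of(S, x, c);
    S.nd[x].pa[sx] = y;
    if (y >= 0) {
      int ycs = child_slot_of(S, y, c, 0);
      S.nd[y].ch[ycs] = x;
    }
    kill_node(S, r);
    kill_node(S, c);
    hpe = S.nd[p].h;
  }
  // reverse-birth density, computed on the post-death state
  std::vector<Edge> EB;
  edges_list(S, EB);
  IvSet me = edge_material(S, u, su);
  int span = iv_span(me);
  int mn = iv_min(me);
  if (span <= 0 || !(mn < b && b <= mn + span)) return false;
  int rootB = S.root();
  double rootH = S.nd[rootB].h;
  int k;
  if (hc > rootH) {
    k = 1;
  } else {
    k = 0;
    for (const Edge& t : EB) {
      double hx = S.nd[t.first].h, hy = S.nd[S.nd[t.first].pa[t.second]].h;
      if (hx < hc && hc < hy) ++k;
    }
    if (k == 0) return false;
  }
  double lqb = -std::log((double)EB.size()) - std::log((double)span)
    - std::log(hpe - hu) - std::log(lambda) - (hc - hr) / lambda
    - std::log((double)k);
  if (!trivial) lqb += std::log(0.5);
  double lqd = -std::log((double)RA) - (trivial ? 0.0 : std::log(2.0));
  pr.logHR = lqb - lqd;
  pr.structural = true;
  pr.fullDirty = false;
  return true;
}

static bool kern_bpshift(State& S, const Tuning& tu, Proposal& pr) {
  std::vector<int> recs;
  for (size_t i = 0; i < S.nd.size(); ++i) {
    if (S.nd[i].alive && S.nd[i].kind == 2) recs.push_back((int)i);
  }
  if (recs.empty()) return false;
  int r = recs[(int)(unif_rand() * recs.size())];
  int mag = 1 + (int)R::rgeom(tu.geom_p);
  int sgn = unif_rand() < 0.5 ? -1 : 1;
  int b = S.nd[r].bp;
  int b2 = b + sgn * mag;
  const IvSet& m = S.mat[r];
  int mn = iv_min(m), mx = iv_max(m);
  if (!(b2 > mn && b2 <= mx)) return false; // outside eligible gaps
  IvSet win{{std::min(b, b2), std::max(b, b2)}};
  IvSet inter;
  for (const Iv& i : m) {
    int s = std::max(i.s, win[0].s), e = std::min(i.e, win[0].e);
    if (s < e) inter.push_back({s, e});
  }
  pr.dirty = iv_norm(inter);
  S.nd[r].bp = b2;
  pr.logHR = 0.0;
  pr.structural = true;
  pr.fullDirty = false;
  return true;
}

static bool kern_regraft(State& S, const Tuning& tu, Proposal& pr) {
  // detachable edges: (v, slot) whose parent is coalescent, with a distinct
  // sibling; if the parent is the root the sibling must be coalescent
  std::vector<Edge> C;
  std::vector<Edge> allE;
  edges_list(S, allE);
  for (const Edge& e : allE) {
    int v = e.first, sv = e.second;
    int p = S.nd[v].pa[sv];
    if (S.nd[p].kind != 1) continue;
    int pcs = child_slot_of(S, p, v, sv);
    int w = S.nd[p].ch[1 - pcs];
    if (w == v) continue;
    if (S.nd[p].pa[0] < 0 && S.nd[w].kind != 1) continue;
    C.push_back(e);
  }
  if (C.empty()) return false;
  int NdA = (int)C.size();
  Edge e = C[(int)(unif_rand() * NdA)];
  int v = e.first, sv = e.second;
  int p = S.nd[v].pa[sv];
  int pcs = child_slot_of(S, p, v, sv);
  int w = S.nd[p].ch[1 - pcs];
  int sw = pa_slot_of(S, w, p);
  int q = S.nd[p].pa[0];
  double hv = S.nd[v].h, hw = S.nd[w].h, hp_old = S.nd[p].h;
  double hq = (q >= 0) ? S.nd[q].h : 0.0;
  IvSet mv = edge_material(S, v, sv);
  IvSet mw = edge_material(S, w, sw);
  // splice p out
  S.nd[w].pa[sw] = q;
  if (q >= 0) {
    int qcs = child_slot_of(S, q, p, 0);
    S.nd[q].ch[qcs] = w;
  }
  S.nd[v].pa[sv] = -1;
  S.nd[p].ch[0] = S.nd[p].ch[1] = -1;
  S.nd[p].pa[0] = S.nd[p].pa[1] = -1;
  int root0 = (q >= 0) ? S.root() : w;
  // p is dangling; S.root() may find p first — exclude it explicitly
  if (q >= 0) {
    root0 = -1;
    for (size_t i = 0; i < S.nd.size(); ++i) {
      if (!S.nd[i].alive || (int)i == p || (int)i == v) continue;
      if (S.nd[i].pa[0] < 0 && S.nd[i].pa[1] < 0) { root0 = (int)i; break; }
    }
    if (root0 < 0) root0 = w;
  }
  double hroot0 = S.nd[root0].h;
  double lambda = S.theta;
  // target edges in the intermediate graph
  std::vector<Edge> T;
  for (size_t i = 0; i < S.nd.size(); ++i) {
    if (!S.nd[i].alive || (int)i == p || (int)i == v) continue;
    int nslots = (S.nd[i].kind == 2) ? 2 : 1;
    for (int s = 0; s < nslots; ++s) {
      int pa = S.nd[i].pa[s];
      if (pa < 0) continue;
      double lo = std::max(hv, S.nd[i].h);
      if (S.nd[pa].h > lo) T.push_back({(int)i, s});
    }
  }
  int nopts = (int)T.size() + 1;
  int j = (int)(unif_rand() * nopts);
  double hnew, ldens_f;
  IvSet mx;
  if (j == (int)T.size()) {
    double base = std::max(hv, hroot0);
    hnew = base + exp_rand() * lambda;
    ldens_f = -std::log(lambda) - (hnew - base) / lambda;
    S.nd[p].h = hnew;
    S.nd[p].ch[0] = root0;
    S.nd[p].ch[1] = v;
    S.nd[root0].pa[0] = p;
    S.nd[v].pa[sv] = p;
  } else {
    int x = T[j].first, sx = T[j].second;
    int y = S.nd[x].pa[sx];
    double lo = std::max(hv, S.nd[x].h);
    double hy = S.nd[y].h;
    hnew = lo + unif_rand() * (hy - lo);
    ldens_f = -std::log(hy - lo);
    mx = edge_material(S, x, sx);
    int ycs = child_slot_of(S, y, x, sx);
    S.nd[x].pa[sx] = p;
    S.nd[y].ch[ycs] = p;
    S.nd[p].h = hnew;
    S.nd[p].ch[0] = x;
    S.nd[p].ch[1] = v;
    S.nd[p].pa[0] = y;
    S.nd[v].pa[sv] = p;
  }
  // reverse density at the original location
  double ldens_r;
  if (q >= 0) {
    ldens_r = -std::log(hq - std::max(hv, hw));
  } else {
    double base = std::max(hv, hroot0); // root of the intermediate graph is w
    ldens_r = -std::log(lambda) - (hp_old - base) / lambda;
  }
  // candidate count in the proposed state
  std::vector<Edge> allE2;
  edges_list(S, allE2);
  int NdB = 0;
  for (const Edge& e2 : allE2) {
    int v2 = e2.first, sv2 = e2.second;
    int p2 = S.nd[v2].pa[sv2];
    if (S.nd[p2].kind != 1) continue;
    int pcs2 = child_slot_of(S, p2, v2, sv2);
    int w2 = S.nd[p2].ch[1 - pcs2];
    if (w2 == v2) continue;
    if (S.nd[p2].pa[0] < 0 && S.nd[w2].kind != 1) continue;
    ++NdB;
  }
  pr.logHR = std::log((double)NdA) - std::log((double)NdB) + ldens_r - ldens_f;
  pr.dirty = iv_union(iv_union(mv, mw), mx);
  pr.structural = true;
  pr.fullDirty = false;
  return true;
}

static bool kern_scalar(State& S, const Tuning& tu, Proposal& pr, int which) {
  double m = std::exp(tu.f_scalar * (unif_rand() - 0.5));
  switch (which) {
    case 0: S.theta *= m; break;
    case 1: S.rho *= m; break;
    case 2:
      if (S.mod.f84) S.mod.kappa *= m; else S.mod.aRraw *= m;
      S.mod.derive();
      break;
    case 3:
      if (S.mod.f84) return false;
      S.mod.aYraw *= m;
      S.mod.derive();
      break;
  }
  pr.logHR = std::log(m);
  pr.structural = false;
  pr.fullDirty = (which >= 2);
  return true;
}

static bool propose(State& S, int kernel, const Tuning& tu, Proposal& pr) {
  pr.logHR = 0.0;
  pr.dirty.clear();
  pr.structural = false;
  pr.fullDirty = false;
  switch (kernel) {
    case K_HEIGHT: return kern_height(S, tu, pr);
    case K_ROOT_SCALE: return kern_root_scale(S, tu, pr);
    case K_REGRAFT: return kern_regraft(S, tu, pr);
    case K_BIRTH: return kern_birth(S, tu, pr);
    case K_DEATH: return kern_death(S, tu, pr);
    case K_BPSHIFT: return kern_bpshift(S, tu, pr);
    case K_ARG_SCALE: return kern_arg_scale(S, tu, pr);
    case K_THETA: return kern_scalar(S, tu, pr, 0);
    case K_RHO: return kern_scalar(S, tu, pr, 1);
    case K_SUB1: return kern_scalar(S, tu, pr, 2);
    case K_SUB2: return kern_scalar(S, tu, pr, 3);
  }
  return false;
}

// ---------------------------------------------------------------- R <-> C++

static State state_from_r(List argList, List paramsList) {
  State S;
  NumericVector h = argList["heights"];
  IntegerVector kind = argList["kind"];
  IntegerMatrix ch = argList["children"];
  IntegerMatrix pa = argList["parents"];
  IntegerVector bp = argList["breakpoints"];
  S.ntips = as<int>(argList["n_tips"]);
  S.L = as<int>(argList["L"]);
  int n = h.size();
  S.nd.resize(n);
  S.mat.resize(n);
  for (int i = 0; i < n; ++i) {
    Node& N = S.nd[i];
    N.h = h[i];
    N.kind = kind[i];
    N.ch[0] = ch(i, 0) == NA_INTEGER ? -1 : ch(i, 0) - 1;
    N.ch[1] = ch(i, 1) == NA_INTEGER ? -1 : ch(i, 1) - 1;
    N.pa[0] = pa(i, 0) == NA_INTEGER ? -1 : pa(i, 0) - 1;
    N.pa[1] = pa(i, 1) == NA_INTEGER ? -1 : pa(i, 1) - 1;
    N.bp = bp[i] == NA_INTEGER ? -1 : bp[i];
    N.alive = true;
  }
  S.theta = as<double>(paramsList["theta"]);
  S.rho = as<double>(paramsList["rho"]);
  S.growth = as<double>(paramsList["growth"]);
  List mod = paramsList["model"];
  NumericVector pi = mod["freqs"];
  for (int i = 0; i < 4; ++i) S.mod.pi[i] = pi[i];
  S.mod.f84 = as<std::string>(mod["family"]) == "F84";
  S.mod.kappa = as<double>(mod["kappa"]);
  S.mod.aRraw = as<double>(mod["alpha_R"]);
  S.mod.aYraw = as<double>(mod["alpha_Y"]);
  S.mod.derive();
  S.ll = 0.0;
  S.lp = 0.0;
  annotate(S);
  return S;
}

static List state_to_r(const State& S) {
  // compact alive nodes; tips keep positions 1..ntips
  std::vector<int> ids;
  for (size_t i = 0; i < S.nd.size(); ++i) if (S.nd[i].alive) ids.push_back((int)i);
  std::vector<int> newId(S.nd.size(), -1);
  for (size_t i = 0; i < ids.size(); ++i) newId[ids[i]] = (int)i;
  int n = (int)ids.size();
  NumericVector h(n);
  IntegerVector kind(n), bp(n);
  IntegerMatrix ch(n, 2), pa(n, 2);
  for (int i = 0; i < n; ++i) {
    const Node& N = S.nd[ids[i]];
    h[i] = N.h;
    kind[i] = N.kind;
    bp[i] = N.bp < 0 ? NA_INTEGER : N.bp;
    for (int s = 0; s < 2; ++s) {
      ch(i, s) = N.ch[s] < 0 ? NA_INTEGER : newId[N.ch[s]] + 1;
      pa(i, s) = N.pa[s] < 0 ? NA_INTEGER : newId[N.pa[s]] + 1;
    }
  }
  return List::create(
    _["heights"] = h, _["kind"] = kind, _["children"] = ch, _["parents"] = pa,
    _["breakpoints"] = bp, _["n_tips"] = S.ntips, _["L"] = S.L
  );
}

static Align align_from_r(List alnList) {
  Align A;
  A.n = as<int>(alnList["n"]);
  A.L = as<int>(alnList["L"]);
  IntegerVector sp = alnList["site_pattern"];
  A.sitePat.assign(sp.begin(), sp.end());
  IntegerMatrix pm = alnList["patterns"]; // n rows x P cols
  A.P = pm.ncol();
  A.pat.resize((size_t)A.P * A.n);
  for (int p = 0; p < A.P; ++p) {
    for (int i = 0; i < A.n; ++i) A.pat[(size_t)p * A.n + i] = pm(i, p);
  }
  NumericVector inv = alnList["inv_counts"];
  A.hasInv = false;
  for (int i = 0; i < 4; ++i) {
    A.invCounts[i] = inv[i];
    if (inv[i] > 0) A.hasInv = true;
  }
  return A;
}

static Priors priors_from_r(List paramsList) {
  Priors pr;
  List pl = paramsList["priors"];
  pr.th_sampled = as<bool>(pl["theta_sampled"]);
  pr.rho_sampled = as<bool>(pl["rho_sampled"]);
  pr.sub_sampled = as<bool>(pl["sub_sampled"]);
  pr.th_lo = as<double>(pl["theta_lo"]);
  pr.th_hi = as<double>(pl["theta_hi"]);
  pr.rho_lo = as<double>(pl["rho_lo"]);
  pr.rho_hi = as<double>(pl["rho_hi"]);
  pr.kap_lo = as<double>(pl["sub_lo"]);
  pr.kap_hi = as<double>(pl["sub_hi"]);
  return pr;
}

static Tuning tuning_from_r(List cfg) {
  Tuning tu;
  tu.win_height = as<double>(cfg["win_height"]);
  tu.f_root = as<double>(cfg["f_root"]);
  tu.f_arg = as<double>(cfg["f_arg"]);
  tu.f_scalar = as<double>(cfg["f_scalar"]);
  tu.geom_p = as<double>(cfg["geom_p"]);
  return tu;
}

// ------------------------------------------------------------- exported API

// [[Rcpp::export]]
List cpp_arg_loglik(List argList, List alnList, List paramsList) {
  State S = state_from_r(argList, paramsList);
  Align A = align_from_r(alnList);
  Workspace W;
  refresh_likelihood(S, A, IvSet(), true, W);
  int ni = (int)S.ivStart.size();
  IntegerVector st(ni), en(ni);
  NumericVector ll(ni);
  for (int i = 0; i < ni; ++i) {
    st[i] = S.ivStart[i];
    en[i] = (i + 1 < ni) ? S.ivStart[i + 1] : S.L;
    ll[i] = S.ivLL[i];
  }
  return List::create(
    _["loglik"] = S.ll, _["starts"] = st, _["ends"] = en, _["interval_loglik"] = ll
  );
}

// [[Rcpp::export]]
double cpp_interval_loglik(List argList, List alnList, List paramsList, int a, int b) {
  State S = state_from_r(argList, paramsList);
  Align A = align_from_r(alnList);
  Workspace W;
  return interval_loglik(S, A, a, b, W);
}

// [[Rcpp::export]]
double cpp_arg_log_prior(List argList, List paramsList) {
  State S = state_from_r(argList, paramsList);
  return log_prior_arg(S);
}

// [[Rcpp::export]]
List cpp_propose(List argList, List paramsList, int kernel, List cfg) {
  State S = state_from_r(argList, paramsList);
  Tuning tu = tuning_from_r(cfg);
  Proposal pr;
  bool ok = propose(S, kernel, tu, pr);
  if (ok && pr.structural) annotate(S);
  IntegerMatrix dm((int)pr.dirty.size(), 2);
  for (size_t i = 0; i < pr.dirty.size(); ++i) {
    dm((int)i, 0) = pr.dirty[i].s;
    dm((int)i, 1) = pr.dirty[i].e;
  }
  RObject argOut = ok ? (RObject)state_to_r(S) : (RObject)R_NilValue;
  return List::create(
    _["ok"] = ok, _["arg"] = argOut,
    _["log_hr"] = pr.logHR, _["dirty"] = dm,
    _["full_dirty"] = pr.fullDirty, _["structural"] = pr.structural,
    _["theta"] = S.theta, _["rho"] = S.rho,
    _["kappa"] = S.mod.kappa, _["alpha_R"] = S.mod.aRraw, _["alpha_Y"] = S.mod.aYraw
  );
}

// Fuzz audit: random proposals; incremental likelihood refresh vs from-
// scratch recomputation on the proposed state.
// [[Rcpp::export]]
List cpp_fuzz_audit(List argList, List alnList, List paramsList, List cfg,
                    int nprop, NumericVector weights) {
  State S = state_from_r(argList, paramsList);
  Align A = align_from_r(alnList);
  Priors prs = priors_from_r(paramsList);
  Tuning tu = tuning_from_r(cfg);
  Workspace W;
  refresh_likelihood(S, A, IvSet(), true, W);
  S.lp = log_prior_total(S, prs);
  double maxDiff = 0.0;
  int nOk = 0;
  double wtot = 0.0;
  for (int i = 0; i < weights.size(); ++i) wtot += weights[i];
  for (int it = 0; it < nprop; ++it) {
    double u = unif_rand() * wtot, acc = 0.0;
    int kern = 0;
    for (int i = 0; i < weights.size(); ++i) {
      acc += weights[i];
      if (u <= acc) { kern = i; break; }
    }
    State S2 = S;
    Proposal pr;
    if (!propose(S2, kern, tu, pr)) continue;
    if (pr.structural) annotate(S2);
    double lp2 = log_prior_total(S2, prs);
    if (lp2 == NEG_INF) continue;
    refresh_likelihood(S2, A, pr.dirty, pr.fullDirty, W);
    double scratch = loglik_scratch(S2, A, W);
    double d = std::fabs(S2.ll - scratch);
    if (d > maxDiff) maxDiff = d;
    ++nOk;
    // accept unconditionally to wander over state space
    S2.lp = lp2;
    std::swap(S, S2);
  }
  return List::create(_["max_abs_diff"] = maxDiff, _["n_evaluated"] = nOk);
}

// [[Rcpp::export]]
List cpp_run_mcmc(List argList, Nullable<List> alnList, List paramsList, List cfg) {
  State S = state_from_r(argList, paramsList);
  Priors prs = priors_from_r(paramsList);
  Tuning tu = tuning_from_r(cfg);
  NumericVector weights = cfg["weights"];
  long nsteps = (long)as<double>(cfg["n_steps"]);
  long sampleInt = (long)as<double>(cfg["sample_interval"]);
  long argSampleInt = (long)as<double>(cfg["arg_sample_interval"]);
  long burnin = (long)as<double>(cfg["burnin"]);
  long auditInt = (long)as<double>(cfg["audit_interval"]);
  double temperature = as<double>(cfg["temperature"]);
  bool tune = as<bool>(cfg["tune"]);
  long stepOffset = (long)as<double>(cfg["step_offset"]);
  bool hasData = alnList.isNotNull();
  Align A;
  if (hasData) A = align_from_r(alnList.get());
  Workspace W;

  if (hasData) refresh_likelihood(S, A, IvSet(), true, W); else S.ll = 0.0;
  S.lp = log_prior_total(S, prs);
  if (S.lp == NEG_INF) stop("initial state has zero prior density");

  double wtot = 0.0;
  for (int i = 0; i < weights.size(); ++i) wtot += weights[i];
  std::vector<long> nProp(K_COUNT, 0), nAcc(K_COUNT, 0);
  std::vector<long> tuneProp(K_COUNT, 0), tuneAcc(K_COUNT, 0);

  long nSamples = (sampleInt > 0) ? nsteps / sampleInt : 0;
  NumericMatrix trace((int)nSamples, 9);
  int traceRow = 0;
  List argSamples;
  std::vector<List> argSampleVec;
  double auditMaxLL = 0.0, auditMaxLP = 0.0;
  double bestLL = -std::numeric_limits<double>::infinity();
  long bestStep = -1;
  RObject bestArg = R_NilValue;

  for (long step = 1; step <= nsteps; ++step) {
    double u = unif_rand() * wtot, acc = 0.0;
    int kern = 0;
    for (int i = 0; i < weights.size(); ++i) {
      acc += weights[i];
      if (u <= acc) { kern = i; break; }
    }
    nProp[kern]++;
    tuneProp[kern]++;
    State S2 = S;
    Proposal pr;
    bool ok = propose(S2, kern, tu, pr);
    bool accepted = false;
    if (ok) {
      if (pr.structural) annotate(S2);
      double lp2 = log_prior_total(S2, prs);
      if (lp2 != NEG_INF) {
        if (hasData) refresh_likelihood(S2, A, pr.dirty, pr.fullDirty, W);
        else S2.ll = 0.0;
        S2.lp = lp2;
        if (std::isnan(S2.ll) || std::isnan(S2.lp)) {
          stop("NaN in likelihood/prior at step %d (kernel %d)", (int)step, kern);
        }
        double logA = (S2.ll - S.ll + S2.lp - S.lp) / temperature + pr.logHR;
        if (logA >= 0 || unif_rand() < std::exp(logA)) {
          std::swap(S, S2);  // reference exchange, no deep copy back
          accepted = true;
        }
      }
    }
    if (accepted) { nAcc[kern]++; tuneAcc[kern]++; }
    // burn-in auto-tuning toward 0.234 acceptance
    if (tune && step <= burnin && tuneProp[kern] >= 50) {
      double rate = (double)tuneAcc[kern] / tuneProp[kern];
      double f = std::exp(0.33 * (rate - 0.234));
      switch (kern) {
        case K_HEIGHT: tu.win_height = std::min(1e4, std::max(1e-8, tu.win_height * f)); break;
        case K_ROOT_SCALE: tu.f_root = std::min(10.0, std::max(1e-4, tu.f_root * f)); break;
        case K_ARG_SCALE: tu.f_arg = std::min(10.0, std::max(1e-4, tu.f_arg * f)); break;
        case K_THETA: case K_RHO: case K_SUB1: case K_SUB2:
          tu.f_scalar = std::min(10.0, std::max(1e-4, tu.f_scalar * f)); break;
        case K_BPSHIFT:
          tu.geom_p = std::min(0.9, std::max(1e-4, tu.geom_p / f)); break;
        default: break;
      }
      tuneProp[kern] = 0;
      tuneAcc[kern] = 0;
    }
    if (sampleInt > 0 && step % sampleInt == 0 && traceRow < (int)nSamples) {
      int nrec = 0;
      double rootH = 0.0;
      for (size_t i = 0; i < S.nd.size(); ++i) {
        if (!S.nd[i].alive) continue;
        if (S.nd[i].kind == 2) ++nrec;
        if (S.nd[i].h > rootH) rootH = S.nd[i].h;
      }
      trace(traceRow, 0) = (double)(step + stepOffset);
      trace(traceRow, 1) = S.ll;
      trace(traceRow, 2) = S.lp;
      trace(traceRow, 3) = S.theta;
      trace(traceRow, 4) = S.rho;
      trace(traceRow, 5) = S.mod.f84 ? S.mod.kappa : S.mod.aRraw;
      trace(traceRow, 6) = S.mod.f84 ? NA_REAL : S.mod.aYraw;
      trace(traceRow, 7) = (double)nrec;
      trace(traceRow, 8) = rootH;
      ++traceRow;
      if (hasData && S.ll > bestLL) {
        bestLL = S.ll;
        bestStep = step + stepOffset;
        bestArg = state_to_r(S);
      }
      if (auditInt > 0 && (step / sampleInt) % auditInt == 0) {
        if (hasData) {
          double scr = loglik_scratch(S, A, W);
          auditMaxLL = std::max(auditMaxLL, std::fabs(scr - S.ll));
        }
        double lps = log_prior_total(S, prs);
        auditMaxLP = std::max(auditMaxLP, std::fabs(lps - S.lp));
      }
    }
    if (argSampleInt > 0 && step % argSampleInt == 0 && step > burnin) {
      List s = state_to_r(S);
      s["step"] = (double)(step + stepOffset);
      s["theta"] = S.theta;
      s["rho"] = S.rho;
      argSampleVec.push_back(s);
    }
  }
  List argOut(argSampleVec.size());
  for (size_t i = 0; i < argSampleVec.size(); ++i) argOut[i] = argSampleVec[i];
  IntegerVector np(K_COUNT), na(K_COUNT);
  for (int i = 0; i < K_COUNT; ++i) { np[i] = (int)nProp[i]; na[i] = (int)nAcc[i]; }
  return List::create(
    _["trace"] = trace, _["arg_samples"] = argOut,
    _["proposed"] = np, _["accepted"] = na,
    _["final"] = state_to_r(S),
    _["final_theta"] = S.theta, _["final_rho"] = S.rho,
    _["final_kappa"] = S.mod.kappa,
    _["final_alpha_R"] = S.mod.aRraw, _["final_alpha_Y"] = S.mod.aYraw,
    _["final_loglik"] = S.ll, _["final_logprior"] = S.lp,
    _["best_arg"] = bestArg, _["best_step"] = (double)bestStep,
    _["best_loglik"] = bestLL,
    _["audit_max_loglik_diff"] = auditMaxLL,
    _["audit_max_logprior_diff"] = auditMaxLP,
    _["tuning"] = List::create(
      _["win_height"] = tu.win_height, _["f_root"] = tu.f_root,
      _["f_arg"] = tu.f_arg, _["f_scalar"] = tu.f_scalar,
      _["geom_p"] = tu.geom_p)
  );
}
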