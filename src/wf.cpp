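// Linked-haplotype Wright-Fisher engine for a herbicide-target locus.
//
// Haplotypes are sparse, sorted lists of mutation ids with copy-on-write
// sharing: a gamete that experiences neither crossover nor mutation reuses
// its parental haplotype object, so per-generation work scales with the
// number of mutation/recombination events plus the (short) per-individual
// fitness-relevant mutation lists, not with locus length.
//
// Performance notes (the rescaled study protocol runs 10N ~ 21,000
// burn-in generations per replicate, hundreds of replicates; the hot loop
// must avoid pointer chasing):
//   * the engine uses its own xoshiro256++ stream, seeded from R's RNG at
//     entry, so R-level set.seed() gives bitwise reproducibility;
//   * fitness-proportional parent sampling uses a Walker alias table;
//   * hot per-slot state (cached haplotype fitness, fitness-active
//     mutation ids as CSR rows, TSR-carrier flags) lives in flat arrays
//     rebuilt by sequential copies each generation; the haplotype objects
//     themselves are only touched on mutation, recombination or
//     bookkeeping;
//   * haplotype objects live in an arena collected by mark-and-sweep at
//     prune intervals (no per-copy refcounting);
//   * pair fitness is exact (1 / 1+hs / 1+s per site), with homozygotes
//     found by a generation-stamped carrier scan; deleterious mutations
//     with |2Ns| < 0.1 are carried and recorded but treated as
//     fitness-neutral (drift dominates such effects by an order of
//     magnitude; documented numerical tolerance).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cmath>
#include <cstdint>
#include <cstring>

using namespace Rcpp;

namespace {

// ------------------------------------------------------------------ RNG --

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  void seedFromR() {
    // pull entropy from R's RNG so R-level set.seed() controls the stream
    uint64_t x = (uint64_t)(unif_rand() * 9007199254740992.0);
    x ^= (uint64_t)(unif_rand() * 9007199254740992.0) << 11;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  double uniform() {  // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }

  int uniformInt(int n) {  // in [0, n)
    int k = (int)(uniform() * n);
    return k >= n ? n - 1 : k;
  }

  int rpois(double lambda) {
    if (lambda <= 0.0) return 0;
    // inversion; adequate for the small per-gamete event rates used here
    double p = std::exp(-lambda), F = p, u = uniform();
    int k = 0;
    while (u > F && k < 100000) {
      ++k;
      p *= lambda / k;
      F += p;
    }
    return k;
  }

  double rnorm() {
    double u1 = uniform(), u2 = uniform();
    while (u1 <= 0.0) u1 = uniform();
    return std::sqrt(-2.0 * std::log(u1)) *
           std::cos(6.283185307179586 * u2);
  }

  // Marsaglia-Tsang, with the shape<1 boost
  double rgamma(double shape, double scale) {
    if (shape < 1.0) {
      double u = uniform();
      while (u <= 0.0) u = uniform();
      return rgamma(shape + 1.0, scale) * std::pow(u, 1.0 / shape);
    }
    double d = shape - 1.0 / 3.0;
    double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x = rnorm();
      double v = 1.0 + c * x;
      if (v <= 0.0) continue;
      v = v * v * v;
      double u = uniform();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v * scale;
      if (u > 0.0 &&
          std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v)))
        return d * v * scale;
    }
  }
};

// Walker alias table for O(1) weighted sampling
struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;
  std::vector<double> p;           // scratch, reused across builds
  std::vector<int> small, large;   // scratch

  void build(const std::vector<double>& w) {
    int n = (int)w.size();
    prob.assign(n, 0.0); alias.assign(n, 0);
    double tot = 0.0;
    for (size_t i = 0; i < w.size(); ++i) tot += w[i];
    if (tot <= 0.0) stop("population fitness collapsed to zero");
    p.resize(n);
    for (int i = 0; i < n; ++i) p[i] = w[i] * n / tot;
    small.clear(); large.clear();
    small.reserve(n); large.reserve(n);
    for (int i = 0; i < n; ++i)
      (p[i] < 1.0 ? small : large).push_back(i);
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = p[s];
      alias[s] = l;
      p[l] = (p[l] + p[s]) - 1.0;
      (p[l] < 1.0 ? small : large).push_back(l);
    }
    while (!large.empty()) { prob[large.back()] = 1.0; large.pop_back(); }
    while (!small.empty()) { prob[small.back()] = 1.0; small.pop_back(); }
  }

  int sample(Xoshiro& rng) const {
    double u = rng.uniform() * prob.size();
    int i = (int)u;
    if (i >= (int)prob.size()) i = (int)prob.size() - 1;
    return (u - i) < prob[i] ? i : alias[i];
  }
};

// --------------------------------------------------------------- model --

// site classes, kept in sync with the R-level classifySite()
enum SiteClass { TSR_TARGET = 0, EXON_NEUTRAL = 1, EXON_DELETERIOUS = 2,
                 NONCODING_NEUTRAL = 3 };

struct Registry {
  std::vector<int> site;        // 0-based site index
  std::vector<double> s;        // selection coefficient (simulation scale)
  std::vector<double> h;        // dominance
  std::vector<int> cls;         // SiteClass
  std::vector<int> ogen;        // origin generation (<=0 burn-in)
  std::vector<double> het;      // 1 + h s   (floored at 1e-9)
  std::vector<double> selfterm; // (1+s) / (1+hs)^2
  std::vector<char> act;        // fitness-active flag
  std::vector<int> dense;       // compact index among active mutations
  int denseCount;
  Registry() : denseCount(0) {}
  size_t size() const { return site.size(); }

  int add(int st, double sel, double dom, int cl, int gen, double nsEps) {
    site.push_back(st); s.push_back(sel); h.push_back(dom);
    cls.push_back(cl); ogen.push_back(gen);
    double hetv = std::max(1e-9, 1.0 + dom * sel);
    double homv = std::max(1e-9, 1.0 + sel);
    het.push_back(hetv);
    selfterm.push_back(homv / (hetv * hetv));
    // effectively-neutral deleterious effects skip fitness bookkeeping;
    // TSR effects always count
    bool active = sel != 0.0 &&
                  (cl == TSR_TARGET || std::fabs(sel) >= nsEps);
    act.push_back(active ? 1 : 0);
    dense.push_back(active ? denseCount++ : -1);
    return (int)site.size() - 1;
  }
};

struct Hap {
  std::vector<int> mut;   // all mutation ids, sorted by (site, id)
  std::vector<int> sel;   // fitness-active ids
  std::vector<int> tsr;   // ids with cls == TSR_TARGET
  double w;               // product of het terms over sel
  char mark;              // mark-and-sweep flag
  Hap() : w(1.0), mark(0) {}
};

struct Template {
  int L;
  std::vector<int> ex_start, ex_end;  // half-open, sorted
  std::vector<int> tsr_sites;         // sorted
};

struct DFE {
  double p_neutral_exon, gamma_shape, gamma_scale, h_del, tsr_s_before;
};

struct Cfg {
  int N;
  double mu_site, rec_site, survival_ratio, lambda;
  int prune_every;
};

int classify_site(const Template& T, int site) {
  if (std::binary_search(T.tsr_sites.begin(), T.tsr_sites.end(), site))
    return TSR_TARGET;
  size_t k = std::upper_bound(T.ex_start.begin(), T.ex_start.end(), site) -
             T.ex_start.begin();
  if (k > 0 && site < T.ex_end[k - 1]) return EXON_NEUTRAL;
  return NONCODING_NEUTRAL;
}

void finalize_hap(Hap& H, const Registry& reg) {
  H.sel.clear(); H.tsr.clear();
  H.w = 1.0;
  for (size_t j = 0; j < H.mut.size(); ++j) {
    int id = H.mut[j];
    if (reg.cls[id] == TSR_TARGET) H.tsr.push_back(id);
    if (reg.act[id]) {
      H.sel.push_back(id);
      H.w *= reg.het[id];
    }
  }
}

struct SiteLess {
  const Registry* reg;
  bool operator()(int a, int b) const {
    if (reg->site[a] != reg->site[b]) return reg->site[a] < reg->site[b];
    return a < b;
  }
};

// immutable pool of fitness-active-id rows, one row per distinct
// haplotype; slots reference rows by (start, length), so the per-gamete
// fast path copies 8 bytes instead of a whole row
struct RowPool {
  std::vector<int> ids;
  int sz;
  RowPool() : sz(0) {}
  void clear() { sz = 0; }
  int append(const int* src, int n) {
    if (sz + n > (int)ids.size())
      ids.resize(std::max((int)ids.size() * 2 + 1024, sz + n));
    std::memcpy(ids.data() + sz, src, n * sizeof(int));
    int start = sz;
    sz += n;
    return start;
  }
  // append a row of mutation ids translated to dense indices
  int appendDense(const std::vector<int>& sel,
                  const std::vector<int>& dense) {
    int n = (int)sel.size();
    if (sz + n > (int)ids.size())
      ids.resize(std::max((int)ids.size() * 2 + 1024, sz + n));
    for (int j = 0; j < n; ++j) ids[sz + j] = dense[sel[j]];
    int start = sz;
    sz += n;
    return start;
  }
};

struct Engine {
  Template T;
  DFE D;
  Cfg C;
  Registry reg;
  Xoshiro rng;
  double pAny;        // P(gamete has >= 1 crossover or mutation)
  double muL, recL;
  double nsEps;       // fitness-bookkeeping threshold on |s|
  bool anyActive;     // any fitness-active mutation possibly segregating

  // population state: per-slot hot fields packed into one cache line
  struct alignas(32) Slot {
    const Hap* h;   // haplotype object (cold data)
    double w;       // cached haplotype fitness
    int rs, rl;     // row-pool start / length of fitness-active ids
    int tsr;        // carries >= 1 TSR allele
  };
  std::vector<Slot> slot, slotNext;
  RowPool pool;

  std::vector<Hap*> arena;            // all haplotype objects ever made
  std::vector<double> weights;
  std::vector<int> parentBuf;
  AliasTable alias;
  std::vector<int> counts;
  std::vector<int64_t> lastSeen;      // per dense id: last carrier tag
  std::vector<double> selfByDense;    // selfterm indexed by dense id
  int64_t genSerial;

  ~Engine() {
    for (size_t i = 0; i < arena.size(); ++i) delete arena[i];
  }

  void init_rates() {
    muL = C.mu_site * T.L;
    recL = C.rec_site * (T.L - 1);
    pAny = -std::expm1(-(muL + recL));
    nsEps = 0.1 / (2.0 * C.N);
    anyActive = false;
    genSerial = 1;
  }

  Hap* fresh() {
    Hap* h = new Hap();
    arena.push_back(h);
    return h;
  }

  // rebuild the flat slot fields (and the row pool) from the haplotype
  // objects; called at import and at prune intervals
  void refreshSlots() {
    int slots = (int)slot.size();
    pool.clear();
    std::unordered_map<const Hap*, int> seen;
    for (int s = 0; s < slots; ++s) {
      const Hap* h = slot[s].h;
      slot[s].w = h->w;
      slot[s].tsr = h->tsr.empty() ? 0 : 1;
      std::unordered_map<const Hap*, int>::iterator it = seen.find(h);
      if (it == seen.end()) {
        int st = pool.appendDense(h->sel, reg.dense);
        seen[h] = st;
        slot[s].rs = st;
      } else {
        slot[s].rs = it->second;
      }
      slot[s].rl = (int)h->sel.size();
    }
  }

  // mark-and-sweep garbage collection of unreferenced haplotypes
  void sweep() {
    for (size_t i = 0; i < slot.size(); ++i)
      const_cast<Hap*>(slot[i].h)->mark = 1;
    size_t keep = 0;
    for (size_t i = 0; i < arena.size(); ++i) {
      if (arena[i]->mark) {
        arena[i]->mark = 0;
        arena[keep++] = arena[i];
      } else {
        delete arena[i];
      }
    }
    arena.resize(keep);
  }

  int draw_effect(int site, int gen) {
    int base = classify_site(T, site);
    double s, h; int cl;
    if (base == TSR_TARGET) {
      s = D.tsr_s_before * C.lambda;
      if (s < -0.999999) s = -0.999999;
      h = D.h_del; cl = TSR_TARGET;
    } else if (base == NONCODING_NEUTRAL) {
      s = 0.0; h = 0.5; cl = NONCODING_NEUTRAL;
    } else if (rng.uniform() < D.p_neutral_exon) {
      s = 0.0; h = 0.5; cl = EXON_NEUTRAL;
    } else {
      double g = rng.rgamma(D.gamma_shape, D.gamma_scale);
      s = -std::min(0.999999, g * C.lambda);
      h = D.h_del; cl = EXON_DELETERIOUS;
    }
    int id = reg.add(site, s, h, cl, gen, nsEps);
    if (reg.act[id]) {
      anyActive = true;
      selfByDense.push_back(reg.selfterm[id]);
    }
    return id;
  }

  // build a recombinant/mutant gamete; slotA is the starting strand
  Hap* make_gamete_slow(int slotA, int slotB, int nco, int nmu, int gen) {
    Hap* out = fresh();
    const Hap* A = slot[slotA].h;
    const Hap* B = slot[slotB].h;

    if (nco == 0) {
      out->mut = A->mut;
    } else {
      std::vector<int> bp(nco);
      for (int k = 0; k < nco; ++k) bp[k] = 1 + rng.uniformInt(T.L - 1);
      std::sort(bp.begin(), bp.end());
      bp.push_back(T.L);
      size_t ia = 0, ib = 0;
      bool useA = true;
      int prev = 0;
      for (size_t kk = 0; kk < bp.size(); ++kk) {
        int b = bp[kk];
        if (b > prev) {
          if (useA) {
            while (ia < A->mut.size() && reg.site[A->mut[ia]] < b)
              out->mut.push_back(A->mut[ia++]);
            while (ib < B->mut.size() && reg.site[B->mut[ib]] < b) ++ib;
          } else {
            while (ib < B->mut.size() && reg.site[B->mut[ib]] < b)
              out->mut.push_back(B->mut[ib++]);
            while (ia < A->mut.size() && reg.site[A->mut[ia]] < b) ++ia;
          }
          prev = b;
        }
        useA = !useA;
      }
    }

    if (nmu > 0) {
      std::vector<int> newIds(nmu);
      for (int k = 0; k < nmu; ++k)
        newIds[k] = draw_effect(rng.uniformInt(T.L), gen);
      SiteLess cmp{&reg};
      std::sort(newIds.begin(), newIds.end(), cmp);
      std::vector<int> merged;
      merged.reserve(out->mut.size() + newIds.size());
      std::merge(out->mut.begin(), out->mut.end(), newIds.begin(),
                 newIds.end(), std::back_inserter(merged), cmp);
      out->mut.swap(merged);
    }

    finalize_hap(*out, reg);
    return out;
  }

  // one Wright-Fisher generation
  void generation(int gen, bool selection) {
    const int N = C.N;
    const int slots = 2 * N;
    bool doSel = selection && C.survival_ratio != 1.0;
    bool anySel = false;
    if (anyActive || doSel) {
      weights.resize(N);
      lastSeen.resize(reg.denseCount, 0);
      // heterozygous products come cached per slot; homozygotes are
      // found by scanning carriers of each active mutation with
      // generation-stamped tags (exact 1 / 1+hs / 1+s fitness)
      const int64_t base = (genSerial++) * (int64_t)(N + 1);
      const int* ids = pool.ids.data();
      const double* sbd = selfByDense.data();
      int64_t* seen = lastSeen.data();
      for (int i = 0; i < N; ++i) {
        const Slot& a = slot[2 * i];
        const Slot& b = slot[2 * i + 1];
        double w = a.w * b.w;
        const int64_t tag = base + i;
        const int* rowA = ids + a.rs;
        for (int j = 0; j < a.rl; ++j) seen[rowA[j]] = tag;
        const int* rowB = ids + b.rs;
        for (int j = 0; j < b.rl; ++j) {
          int k = rowB[j];
          if (seen[k] == tag) w *= sbd[k];  // carried on both haplotypes
        }
        if (doSel && (a.tsr || b.tsr)) w *= C.survival_ratio;
        if (w != 1.0) anySel = true;
        weights[i] = w;
      }
    }
    // fitness-proportional sampling: cheap rejection sampling while the
    // weight spread is mild (burn-in), alias table otherwise
    double wmax = 0.0, wtot = 0.0;
    bool rejectMode = false;
    if (anySel) {
      for (int i = 0; i < N; ++i) {
        wtot += weights[i];
        if (weights[i] > wmax) wmax = weights[i];
      }
      if (wtot <= 0.0) stop("population fitness collapsed to zero");
      rejectMode = wmax * N <= 1.3 * wtot;
      if (!rejectMode) alias.build(weights);
    }

    slotNext.resize(slots);
    // draw all parents first: the tight loop pipelines the RNG and the
    // alias-table lookups much better than interleaving with the copies
    parentBuf.resize(slots);
    if (!anySel) {
      for (int i = 0; i < slots; ++i) parentBuf[i] = rng.uniformInt(N);
    } else if (rejectMode) {
      const double* wp = weights.data();
      for (int i = 0; i < slots; ++i) {
        int cand;
        do {
          cand = rng.uniformInt(N);
        } while (rng.uniform() * wmax > wp[cand]);
        parentBuf[i] = cand;
      }
    } else {
      for (int i = 0; i < slots; ++i) parentBuf[i] = alias.sample(rng);
    }
    for (int i = 0; i < slots; ++i) {
      int p = parentBuf[i];
      double u = rng.uniform();
      // strand choice and a recycled second uniform, branch-free
      int st = (int)(2.0 * u);           // 0 or 1
      double v = 2.0 * u - st;
      int src = 2 * p + st;
      if (v >= pAny) {  // fast path: share the parental haplotype
        slotNext[i] = slot[src];
        continue;
      }
      // conditional on >= 1 event; rejection keeps the joint distribution
      int nco = 0, nmu = 0;
      do {
        nco = rng.rpois(recL);
        nmu = rng.rpois(muL);
      } while (nco == 0 && nmu == 0);
      Hap* g = make_gamete_slow(src, 2 * p + (1 - st), nco, nmu, gen);
      Slot& sl = slotNext[i];
      sl.h = g;
      sl.w = g->w;
      sl.tsr = g->tsr.empty() ? 0 : 1;
      sl.rs = pool.appendDense(g->sel, reg.dense);
      sl.rl = (int)g->sel.size();
    }
    slot.swap(slotNext);
  }

  void count_all() {
    counts.assign(reg.size(), 0);
    for (size_t k = 0; k < slot.size(); ++k) {
      const Hap* h = slot[k].h;
      for (size_t j = 0; j < h->mut.size(); ++j) ++counts[h->mut[j]];
    }
  }

  // drop fixed non-TSR mutations from every haplotype; returns their ids
  std::vector<int> prune_fixed(int twoN) {
    std::vector<char> drop(reg.size(), 0);
    std::vector<int> fixed;
    for (size_t id = 0; id < reg.size(); ++id)
      if (counts[id] == twoN && reg.cls[id] != TSR_TARGET) {
        drop[id] = 1;
        fixed.push_back((int)id);
      }
    bool act = false;
    reg.denseCount = 0;
    selfByDense.clear();
    for (size_t id = 0; id < reg.size(); ++id)
      if (reg.act[id]) {
        if (counts[id] > 0) {  // segregating or fixed active TSR
          act = true;
          reg.dense[id] = reg.denseCount++;
          selfByDense.push_back(reg.selfterm[id]);
        } else {
          reg.dense[id] = -1;
        }
      }
    lastSeen.assign(reg.denseCount, 0);
    anyActive = act;
    if (fixed.empty()) return fixed;
    std::unordered_map<const Hap*, Hap*> rebuilt;
    for (size_t k = 0; k < slot.size(); ++k) {
      const Hap* old = slot[k].h;
      std::unordered_map<const Hap*, Hap*>::iterator it =
          rebuilt.find(old);
      if (it != rebuilt.end()) { slot[k].h = it->second; continue; }
      Hap* nh = fresh();
      nh->mut.reserve(old->mut.size());
      for (size_t j = 0; j < old->mut.size(); ++j)
        if (!drop[old->mut[j]]) nh->mut.push_back(old->mut[j]);
      finalize_hap(*nh, reg);
      rebuilt[old] = nh;
      slot[k].h = nh;
    }
    return fixed;
  }

  void tsr_counts(std::unordered_map<int, int>& out) const {
    out.clear();
    for (size_t k = 0; k < slot.size(); ++k) {
      const Hap* h = slot[k].h;
      for (size_t j = 0; j < h->tsr.size(); ++j) ++out[h->tsr[j]];
    }
  }
};

Template as_template(const List& tmpl) {
  Template T;
  T.L = as<int>(tmpl["length_bp"]);
  T.ex_start = as<std::vector<int> >(tmpl["exon_start"]);
  T.ex_end = as<std::vector<int> >(tmpl["exon_end"]);
  T.tsr_sites = as<std::vector<int> >(tmpl["tsr_sites"]);
  std::sort(T.tsr_sites.begin(), T.tsr_sites.end());
  return T;
}

DFE as_dfe(const List& dfe) {
  DFE D;
  D.p_neutral_exon = as<double>(dfe["p_neutral_exon"]);
  D.gamma_shape = as<double>(dfe["gamma_shape"]);
  D.gamma_scale = as<double>(dfe["gamma_scale"]);
  D.h_del = as<double>(dfe["h_del"]);
  D.tsr_s_before = as<double>(dfe["tsr_s_before"]);
  return D;
}

Cfg as_cfg(const List& cfg) {
  Cfg C;
  C.N = as<int>(cfg["N"]);
  C.mu_site = as<double>(cfg["mu_site"]);
  C.rec_site = as<double>(cfg["rec_site"]);
  C.survival_ratio = as<double>(cfg["survival_ratio"]);
  C.lambda = as<double>(cfg["lambda"]);
  C.prune_every = as<int>(cfg["prune_every"]);
  return C;
}

}  // namespace

// Run `n_gens` generations of burn-in (selection = false, generations
// counted ..., -1, 0) or herbicide selection (true, generations 1..T).
//
// `state` is NULL (start from a mutation-free population) or a list with
// elements `generation`, `haplotypes` (list of integer id vectors,
// 1-based into the registry) and `registry`.
//
// Returns the final state (ids remapped to surviving registry rows), the
// TSR trajectory table, the burn-in census and the fixed-mutation
// archive.
// [[Rcpp::export]]
List cpp_wf_run(Nullable<List> state, List tmpl, List dfe, List cfg,
                int n_gens, bool selection, int census_every,
                bool record_trajectory, int sel_after,
                bool export_haplotypes) {
  Engine E;
  E.T = as_template(tmpl);
  E.D = as_dfe(dfe);
  E.C = as_cfg(cfg);
  E.init_rates();
  const int twoN = 2 * E.C.N;

  GetRNGstate();
  E.rng.seedFromR();
  PutRNGstate();

  int gen0 = selection ? 0 : -n_gens;

  if (state.isNotNull()) {
    List st(state);
    gen0 = as<int>(st["generation"]);
    List regl = st["registry"];
    std::vector<int> rsite = as<std::vector<int> >(regl["site"]);
    std::vector<double> rs = as<std::vector<double> >(regl["s"]);
    std::vector<double> rh = as<std::vector<double> >(regl["h"]);
    std::vector<int> rcls = as<std::vector<int> >(regl["cls"]);
    std::vector<int> rogen = as<std::vector<int> >(regl["origin_gen"]);
    for (size_t j = 0; j < rsite.size(); ++j) {
      int id = E.reg.add(rsite[j], rs[j], rh[j], rcls[j], rogen[j],
                         E.nsEps);
      if (E.reg.act[id]) {
        E.anyActive = true;
        E.selfByDense.push_back(E.reg.selfterm[id]);
      }
    }
    List haps = st["haplotypes"];
    if (haps.size() != twoN)
      stop("state has %d haplotypes but config N implies %d",
           (int)haps.size(), twoN);
    E.slot.resize(twoN);
    SiteLess cmp{&E.reg};
    for (int k = 0; k < twoN; ++k) {
      Hap* h = E.fresh();
      IntegerVector ids = haps[k];
      h->mut.reserve(ids.size());
      for (int j = 0; j < ids.size(); ++j) {
        int id = ids[j];
        if (id < 1 || id > (int)E.reg.size())
          stop("haplotype id out of range");
        h->mut.push_back(id - 1);
      }
      std::sort(h->mut.begin(), h->mut.end(), cmp);
      finalize_hap(*h, E.reg);
      E.slot[k].h = h;
    }
  } else {
    Hap* empty = E.fresh();
    E.slot.resize(twoN);
    for (int k = 0; k < twoN; ++k) E.slot[k].h = empty;
  }
  E.refreshSlots();

  std::vector<int> fx_id, fx_gen;                  // fixed (non-TSR)
  std::vector<int> tr_gen, tr_id, tr_count;        // TSR trajectory
  std::unordered_map<int, int> tcounts;
  std::vector<int> cs_gen, cs_n;                   // burn-in census

  // record one trajectory row per segregating TSR origin at `gen`
#define RECORD_TSR(gen_)                                        \
  do {                                                          \
    E.tsr_counts(tcounts);                                      \
    std::vector<int> ids_;                                      \
    ids_.reserve(tcounts.size());                               \
    for (std::unordered_map<int, int>::iterator it =            \
             tcounts.begin(); it != tcounts.end(); ++it)        \
      ids_.push_back(it->first);                                \
    std::sort(ids_.begin(), ids_.end());                        \
    for (size_t q = 0; q < ids_.size(); ++q) {                  \
      tr_gen.push_back(gen_);                                   \
      tr_id.push_back(ids_[q]);                                 \
      tr_count.push_back(tcounts[ids_[q]]);                     \
    }                                                           \
  } while (0)

  // up to two phases: a burn-in stretch and/or a selection stretch (the
  // latter either because selection=true or because sel_after > 0)
  int nPhase[2]; bool selPhase[2];
  if (selection) {
    nPhase[0] = n_gens; selPhase[0] = true;
    nPhase[1] = 0; selPhase[1] = false;
  } else {
    nPhase[0] = n_gens; selPhase[0] = false;
    nPhase[1] = sel_after; selPhase[1] = true;
  }

  int gen = gen0;
  for (int ph = 0; ph < 2; ++ph) {
    if (nPhase[ph] <= 0) continue;
    bool selNow = selPhase[ph];
    int phStart = gen;
    int last = gen + nPhase[ph];
    if (record_trajectory && selNow) RECORD_TSR(gen);  // onset snapshot
    bool exited = false;
    for (gen = phStart + 1; gen <= last; ++gen) {
      E.generation(gen, selNow);

      if (record_trajectory && selNow) RECORD_TSR(gen);
      if (!selNow && census_every > 0 &&
          ((gen - phStart) % census_every == 0 || gen == last)) {
        E.tsr_counts(tcounts);
        cs_gen.push_back(gen);
        cs_n.push_back((int)tcounts.size());
      }

      bool do_prune = (E.C.prune_every > 0 &&
                       (gen - phStart) % E.C.prune_every == 0) ||
                      gen == last;
      if (do_prune) {
        E.count_all();
        std::vector<int> fixed = E.prune_fixed(twoN);
        E.sweep();
        E.refreshSlots();  // also compacts the row pool
        for (size_t j = 0; j < fixed.size(); ++j) {
          fx_id.push_back(fixed[j]);
          fx_gen.push_back(gen);
        }
        // early exit: monomorphic and no mutational input
        if (E.C.mu_site == 0.0 && gen < last) {
          bool seg = false;
          for (size_t id = 0; id < E.reg.size(); ++id)
            if (E.counts[id] > 0 && E.counts[id] < twoN) {
              seg = true; break;
            }
          if (!seg) {
            if (record_trajectory && selNow) {
              // fixed TSR lineages persist at frequency 1
              for (int g2 = gen + 1; g2 <= last; ++g2) RECORD_TSR(g2);
            }
            exited = true;
            break;
          }
        }
      }
    }
    gen = last;
    (void)exited;
  }
  int last = gen;
#undef RECORD_TSR

  // ---- export: keep registry rows still present on haplotypes ----
  E.count_all();
  std::vector<int> keep;
  std::vector<int> remap(E.reg.size(), 0);  // old id -> new 1-based id
  for (size_t id = 0; id < E.reg.size(); ++id)
    if (E.counts[id] > 0) {
      remap[id] = (int)keep.size() + 1;
      keep.push_back((int)id);
    }

  int K = (int)keep.size();
  IntegerVector r_site(K), r_cls(K), r_ogen(K), r_count(K);
  NumericVector r_s(K), r_h(K);
  for (int k = 0; k < K; ++k) {
    int id = keep[k];
    r_site[k] = E.reg.site[id]; r_s[k] = E.reg.s[id];
    r_h[k] = E.reg.h[id]; r_cls[k] = E.reg.cls[id];
    r_ogen[k] = E.reg.ogen[id]; r_count[k] = E.counts[id];
  }

  List haps(export_haplotypes ? twoN : 0);
  if (export_haplotypes) {
    for (int k = 0; k < twoN; ++k) {
      const std::vector<int>& m = E.slot[k].h->mut;
      IntegerVector v(m.size());
      for (size_t j = 0; j < m.size(); ++j) v[j] = remap[m[j]];
      haps[k] = v;
    }
  }

  // trajectory ids -> export ids where possible; lost lineages keep a
  // negative id so independent origins remain countable
  int ntr = (int)tr_gen.size();
  IntegerVector t_gen(ntr), t_id(ntr), t_count(ntr), t_ogen(ntr),
      t_site(ntr);
  for (int j = 0; j < ntr; ++j) {
    int id = tr_id[j];
    t_gen[j] = tr_gen[j];
    t_id[j] = remap[id] > 0 ? remap[id] : -(id + 1);
    t_count[j] = tr_count[j];
    t_ogen[j] = E.reg.ogen[id];
    t_site[j] = E.reg.site[id];
  }

  int nfx = (int)fx_id.size();
  IntegerVector f_site(nfx), f_cls(nfx), f_ogen(nfx), f_gen(nfx);
  NumericVector f_s(nfx);
  for (int j = 0; j < nfx; ++j) {
    int id = fx_id[j];
    f_site[j] = E.reg.site[id]; f_s[j] = E.reg.s[id];
    f_cls[j] = E.reg.cls[id]; f_ogen[j] = E.reg.ogen[id];
    f_gen[j] = fx_gen[j];
  }

  return List::create(
      _["generation"] = last,
      _["haplotypes"] = haps,
      _["registry"] = List::create(
          _["site"] = r_site, _["s"] = r_s, _["h"] = r_h, _["cls"] = r_cls,
          _["origin_gen"] = r_ogen, _["count"] = r_count),
      _["trajectory"] = List::create(
          _["generation"] = t_gen, _["origin_id"] = t_id,
          _["count"] = t_count, _["origin_gen"] = t_ogen,
          _["site"] = t_site),
      _["census"] = List::create(_["generation"] = cs_gen,
                                 _["n_tsr_origins"] = cs_n),
      _["fixed"] = List::create(
          _["site"] = f_site, _["s"] = f_s, _["cls"] = f_cls,
          _["origin_gen"] = f_ogen, _["fixed_gen"] = f_gen));
}
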