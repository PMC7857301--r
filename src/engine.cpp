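// Core individual-based non-Wright-Fisher engine.
//
// A Population holds diploid individuals whose haplotypes are spans into a
// pooled, generation-compacted arena of 16-byte entries. Each entry packs
// the mutation's sort key ((bp position << 32) | id) together with its
// heterozygous and homozygous fitness factors, so the per-generation hot
// path (gamete formation, offspring fitness) is sequential over a compact
// arena and never touches the growing mutation table. The table itself is
// append-only and shared (shared_ptr) by all populations cloned from a
// common ancestor within one replicate, which is what allows migrants to
// be copied between populations. All randomness goes through R's RNG so
// that set.seed() on the R side gives full reproducibility.

#include <Rcpp.h>
#include <memory>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

typedef uint64_t mkey;

static inline mkey make_key(int pos, int id) {
  return ((mkey)(uint32_t)pos << 32) | (uint32_t)id;
}
static inline int key_pos(mkey k) { return (int)(k >> 32); }
static inline int key_id(mkey k) { return (int)(uint32_t)k; }

// One haplotype entry: sort key plus the mutation's heterozygous (1 + h*s)
// and homozygous (1 + s) fitness factors. Single precision keeps the entry
// at 16 bytes; the ~1e-7 relative rounding on a fitness factor is far
// below the drift and sampling noise of the model.
struct Entry {
  mkey key;
  float hetf, homf;
  bool operator<(const Entry& o) const { return key < o.key; }
};

// ---------------------------------------------------------------------------
// data structures

struct MutTable {
  std::vector<int> pos;     // global coding-coordinate bp, 1-based
  std::vector<int> gene;    // 0-based gene index
  std::vector<double> s;    // selection coefficient, <= 0
  std::vector<double> h;    // dominance coefficient
  std::vector<int> origin;  // generation of origin
  int add(int p, int g, double s_, double h_, int org) {
    pos.push_back(p); gene.push_back(g); s.push_back(s_); h.push_back(h_);
    origin.push_back(org);
    return (int)pos.size() - 1;
  }
  int size() const { return (int)pos.size(); }
};

struct Params {
  int n_genes, gene_len, n_chrom;
  std::vector<int> chrom_cum;     // cumulative gene counts, length n_chrom+1
  std::vector<int> adj_cum;       // cumulative within-chromosome adjacencies
  double recomb, mu_bp;
  double total_bp;
  double log1m_recomb;            // log(1 - recomb), geometric crossover gaps
  double mu_lambda, exp_neg_lambda;
  uint64_t div_magic; int div_shift; bool div_ok;  // fast (pos-1)/L
  std::vector<int> chrom_end_bp;  // global bp end of each chromosome
  // DFE
  double p_del, g_shape, g_scale;
  int trunc;                      // 0 none, 1 strong_only, 2 weak_moderate_only
  // dominance
  int dom_model;                  // 0 hs_relationship, 1 hmix, 2 fixed
  double fixed_h, hs_c, hmix_thr, hmix_weak, hmix_strong;
};

struct Indiv {
  int id;
  int age;
  double segw;              // cached fitness product over the (immutable)
                            // genotype; pruning divides out fixed factors
  uint32_t o1, l1, o2, l2;  // haplotype spans into the population arena
};

struct Pop {
  std::shared_ptr<MutTable> tab;
  Params par;
  std::vector<Entry> pool;      // haplotype arena
  std::vector<Entry> scratch;   // swap buffer for compaction
  std::vector<Indiv> inds;
  double fixed_load = 1.0;
  int generation = 0;
  int K_base = 0, K_cur = 0;
  int next_id = 0;
};

typedef XPtr<Pop> PopPtr;

static inline const Entry* hap1(const Pop& p, const Indiv& i) {
  return p.pool.data() + i.o1;
}
static inline const Entry* hap2(const Pop& p, const Indiv& i) {
  return p.pool.data() + i.o2;
}

// drop the arena holes left by dead individuals / pruned mutations
static void compact(Pop& pop) {
  pop.scratch.clear();
  pop.scratch.reserve(pop.pool.size());
  for (auto& ind : pop.inds) {
    uint32_t o1 = (uint32_t)pop.scratch.size();
    pop.scratch.insert(pop.scratch.end(), hap1(pop, ind),
                       hap1(pop, ind) + ind.l1);
    uint32_t o2 = (uint32_t)pop.scratch.size();
    pop.scratch.insert(pop.scratch.end(), hap2(pop, ind),
                       hap2(pop, ind) + ind.l2);
    ind.o1 = o1; ind.o2 = o2;
  }
  pop.pool.swap(pop.scratch);
}

// ---------------------------------------------------------------------------
// helpers

static Params params_from_list(List p) {
  Params q;
  q.n_genes  = as<int>(p["n_genes"]);
  q.gene_len = as<int>(p["gene_length_bp"]);
  q.n_chrom  = as<int>(p["n_chromosomes"]);
  IntegerVector counts = p["per_chromosome_gene_counts"];
  if ((int)counts.size() != q.n_chrom)
    stop("per_chromosome_gene_counts must have length n_chromosomes");
  q.chrom_cum.assign(q.n_chrom + 1, 0);
  q.adj_cum.assign(q.n_chrom + 1, 0);
  for (int c = 0; c < q.n_chrom; ++c) {
    q.chrom_cum[c + 1] = q.chrom_cum[c] + counts[c];
    q.adj_cum[c + 1] = q.adj_cum[c] + std::max(0, counts[c] - 1);
  }
  if (q.chrom_cum[q.n_chrom] != q.n_genes)
    stop("per_chromosome_gene_counts must sum to n_genes");
  q.recomb   = as<double>(p["inter_gene_recomb_rate"]);
  q.mu_bp    = as<double>(p["mutation_rate_per_bp"]);
  q.total_bp = (double)q.n_genes * (double)q.gene_len;
  q.log1m_recomb = (q.recomb > 0.0 && q.recomb < 1.0) ? std::log1p(-q.recomb)
                                                      : 0.0;
  q.mu_lambda = q.mu_bp * q.total_bp;
  q.exp_neg_lambda = std::exp(-q.mu_lambda);
  // multiplicative reciprocal for the hot (pos-1)/gene_length division,
  // verified exhaustively at every gene boundary before use
  q.div_shift = 40;
  q.div_magic = ((uint64_t)1 << q.div_shift) / q.gene_len + 1;
  q.div_ok = true;
  for (int g = 0; g <= q.n_genes && q.div_ok; ++g) {
    uint64_t lo = (uint64_t)g * q.gene_len;
    if ((uint32_t)((lo * q.div_magic) >> q.div_shift) != (uint32_t)g)
      q.div_ok = false;
    if (g > 0) {
      uint64_t hi = lo - 1;
      if ((uint32_t)((hi * q.div_magic) >> q.div_shift) != (uint32_t)(g - 1))
        q.div_ok = false;
    }
  }
  q.chrom_end_bp.resize(q.n_chrom);
  for (int c = 0; c < q.n_chrom; ++c)
    q.chrom_end_bp[c] = q.chrom_cum[c + 1] * q.gene_len;
  q.p_del    = as<double>(p["p_deleterious"]);
  q.g_shape  = as<double>(p["gamma_shape"]);
  q.g_scale  = as<double>(p["gamma_scale"]);
  q.trunc    = as<int>(p["truncation_code"]);
  q.dom_model = as<int>(p["dominance_code"]);
  q.fixed_h  = as<double>(p["fixed_h"]);
  q.hs_c     = as<double>(p["hs_scale_constant"]);
  q.hmix_thr = as<double>(p["hmix_strong_threshold"]);
  q.hmix_weak = as<double>(p["hmix_weak_h"]);
  q.hmix_strong = as<double>(p["hmix_strong_h"]);
  return q;
}

static inline int gene_of(const Params& par, int pos) {
  if (par.div_ok)
    return (int)(((uint64_t)(pos - 1) * par.div_magic) >> par.div_shift);
  return (pos - 1) / par.gene_len;
}

static inline int chrom_of(const Params& par, int gene) {
  int lo = std::upper_bound(par.chrom_cum.begin() + 1, par.chrom_cum.end(),
                            gene) - par.chrom_cum.begin();
  return lo - 1;
}

static inline double dominance_of(const Params& par, double s) {
  if (s == 0.0) return 0.5;              // neutral: bookkeeping value only
  switch (par.dom_model) {
  case 0:  return 0.5 / (1.0 + par.hs_c * (-s));
  case 1:  return (s >= par.hmix_thr) ? par.hmix_weak : par.hmix_strong;
  default: return par.fixed_h;
  }
}

static inline double draw_s(const Params& par) {
  if (unif_rand() >= par.p_del) return 0.0;
  double x = R::rgamma(par.g_shape, par.g_scale);
  double s = -std::min(1.0, x);
  if (par.trunc == 1 && s >= -0.01) s = 0.0;       // strong_only
  else if (par.trunc == 2 && s < -0.01) s = 0.0;   // weak_moderate_only
  return s;
}

// multiplicative fitness over one diploid genotype given as two sorted
// entry ranges (segregating part only)
static double seg_fitness_spans(const Entry* a, size_t na,
                                const Entry* b, size_t nb) {
  double w = 1.0;
  size_t i = 0, j = 0;
  while (i < na || j < nb) {
    if (i < na && j < nb && a[i].key == b[j].key) {       // homozygous
      w *= a[i].homf;
      ++i; ++j;
    } else if (j == nb || (i < na && a[i].key < b[j].key)) {
      w *= a[i].hetf;
      ++i;
    } else {
      w *= b[j].hetf;
      ++j;
    }
  }
  return w;
}

static inline double seg_fitness(const Pop& pop, const Indiv& ind) {
  return seg_fitness_spans(hap1(pop, ind), ind.l1, hap2(pop, ind), ind.l2);
}

static inline double full_fitness(const Pop& pop, const Indiv& ind) {
  double w = pop.fixed_load * ind.segw;
  if (w < 0.0) w = 0.0;
  if (w > 1.0) w = 1.0;
  return w;
}

// ---------------------------------------------------------------------------
// gamete formation

// One gamete from a parent: per chromosome a random starting haplotype;
// crossovers at inter-gene boundaries with probability `recomb` each,
// sampled as geometric gaps over all within-chromosome adjacencies
// (identical in distribution to independent Bernoulli trials); free
// recombination between chromosomes; no recombination within genes.
//
// Each parental haplotype is filtered independently against the crossover
// mosaic (a mutation is transmitted iff the active source at its gene
// matches its haplotype; a homozygous mutation is on both haplotypes, so
// exactly one filter passes it), then the two sorted survivor lists are
// merged. The filters are branchless (unconditional store, conditional
// index bump) and roll through chromosomes by bp comparison.
static void make_gamete(const Pop& pop, const Indiv& parent,
                        std::vector<Entry>& out) {
  const Params& par = pop.par;
  out.clear();
  if (parent.l1 == 0 && parent.l2 == 0) return;

  // starting haplotype bit per chromosome, packed 30 bits per uniform
  // draw and extracted on demand
  uint32_t bitw[3] = {0, 0, 0};
  for (int c = 0, k = 0; c < par.n_chrom; c += 30, ++k)
    bitw[k] = (uint32_t)(unif_rand() * 1073741824.0);  // 2^30
  auto start_bit = [&](int c) -> int {
    return (bitw[c / 30] >> (c % 30)) & 1u;
  };

  // crossover switch points as global bp thresholds (pos > sw_bp flips),
  // sampled as geometric gaps over all within-chromosome adjacencies --
  // identical in distribution to independent Bernoulli(recomb) trials
  static std::vector<int> sw;
  sw.clear();
  int n_adj = par.adj_cum[par.n_chrom];
  if (par.recomb > 0.0 && n_adj > 0) {
    long slot = -1;
    for (;;) {
      double u = unif_rand();
      if (u <= 0.0) break;
      slot += 1 + (long)(std::log(u) / par.log1m_recomb);
      if (slot >= n_adj || slot < 0) break;
      int c = (int)(std::upper_bound(par.adj_cum.begin() + 1,
                                     par.adj_cum.end(), (int)slot)
                    - par.adj_cum.begin()) - 1;
      int g = par.chrom_cum[c] + ((int)slot - par.adj_cum[c]);
      sw.push_back((g + 1) * par.gene_len);  // flip for pos > (g+1)*L
    }
  }
  sw.push_back(INT32_MAX);  // sentinel

  static std::vector<Entry> tmp1, tmp2;  // grow-only scratch
  auto filter = [&](const Entry* h, uint32_t len, int want,
                    std::vector<Entry>& dst) -> size_t {
    if (dst.size() < len) dst.resize(len);
    Entry* o = dst.data();
    size_t k = 0, sw_ptr = 0;
    int c = -1, cur_end = 0, parity = 0, bit = 0;
    for (uint32_t i = 0; i < len; ++i) {
      const Entry e = h[i];
      const int pos = key_pos(e.key);
      if (pos > cur_end) {
        do { ++c; } while (pos > par.chrom_end_bp[c]);
        cur_end = par.chrom_end_bp[c];
        const int start_bp = c > 0 ? par.chrom_end_bp[c - 1] : 0;
        while (sw[sw_ptr] <= start_bp) ++sw_ptr;
        parity = 0;
        bit = start_bit(c);
      }
      while (sw[sw_ptr] < pos && sw[sw_ptr] < cur_end) { ++sw_ptr; parity ^= 1; }
      o[k] = e;
      k += ((bit ^ parity) == want);
    }
    return k;
  };
  size_t n1 = filter(hap1(pop, parent), parent.l1, 0, tmp1);
  size_t n2 = filter(hap2(pop, parent), parent.l2, 1, tmp2);
  out.resize(n1 + n2);
  std::merge(tmp1.begin(), tmp1.begin() + n1, tmp2.begin(), tmp2.begin() + n2,
             out.begin());
}

// Poisson draw by inverse transform for the small per-gamete mutation
// rates used here (falls back to R's sampler for large rates)
static inline int rpois_small(double lambda, double exp_neg_lambda) {
  if (lambda > 30.0) return (int)R::rpois(lambda);
  double u = unif_rand();
  if (u < exp_neg_lambda) return 0;
  int k = 0;
  double p = exp_neg_lambda, F = p;
  while (u > F && k < 1000) {
    ++k;
    p *= lambda / k;
    F += p;
  }
  return k;
}

static void mutate_gamete_vec(Pop& pop, std::vector<Entry>& hap) {
  const Params& par = pop.par;
  if (par.mu_lambda <= 0.0) return;
  int n_new = rpois_small(par.mu_lambda, par.exp_neg_lambda);
  if (n_new == 0) return;
  MutTable& t = *pop.tab;
  for (int k = 0; k < n_new; ++k) {
    int pos = 1 + (int)(unif_rand() * par.total_bp);
    if (pos > (int)par.total_bp) pos = (int)par.total_bp;
    double s = draw_s(par);
    double h = dominance_of(par, s);
    int id = t.add(pos, gene_of(par, pos), s, h, pop.generation);
    hap.push_back(Entry{make_key(pos, id), (float)(1.0 + h * s),
                        (float)(1.0 + s)});
  }
  std::sort(hap.begin(), hap.end());
}

// ---------------------------------------------------------------------------
// generation phases

static void append_span(Pop& pop, const std::vector<Entry>& v,
                        uint32_t& off, uint32_t& len) {
  off = (uint32_t)pop.pool.size();
  len = (uint32_t)v.size();
  pop.pool.insert(pop.pool.end(), v.begin(), v.end());
}

static void phase_reproduce(Pop& pop) {
  int n = (int)pop.inds.size();
  if (n < 2) return;
  // mate for each focal individual: uniform over the others (no selfing)
  static std::vector<int> mates;
  mates.resize(n);
  for (int i = 0; i < n; ++i) {
    int j = (int)(unif_rand() * (n - 1));
    if (j >= n - 1) j = n - 2;
    if (j >= i) ++j;  // exclude self
    mates[i] = j;
  }
  pop.inds.reserve(2 * (size_t)n);
  pop.pool.reserve(2 * pop.pool.size() + 64);
  static std::vector<Entry> gam1, gam2;
  for (int i = 0; i < n; ++i) {
    Indiv kid;
    kid.id = pop.next_id++;
    kid.age = 0;
    make_gamete(pop, pop.inds[i], gam1);
    mutate_gamete_vec(pop, gam1);
    make_gamete(pop, pop.inds[mates[i]], gam2);
    mutate_gamete_vec(pop, gam2);
    kid.segw = seg_fitness_spans(gam1.data(), gam1.size(),
                                 gam2.data(), gam2.size());
    append_span(pop, gam1, kid.o1, kid.l1);
    append_span(pop, gam2, kid.o2, kid.l2);
    pop.inds.push_back(kid);  // parents stay at [0, n)
  }
}

static void phase_catastrophe(Pop& pop, double p) {
  if (p <= 0.0 || pop.inds.empty()) return;
  size_t keep = 0;
  for (size_t i = 0; i < pop.inds.size(); ++i)
    if (unif_rand() >= p) pop.inds[keep++] = pop.inds[i];
  pop.inds.resize(keep);
}

// keys homozygous in one individual (present on both haplotypes)
static void hom_set(const Pop& pop, const Indiv& ind, std::vector<mkey>& out) {
  out.clear();
  const Entry* a = hap1(pop, ind);
  const Entry* b = hap2(pop, ind);
  uint32_t i = 0, j = 0;
  while (i < ind.l1 && j < ind.l2) {
    if (a[i].key == b[j].key) { out.push_back(a[i].key); ++i; ++j; }
    else if (a[i].key < b[j].key) ++i;
    else ++j;
  }
}

static void phase_prune_fixed(Pop& pop) {
  if (pop.inds.empty()) return;
  std::vector<mkey> cand, tmp, isect;
  hom_set(pop, pop.inds[0], cand);
  for (size_t k = 1; k < pop.inds.size() && !cand.empty(); ++k) {
    hom_set(pop, pop.inds[k], tmp);
    isect.clear();
    std::set_intersection(cand.begin(), cand.end(), tmp.begin(), tmp.end(),
                          std::back_inserter(isect));
    cand.swap(isect);
  }
  if (cand.empty()) return;
  const MutTable& t = *pop.tab;
  for (auto& ind : pop.inds) {
    auto drop = [&](uint32_t off, uint32_t& len) {
      Entry* h = pop.pool.data() + off;
      Entry* e = std::remove_if(h, h + len, [&](const Entry& x) {
        return std::binary_search(cand.begin(), cand.end(), x.key);
      });
      len = (uint32_t)(e - h);
    };
    drop(ind.o1, ind.l1);
    drop(ind.o2, ind.l2);
  }
  // fixed_load gains exactly what each cached genotype product loses, so
  // pruning never changes any individual's fitness
  double factor = 1.0;
  for (mkey k : cand) {
    pop.fixed_load *= (1.0 + t.s[key_id(k)]);
    factor *= (1.0 + t.s[key_id(k)]);
  }
  if (pop.fixed_load < 0.0) pop.fixed_load = 0.0;
  if (factor > 1e-12) {
    for (auto& ind : pop.inds) ind.segw /= factor;
  } else {
    for (auto& ind : pop.inds) ind.segw = seg_fitness(pop, ind);
  }
}

static void phase_viability(Pop& pop, int n_ref) {
  if (pop.inds.empty()) return;
  if (n_ref < 1) n_ref = (int)pop.inds.size();
  double scale = (double)pop.K_cur / (double)n_ref;
  size_t keep = 0;
  for (size_t i = 0; i < pop.inds.size(); ++i) {
    double p = full_fitness(pop, pop.inds[i]) * scale;
    if (p > 1.0) p = 1.0;
    if (unif_rand() < p) {
      pop.inds[i].age += 1;
      pop.inds[keep++] = pop.inds[i];
    }
  }
  pop.inds.resize(keep);
}

// ---------------------------------------------------------------------------
// exported interface

// [[Rcpp::export(name = ".eng_new")]]
SEXP eng_new(List params, int n_founders, int K) {
  Pop* pop = new Pop();
  pop->tab = std::make_shared<MutTable>();
  pop->par = params_from_list(params);
  pop->K_base = pop->K_cur = K;
  for (int i = 0; i < n_founders; ++i) {
    Indiv ind;
    ind.id = pop->next_id++;
    ind.age = 0;
    ind.segw = 1.0;
    ind.o1 = ind.l1 = ind.o2 = ind.l2 = 0;
    pop->inds.push_back(ind);
  }
  return PopPtr(pop, true);
}

// [[Rcpp::export(name = ".eng_clone")]]
SEXP eng_clone(SEXP xp) {
  PopPtr p(xp);
  Pop* q = new Pop(*p);  // deep copy of arena/spans, shared mutation table
  return PopPtr(q, true);
}

// [[Rcpp::export(name = ".eng_size")]]
int eng_size(SEXP xp) { return (int)PopPtr(xp)->inds.size(); }

// [[Rcpp::export(name = ".eng_generation")]]
int eng_generation(SEXP xp) { return PopPtr(xp)->generation; }

// [[Rcpp::export(name = ".eng_set_generation")]]
void eng_set_generation(SEXP xp, int g) { PopPtr(xp)->generation = g; }

// [[Rcpp::export(name = ".eng_K")]]
int eng_K(SEXP xp) { return PopPtr(xp)->K_cur; }

// [[Rcpp::export(name = ".eng_set_K")]]
void eng_set_K(SEXP xp, int K) { PopPtr p(xp); p->K_base = p->K_cur = K; }

// [[Rcpp::export(name = ".eng_fixed_load")]]
double eng_fixed_load(SEXP xp) { return PopPtr(xp)->fixed_load; }

// [[Rcpp::export(name = ".eng_set_fixed_load")]]
void eng_set_fixed_load(SEXP xp, double fl) { PopPtr(xp)->fixed_load = fl; }

// [[Rcpp::export(name = ".eng_table_size")]]
int eng_table_size(SEXP xp) { return PopPtr(xp)->tab->size(); }

// [[Rcpp::export(name = ".eng_ids")]]
IntegerVector eng_ids(SEXP xp) {
  PopPtr p(xp);
  IntegerVector out(p->inds.size());
  for (size_t i = 0; i < p->inds.size(); ++i) out[i] = p->inds[i].id;
  return out;
}

// [[Rcpp::export(name = ".eng_ages")]]
IntegerVector eng_ages(SEXP xp) {
  PopPtr p(xp);
  IntegerVector out(p->inds.size());
  for (size_t i = 0; i < p->inds.size(); ++i) out[i] = p->inds[i].age;
  return out;
}

// keep individuals at the given 1-based indices (in the given order)
// [[Rcpp::export(name = ".eng_subset")]]
void eng_subset(SEXP xp, IntegerVector keep) {
  PopPtr p(xp);
  std::vector<Indiv> out;
  out.reserve(keep.size());
  for (int k : keep) {
    if (k < 1 || k > (int)p->inds.size()) stop("individual index out of range");
    out.push_back(p->inds[k - 1]);
  }
  p->inds.swap(out);
  compact(*p);
}

// copy individuals between populations sharing one mutation table
// [[Rcpp::export(name = ".eng_transfer")]]
void eng_transfer(SEXP from, SEXP to, IntegerVector idx) {
  PopPtr a(from), b(to);
  if (a->tab.get() != b->tab.get())
    stop("populations do not share a mutation table (not from the same replicate)");
  for (int k : idx) {
    if (k < 1 || k > (int)a->inds.size()) stop("individual index out of range");
    const Indiv& src = a->inds[k - 1];
    Indiv m;
    m.id = b->next_id++;
    m.age = 0;
    m.segw = src.segw;
    m.o1 = (uint32_t)b->pool.size(); m.l1 = src.l1;
    b->pool.insert(b->pool.end(), hap1(*a, src), hap1(*a, src) + src.l1);
    m.o2 = (uint32_t)b->pool.size(); m.l2 = src.l2;
    b->pool.insert(b->pool.end(), hap2(*a, src), hap2(*a, src) + src.l2);
    b->inds.push_back(m);
  }
}

// [[Rcpp::export(name = ".eng_reproduce")]]
void eng_reproduce(SEXP xp) { phase_reproduce(*PopPtr(xp)); }

// [[Rcpp::export(name = ".eng_catastrophe")]]
void eng_catastrophe(SEXP xp, double p) {
  PopPtr q(xp);
  phase_catastrophe(*q, p);
  compact(*q);
}

// [[Rcpp::export(name = ".eng_prune_fixed")]]
void eng_prune_fixed(SEXP xp) { phase_prune_fixed(*PopPtr(xp)); }

// [[Rcpp::export(name = ".eng_viability")]]
void eng_viability(SEXP xp, int n_ref) {
  PopPtr q(xp);
  phase_viability(*q, n_ref);
  compact(*q);
}

// one full generation: K update, reproduction, catastrophe, fixation
// pruning, viability selection (density ratio uses the post-reproduction
// count). Returns the surviving population size.
// [[Rcpp::export(name = ".eng_step")]]
int eng_step(SEXP xp, int K_next, double p_cat) {
  PopPtr p(xp);
  p->K_cur = K_next;
  if ((int)p->inds.size() >= 2) phase_reproduce(*p);
  int n_ref = (int)p->inds.size();
  phase_catastrophe(*p, p_cat);
  phase_prune_fixed(*p);
  phase_viability(*p, n_ref);
  compact(*p);
  p->generation += 1;
  return (int)p->inds.size();
}

// [[Rcpp::export(name = ".eng_fitness")]]
NumericVector eng_fitness(SEXP xp) {
  PopPtr p(xp);
  NumericVector out(p->inds.size());
  for (size_t i = 0; i < p->inds.size(); ++i)
    out[i] = full_fitness(*p, p->inds[i]);
  return out;
}

// [[Rcpp::export(name = ".eng_gamete")]]
IntegerVector eng_gamete(SEXP xp, int ind_idx) {
  PopPtr p(xp);
  if (ind_idx < 1 || ind_idx > (int)p->inds.size())
    stop("individual index out of range");
  std::vector<Entry> out;
  make_gamete(*p, p->inds[ind_idx - 1], out);
  IntegerVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = key_id(out[i].key) + 1;
  return res;
}

// [[Rcpp::export(name = ".eng_mutate_gamete")]]
IntegerVector eng_mutate_gamete(SEXP xp, IntegerVector hap) {
  PopPtr p(xp);
  const MutTable& t = *p->tab;
  std::vector<Entry> v;
  v.reserve(hap.size());
  for (int id1 : hap) {
    if (id1 < 1 || id1 > t.size()) stop("unknown mutation id");
    double s = t.s[id1 - 1], h = t.h[id1 - 1];
    v.push_back(Entry{make_key(t.pos[id1 - 1], id1 - 1),
                      (float)(1.0 + h * s), (float)(1.0 + s)});
  }
  std::sort(v.begin(), v.end());
  mutate_gamete_vec(*p, v);
  IntegerVector res(v.size());
  for (size_t i = 0; i < v.size(); ++i) res[i] = key_id(v[i].key) + 1;
  return res;
}

// [[Rcpp::export(name = ".eng_draw_s")]]
NumericVector eng_draw_s(List params, int n) {
  Params par = params_from_list(params);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = draw_s(par);
  return out;
}

// [[Rcpp::export(name = ".eng_assign_h")]]
NumericVector eng_assign_h(List params, NumericVector s) {
  Params par = params_from_list(params);
  NumericVector out(s.size());
  for (int i = 0; i < (int)s.size(); ++i) {
    if (s[i] > 0.0 || s[i] < -1.0) stop("s must lie in [-1, 0]");
    out[i] = dominance_of(par, s[i]);
  }
  return out;
}

// [[Rcpp::export(name = ".eng_mutation_table")]]
DataFrame eng_mutation_table(SEXP xp) {
  PopPtr p(xp);
  const MutTable& t = *p->tab;
  int n = t.size();
  IntegerVector id(n), pos(n), gene(n), chrom(n), origin(n);
  NumericVector s(n), h(n);
  for (int i = 0; i < n; ++i) {
    id[i] = i + 1; pos[i] = t.pos[i]; gene[i] = t.gene[i] + 1;
    chrom[i] = chrom_of(p->par, t.gene[i]) + 1;
    s[i] = t.s[i]; h[i] = t.h[i]; origin[i] = t.origin[i];
  }
  return DataFrame::create(_["id"] = id, _["chrom"] = chrom, _["gene"] = gene,
                           _["pos"] = pos, _["s"] = s, _["h"] = h,
                           _["origin_generation"] = origin);
}

// [[Rcpp::export(name = ".eng_genotypes")]]
List eng_genotypes(SEXP xp) {
  PopPtr p(xp);
  List out(p->inds.size());
  for (size_t i = 0; i < p->inds.size(); ++i) {
    const Indiv& ind = p->inds[i];
    const Entry* a = hap1(*p, ind);
    const Entry* b = hap2(*p, ind);
    IntegerVector va(ind.l1), vb(ind.l2);
    for (uint32_t k = 0; k < ind.l1; ++k) va[k] = key_id(a[k].key) + 1;
    for (uint32_t k = 0; k < ind.l2; ++k) vb[k] = key_id(b[k].key) + 1;
    out[i] = List::create(_["h1"] = va, _["h2"] = vb);
  }
  return out;
}

// build a population from explicit genotypes (testing / toy constructions)
// [[Rcpp::export(name = ".eng_from_genotypes")]]
SEXP eng_from_genotypes(List params, List genotypes, DataFrame muts,
                        double fixed_load, int K) {
  Pop* pop = new Pop();
  pop->tab = std::make_shared<MutTable>();
  pop->par = params_from_list(params);
  pop->K_base = pop->K_cur = K;
  pop->fixed_load = fixed_load;
  IntegerVector pos = muts["pos"];
  NumericVector s = muts["s"], h = muts["h"];
  for (int i = 0; i < (int)pos.size(); ++i) {
    if (pos[i] < 1 || pos[i] > (int)pop->par.total_bp) {
      delete pop;
      stop("mutation position outside the coding genome");
    }
    pop->tab->add(pos[i], gene_of(pop->par, pos[i]), s[i], h[i], 0);
  }
  std::vector<Entry> buf;
  for (int i = 0; i < (int)genotypes.size(); ++i) {
    List g = genotypes[i];
    IntegerVector a = g["h1"], b = g["h2"];
    Indiv ind;
    ind.id = pop->next_id++;
    ind.age = 0;
    bool bad = false;
    auto load = [&](IntegerVector ids, uint32_t& off, uint32_t& len) {
      buf.clear();
      for (int k : ids) {
        if (k < 1 || k > pop->tab->size()) { bad = true; return; }
        double sv = pop->tab->s[k - 1], hv = pop->tab->h[k - 1];
        buf.push_back(Entry{make_key(pop->tab->pos[k - 1], k - 1),
                            (float)(1.0 + hv * sv), (float)(1.0 + sv)});
      }
      std::sort(buf.begin(), buf.end());
      off = (uint32_t)pop->pool.size();
      len = (uint32_t)buf.size();
      pop->pool.insert(pop->pool.end(), buf.begin(), buf.end());
    };
    load(a, ind.o1, ind.l1);
    if (!bad) load(b, ind.o2, ind.l2);
    if (bad) { delete pop; stop("unknown mutation id"); }
    ind.segw = seg_fitness(*pop, ind);
    pop->inds.push_back(ind);
  }
  return PopPtr(pop, true);
}

// ---------------------------------------------------------------------------
// summary statistics

static int het_count(const Pop& pop, const Indiv& ind) {
  const Entry* a = hap1(pop, ind);
  const Entry* b = hap2(pop, ind);
  uint32_t i = 0, j = 0;
  int het = 0;
  while (i < ind.l1 || j < ind.l2) {
    if (i < ind.l1 && j < ind.l2 && a[i].key == b[j].key) { ++i; ++j; }
    else if (j == ind.l2 || (i < ind.l1 && a[i].key < b[j].key)) { ++het; ++i; }
    else { ++het; ++j; }
  }
  return het;
}

// F_ROH for one individual: heterozygous sites partition each chromosome's
// coding coordinate into homozygous segments (bounded by chromosome ends);
// F_ROH = sum of segment lengths strictly greater than min_len / total bp.
static double froh_of(const Pop& pop, const Indiv& ind, double min_len) {
  const Params& par = pop.par;
  std::vector<int> hets;
  const Entry* a = hap1(pop, ind);
  const Entry* b = hap2(pop, ind);
  uint32_t i = 0, j = 0;
  while (i < ind.l1 || j < ind.l2) {
    if (i < ind.l1 && j < ind.l2 && a[i].key == b[j].key) { ++i; ++j; }
    else if (j == ind.l2 || (i < ind.l1 && a[i].key < b[j].key)) {
      hets.push_back(key_pos(a[i].key)); ++i;
    } else {
      hets.push_back(key_pos(b[j].key)); ++j;
    }
  }
  double roh = 0.0;
  size_t k = 0;
  for (int c = 0; c < par.n_chrom; ++c) {
    double cs = (double)par.chrom_cum[c] * par.gene_len;       // global start
    double ce = (double)par.chrom_cum[c + 1] * par.gene_len;   // global end
    double prev = cs;
    while (k < hets.size() && hets[k] <= ce) {
      double len = hets[k] - prev;
      if (len > min_len) roh += len;
      prev = hets[k];
      ++k;
    }
    double len = ce - prev;
    if (len > min_len) roh += len;
  }
  return roh / par.total_bp;
}

// [[Rcpp::export(name = ".eng_froh")]]
NumericVector eng_froh(SEXP xp, IntegerVector idx, double min_len) {
  PopPtr p(xp);
  NumericVector out(idx.size());
  for (int i = 0; i < (int)idx.size(); ++i) {
    if (idx[i] < 1 || idx[i] > (int)p->inds.size())
      stop("individual index out of range");
    out[i] = froh_of(*p, p->inds[idx[i] - 1], min_len);
  }
  return out;
}

// [[Rcpp::export(name = ".eng_het_counts")]]
IntegerVector eng_het_counts(SEXP xp, IntegerVector idx) {
  PopPtr p(xp);
  IntegerVector out(idx.size());
  for (int i = 0; i < (int)idx.size(); ++i) {
    if (idx[i] < 1 || idx[i] > (int)p->inds.size())
      stop("individual index out of range");
    out[i] = het_count(*p, p->inds[idx[i] - 1]);
  }
  return out;
}

// deleterious allele copies per sampled individual in the four s-classes:
// weak (-0.001 < s <= -0.00001), moderate (-0.01 < s <= -0.001),
// strong (s < -0.01), very strong (s < -0.05); strong contains very strong.
// [[Rcpp::export(name = ".eng_del_counts")]]
NumericMatrix eng_del_counts(SEXP xp, IntegerVector idx) {
  PopPtr p(xp);
  const MutTable& t = *p->tab;
  NumericMatrix out(idx.size(), 4);
  for (int i = 0; i < (int)idx.size(); ++i) {
    if (idx[i] < 1 || idx[i] > (int)p->inds.size())
      stop("individual index out of range");
    const Indiv& ind = p->inds[idx[i] - 1];
    double cnt[4] = {0, 0, 0, 0};
    auto tally = [&](const Entry& e, double copies) {
      double s = t.s[key_id(e.key)];
      if (s > -0.001 && s <= -0.00001) cnt[0] += copies;
      else if (s > -0.01 && s <= -0.001) cnt[1] += copies;
      if (s < -0.01) cnt[2] += copies;
      if (s < -0.05) cnt[3] += copies;
    };
    const Entry* a = hap1(*p, ind);
    const Entry* b = hap2(*p, ind);
    uint32_t ii = 0, jj = 0;
    while (ii < ind.l1 || jj < ind.l2) {
      if (ii < ind.l1 && jj < ind.l2 && a[ii].key == b[jj].key) {
        tally(a[ii], 2.0); ++ii; ++jj;
      } else if (jj == ind.l2 || (ii < ind.l1 && a[ii].key < b[jj].key)) {
        tally(a[ii], 1.0); ++ii;
      } else {
        tally(b[jj], 1.0); ++jj;
      }
    }
    for (int k = 0; k < 4; ++k) out(i, k) = cnt[k];
  }
  colnames(out) = CharacterVector::create("n_weak", "n_moderate",
                                          "n_strong", "n_very_strong");
  return out;
}

// per-individual metrics used for migrant screening
// [[Rcpp::export(name = ".eng_individual_metrics")]]
DataFrame eng_individual_metrics(SEXP xp) {
  PopPtr p(xp);
  const MutTable& t = *p->tab;
  int n = (int)p->inds.size();
  IntegerVector id(n), age(n), het(n), strong(n);
  NumericVector w(n);
  for (int i = 0; i < n; ++i) {
    const Indiv& ind = p->inds[i];
    id[i] = ind.id; age[i] = ind.age;
    het[i] = het_count(*p, ind);
    int sc = 0;
    const Entry* a = hap1(*p, ind);
    const Entry* b = hap2(*p, ind);
    uint32_t ii = 0, jj = 0;
    while (ii < ind.l1 || jj < ind.l2) {
      if (ii < ind.l1 && jj < ind.l2 && a[ii].key == b[jj].key) {
        if (t.s[key_id(a[ii].key)] < -0.01) sc += 2;
        ++ii; ++jj;
      } else if (jj == ind.l2 || (ii < ind.l1 && a[ii].key < b[jj].key)) {
        if (t.s[key_id(a[ii].key)] < -0.01) sc += 1;
        ++ii;
      } else {
        if (t.s[key_id(b[jj].key)] < -0.01) sc += 1;
        ++jj;
      }
    }
    strong[i] = sc;
    w[i] = full_fitness(*p, ind);
  }
  return DataFrame::create(_["id"] = id, _["age"] = age, _["n_het"] = het,
                           _["n_strong_alleles"] = strong, _["fitness"] = w);
}

// seed mixing: injective in the replicate index for a fixed master seed
// [[Rcpp::export(name = ".eng_mix_seed")]]
int eng_mix_seed(double master, double index) {
  uint64_t m = (uint64_t)((int64_t)master & 0x7fffffffLL);
  uint64_t i = (uint64_t)index;
  uint64_t v = (m + i * 507060273ULL) & 0x7fffffffULL;  // mod 2^31
  if (v == 0) v = 1;
  return (int)v;
}
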