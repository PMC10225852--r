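// Forward-time diploid two-population Wright-Fisher simulator.
//
// Genomes are sparse sets of derived-mutation ids per haplotype, kept sorted
// by (position, id). Three mutation classes: neutral, recessive deleterious
// (gamma DFE on s), and QTLs with additive N(0, sd^2) phenotypic effects under
// Gaussian stabilizing selection. Demography: constant-size burn-in of a
// single ancestral population, split into two subpopulations that grow to a
// final size, with symmetric per-offspring migration after the split.
//
// All randomness goes through R's RNG so set.seed() on the R side gives
// bit-reproducible runs.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

typedef std::vector<int> Hap; // mutation ids, sorted by (pos, id)

// global-per-call mutation registry
struct Registry {
  std::vector<int> pos;        // 0-based base position
  std::vector<int> type;       // 0 neutral, 1 deleterious, 2 qtl
  std::vector<double> coeff;   // s (deleterious), beta (qtl), 0 (neutral)
  std::vector<int> origin_gen; // absolute generation (1-based)
  std::vector<int> origin_pop; // 0 ancestral, 1 subpop1, 2 subpop2
  std::vector<char> fixed;     // pruned as fixed in the whole (meta)population
  int n() const { return (int)pos.size(); }
};

struct Model {
  bool three_type;
  double p_del, p_qtl;         // P(deleterious), P(qtl); neutral = remainder
  double del_shape, del_scale; // gamma on |s| (already rescaled)
  double dominance;            // h for deleterious heterozygotes
  double qtl_sd;
  double optimum, omega;       // Gaussian stabilizing selection
};

static inline bool mut_less(const Registry& reg, int a, int b) {
  if (reg.pos[a] != reg.pos[b]) return reg.pos[a] < reg.pos[b];
  return a < b;
}

// one recombinant gamete from a diploid parent, plus new mutations
static void make_gamete(const Hap& A, const Hap& B, Registry& reg,
                        double L, double r, double mu, const Model& mod,
                        bool has_model, int gen, int pop, Hap& out) {
  out.clear();
  int nco = (int)R::rpois(L * r);
  if (nco == 0) {
    out = (unif_rand() < 0.5) ? A : B;
  } else {
    std::vector<double> cx(nco);
    for (int i = 0; i < nco; ++i) cx[i] = unif_rand() * L;
    std::sort(cx.begin(), cx.end());
    cx.push_back(L + 1.0); // sentinel closing the last segment
    const Hap* cur = (unif_rand() < 0.5) ? &A : &B;
    const Hap* oth = (cur == &A) ? &B : &A;
    size_t ia = 0, ib = 0; // pointers into *cur and *oth
    for (size_t k = 0; k < cx.size(); ++k) {
      double bound = cx[k];
      while (ia < cur->size() && reg.pos[(*cur)[ia]] < bound)
        out.push_back((*cur)[ia++]);
      while (ib < oth->size() && reg.pos[(*oth)[ib]] < bound) ++ib;
      std::swap(cur, oth);
      std::swap(ia, ib);
    }
  }
  int nm = (int)R::rpois(L * mu);
  for (int i = 0; i < nm; ++i) {
    int p = (int)std::floor(unif_rand() * L);
    if (p >= (int)L) p = (int)L - 1;
    int type = 0; double coeff = 0.0;
    if (has_model && mod.three_type) {
      double u = unif_rand();
      if (u < mod.p_del) {
        type = 1;
        coeff = -R::rgamma(mod.del_shape, mod.del_scale);
      } else if (u < mod.p_del + mod.p_qtl) {
        type = 2;
        coeff = R::rnorm(0.0, mod.qtl_sd);
      }
    }
    int id = reg.n();
    reg.pos.push_back(p);
    reg.type.push_back(type);
    reg.coeff.push_back(coeff);
    reg.origin_gen.push_back(gen);
    reg.origin_pop.push_back(pop);
    reg.fixed.push_back(0);
    // insert keeping (pos, id) order; id is larger than any existing id
    Hap::iterator it = std::lower_bound(
        out.begin(), out.end(), id,
        [&reg](int a, int b) { return mut_less(reg, a, b); });
    out.insert(it, id);
  }
}

// multiplicative fitness of one diploid; z_fixed carries phenotype
// contributions of globally fixed (pruned) QTLs
static double diploid_fitness(const Hap& A, const Hap& B, const Registry& reg,
                              const Model& mod, double z_fixed) {
  double w = 1.0, z = z_fixed;
  size_t ia = 0, ib = 0;
  while (ia < A.size() || ib < B.size()) {
    int id; int dose;
    if (ib == B.size() || (ia < A.size() && mut_less(reg, A[ia], B[ib]))) {
      id = A[ia++]; dose = 1;
    } else if (ia == A.size() || mut_less(reg, B[ib], A[ia])) {
      id = B[ib++]; dose = 1;
    } else { // A[ia] == B[ib]
      id = A[ia]; ++ia; ++ib; dose = 2;
    }
    if (reg.type[id] == 1) {
      double s = reg.coeff[id];
      double f = (dose == 2) ? (1.0 + s) : (1.0 + mod.dominance * s);
      if (f < 0.0) f = 0.0;
      w *= f;
    } else if (reg.type[id] == 2) {
      z += dose * reg.coeff[id];
    }
  }
  double d = z - mod.optimum;
  w *= std::exp(-(d * d) / (2.0 * mod.omega * mod.omega));
  return (w > 0.0) ? w : 0.0;
}

// weighted index draw from cumulative weights
static int draw_parent(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
}

struct Pop { std::vector<Hap> hap; int n() const { return (int)hap.size() / 2; } };

// remove globally fixed mutations from all haplotypes; returns phenotype
// shift contributed by newly fixed QTLs
static double prune_fixed(std::vector<Pop*>& pops, Registry& reg,
                          std::vector<int>& count) {
  long total = 0;
  for (Pop* p : pops) total += (long)p->hap.size();
  std::fill(count.begin(), count.end(), 0);
  count.resize(reg.n(), 0);
  for (Pop* p : pops)
    for (const Hap& h : p->hap)
      for (int id : h) ++count[id];
  std::vector<char> kill(reg.n(), 0);
  bool any = false;
  double dz = 0.0;
  for (int id = 0; id < reg.n(); ++id) {
    if (!reg.fixed[id] && count[id] == (int)total && total > 0) {
      kill[id] = 1; reg.fixed[id] = 1; any = true;
      if (reg.type[id] == 2) dz += 2.0 * reg.coeff[id];
    }
  }
  if (any) {
    for (Pop* p : pops)
      for (Hap& h : p->hap)
        h.erase(std::remove_if(h.begin(), h.end(),
                               [&kill](int id) { return kill[id] != 0; }),
                h.end());
  }
  return dz;
}

// [[Rcpp::export(name = ".run_scenario_cpp")]]
List run_scenario_cpp(List demog, List model, DataFrame cohort_spec) {
  // demography
  int N_anc = as<int>(demog["N_anc"]);
  int T_burn = as<int>(demog["T_burn"]);
  int T_growth = as<int>(demog["T_growth"]);
  int T_post = as<int>(demog["T_post"]); // total post-split generations
  int N_final = as<int>(demog["N_final"]);
  double m = as<double>(demog["m"]);
  double L = as<double>(demog["L"]);
  double r = as<double>(demog["r"]);
  double mu = as<double>(demog["mu"]);
  bool linear_growth = as<bool>(demog["linear_growth"]);
  int prune_every = as<int>(demog["prune_every"]);

  Model mod;
  mod.three_type = as<bool>(model["three_type"]);
  mod.p_del = as<double>(model["p_del"]);
  mod.p_qtl = as<double>(model["p_qtl"]);
  mod.del_shape = as<double>(model["del_shape"]);
  mod.del_scale = as<double>(model["del_scale"]);
  mod.dominance = as<double>(model["dominance"]);
  mod.qtl_sd = as<double>(model["qtl_sd"]);
  mod.optimum = as<double>(model["optimum"]);
  mod.omega = as<double>(model["omega"]);
  bool select = mod.three_type;

  // cohorts: pop (0 ancestral / 1 / 2), time (post-split gen for pops 1-2,
  // absolute burn-in gen for pop 0), n_sample
  IntegerVector co_pop = cohort_spec["pop"];
  IntegerVector co_time = cohort_spec["time"];
  IntegerVector co_n = cohort_spec["n_sample"];
  int n_cohorts = co_pop.size();
  std::vector<std::vector<Hap> > cohort_haps(n_cohorts);

  Registry reg;
  std::vector<int> count;
  double z_fixed = 0.0;

  Pop anc; anc.hap.assign(2 * N_anc, Hap());
  Pop p1, p2;
  bool split_done = false;

  // post-split per-subpopulation size schedule
  double g = (T_growth > 0)
                 ? std::pow((double)N_final / N_anc, 1.0 / T_growth)
                 : 1.0;
  std::vector<int> sched(T_post + 1, N_anc);
  for (int t = 1; t <= T_post; ++t) {
    if (t >= T_growth) sched[t] = N_final;
    else if (linear_growth)
      sched[t] = (int)std::floor(N_anc + (double)(N_final - N_anc) * t / T_growth + 0.5);
    else
      sched[t] = (int)std::floor(N_anc * std::pow(g, t) + 0.5);
    if (sched[t] > N_final) sched[t] = N_final;
    if (sched[t] < 2) sched[t] = 2;
  }
  IntegerMatrix census(std::max(T_post, 0), 2);

  std::vector<double> fit, cum;
  Hap g1, g2;

  // reproduce pool -> two offspring vectors (subpop targets) of given sizes
  // gen: absolute generation of the offspring; pop label for new mutations
  // taken from 'poplab' (pre-migration)
  std::vector<Hap> next1, next2;

  auto reproduce = [&](Pop& pool, int n_off, int gen, int poplab,
                       std::vector<Hap>& out) {
    int np = pool.n();
    if (np < 1) stop("population extinct");
    const bool weighted = select;
    if (weighted) {
      fit.resize(np); cum.resize(np);
      double tot = 0.0;
      for (int i = 0; i < np; ++i) {
        fit[i] = diploid_fitness(pool.hap[2 * i], pool.hap[2 * i + 1], reg,
                                 mod, z_fixed);
        tot += fit[i];
        cum[i] = tot;
      }
      if (tot <= 0.0) stop("all fitnesses zero: population inviable");
    }
    for (int j = 0; j < n_off; ++j) {
      int i1, i2;
      if (weighted) { i1 = draw_parent(cum); i2 = draw_parent(cum); }
      else {
        i1 = (int)(unif_rand() * np); if (i1 >= np) i1 = np - 1;
        i2 = (int)(unif_rand() * np); if (i2 >= np) i2 = np - 1;
      }
      // avoid selfing; give up after a bounded number of redraws (all
      // fitness mass on one parent)
      for (int tries = 0; np > 1 && i2 == i1 && tries < 100; ++tries) {
        i2 = weighted ? draw_parent(cum) : (int)(unif_rand() * np);
        if (i2 >= np) i2 = np - 1;
      }
      make_gamete(pool.hap[2 * i1], pool.hap[2 * i1 + 1], reg, L, r, mu, mod,
                  true, gen, poplab, g1);
      make_gamete(pool.hap[2 * i2], pool.hap[2 * i2 + 1], reg, L, r, mu, mod,
                  true, gen, poplab, g2);
      out.push_back(g1);
      out.push_back(g2);
    }
  };

  auto sample_cohorts = [&](int pop_id, int time_now, Pop& pop) {
    for (int c = 0; c < n_cohorts; ++c) {
      if (co_pop[c] != pop_id || co_time[c] != time_now) continue;
      int ns = co_n[c];
      int np = pop.n();
      if (ns > np) stop("cohort sample larger than population");
      // uniform sample of individuals without replacement
      std::vector<int> idx(np);
      for (int i = 0; i < np; ++i) idx[i] = i;
      for (int i = 0; i < ns; ++i) {
        int j = i + (int)(unif_rand() * (np - i));
        if (j >= np) j = np - 1;
        std::swap(idx[i], idx[j]);
      }
      cohort_haps[c].clear();
      for (int i = 0; i < ns; ++i) {
        cohort_haps[c].push_back(pop.hap[2 * idx[i]]);
        cohort_haps[c].push_back(pop.hap[2 * idx[i] + 1]);
      }
    }
  };

  std::vector<Pop*> live;

  // ---- burn-in ----
  for (int t = 1; t <= T_burn; ++t) {
    next1.clear();
    reproduce(anc, N_anc, t, 0, next1);
    anc.hap.swap(next1);
    if (t % prune_every == 0) {
      live.assign(1, &anc);
      z_fixed += prune_fixed(live, reg, count);
    }
    sample_cohorts(0, t, anc);
    if (t % 200 == 0) Rcpp::checkUserInterrupt();
  }

  // ---- split + growth + sampling epoch ----
  for (int t = 1; t <= T_post; ++t) {
    int target = sched[t];
    next1.clear(); next2.clear();
    if (!split_done) {
      // first post-split generation: both subpopulations drawn from ancestor
      reproduce(anc, target, T_burn + t, 1, next1);
      reproduce(anc, target, T_burn + t, 2, next2);
      split_done = true;
      anc.hap.clear();
    } else {
      reproduce(p1, target, T_burn + t, 1, next1);
      reproduce(p2, target, T_burn + t, 2, next2);
    }
    // migration: each offspring relocates with probability m
    if (m > 0.0) {
      std::vector<Hap> s1, s2;
      s1.reserve(next1.size()); s2.reserve(next2.size());
      for (size_t i = 0; i < next1.size(); i += 2) {
        if (unif_rand() < m) { s2.push_back(next1[i]); s2.push_back(next1[i + 1]); }
        else { s1.push_back(next1[i]); s1.push_back(next1[i + 1]); }
      }
      for (size_t i = 0; i < next2.size(); i += 2) {
        if (unif_rand() < m) { s1.push_back(next2[i]); s1.push_back(next2[i + 1]); }
        else { s2.push_back(next2[i]); s2.push_back(next2[i + 1]); }
      }
      p1.hap.swap(s1); p2.hap.swap(s2);
    } else {
      p1.hap.swap(next1); p2.hap.swap(next2);
    }
    census(t - 1, 0) = p1.n();
    census(t - 1, 1) = p2.n();
    if (t % prune_every == 0) {
      live.clear(); live.push_back(&p1); live.push_back(&p2);
      z_fixed += prune_fixed(live, reg, count);
    }
    sample_cohorts(1, t, p1);
    sample_cohorts(2, t, p2);
    if (t % 50 == 0) Rcpp::checkUserInterrupt();
  }

  // ---- final frequencies over the whole registry ----
  int nmut = reg.n();
  NumericVector f1(nmut), f2(nmut), fpool(nmut);
  {
    std::vector<long> c1(nmut, 0), c2(nmut, 0);
    Pop& q1 = split_done ? p1 : anc;
    for (const Hap& h : q1.hap) for (int id : h) ++c1[id];
    if (split_done) for (const Hap& h : p2.hap) for (int id : h) ++c2[id];
    double n1 = (double)q1.hap.size();
    double n2 = split_done ? (double)p2.hap.size() : 0.0;
    for (int id = 0; id < nmut; ++id) {
      if (reg.fixed[id]) { f1[id] = 1.0; f2[id] = split_done ? 1.0 : NA_REAL; fpool[id] = 1.0; }
      else {
        f1[id] = (n1 > 0) ? c1[id] / n1 : NA_REAL;
        f2[id] = split_done ? ((n2 > 0) ? c2[id] / n2 : NA_REAL) : NA_REAL;
        fpool[id] = (n1 + n2 > 0) ? (c1[id] + c2[id]) / (n1 + n2) : NA_REAL;
      }
    }
  }

  // ---- cohort genotype matrices over each cohort's segregating ids ----
  List cohorts(n_cohorts);
  for (int c = 0; c < n_cohorts; ++c) {
    std::vector<Hap>& hs = cohort_haps[c];
    if (hs.empty()) stop("cohort %d was never sampled (check its time)", c + 1);
    std::vector<int> ids;
    for (const Hap& h : hs) ids.insert(ids.end(), h.begin(), h.end());
    std::sort(ids.begin(), ids.end());
    ids.erase(std::unique(ids.begin(), ids.end()), ids.end());
    // order loci by (pos, id)
    std::sort(ids.begin(), ids.end(),
              [&reg](int a, int b) { return mut_less(reg, a, b); });
    std::vector<int> rank(nmut, -1);
    for (size_t k = 0; k < ids.size(); ++k) rank[ids[k]] = (int)k;
    int ni = (int)hs.size() / 2;
    IntegerMatrix dose((int)ids.size(), ni);
    for (int i = 0; i < ni; ++i)
      for (int hh = 0; hh < 2; ++hh)
        for (int id : hs[2 * i + hh]) dose(rank[id], i) += 1;
    IntegerVector idv(ids.size());
    for (size_t k = 0; k < ids.size(); ++k) idv[k] = ids[k] + 1; // 1-based
    cohorts[c] = List::create(_["mut_id"] = idv, _["dosage"] = dose);
  }

  IntegerVector rid(nmut), rpos(nmut), rtype(nmut), rgen(nmut), rpop(nmut);
  LogicalVector rfix(nmut);
  NumericVector rcoef(nmut);
  for (int id = 0; id < nmut; ++id) {
    rid[id] = id + 1; rpos[id] = reg.pos[id]; rtype[id] = reg.type[id];
    rcoef[id] = reg.coeff[id]; rgen[id] = reg.origin_gen[id];
    rpop[id] = reg.origin_pop[id]; rfix[id] = reg.fixed[id] != 0;
  }
  DataFrame registry = DataFrame::create(
      _["mut_id"] = rid, _["pos"] = rpos, _["type"] = rtype,
      _["coeff"] = rcoef, _["origin_gen"] = rgen, _["origin_pop"] = rpop,
      _["fixed"] = rfix, _["freq_pop1"] = f1, _["freq_pop2"] = f2,
      _["freq_pooled"] = fpool);

  return List::create(_["registry"] = registry, _["cohorts"] = cohorts,
                      _["census"] = census, _["split_done"] = split_done,
                      _["z_fixed"] = z_fixed);
}
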