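// Hot inner loops of the individual-based simulation: Mendelian transmission
// of founder alleles and allele-sharing kinship/diversity estimators.
//
// Allele matrices are stored loci x slots (an individual's genotype is one
// contiguous column). All randomness uses R's RNG stream, so results are
// reproducible via set.seed(); one uniform draw supplies 32 segregation bits.

#include <Rcpp.h>
using namespace Rcpp;

static inline uint32_t rand_bits32() {
  return (uint32_t)(unif_rand() * 4294967296.0);
}

// Drop founder alleles through a whole pedigree (rows ordered parents before
// offspring; parent index 0 = unknown). Unknown parent sides act as unique
// phantom founders. Returns L x n allele matrices and the label count.
// [[Rcpp::export]]
List cpp_drop_alleles(IntegerVector sire_idx, IntegerVector dam_idx, int L) {
  const int n = sire_idx.size();
  RawMatrix A1(L, n), A2(L, n);
  int lab = 0;
  for (int i = 0; i < n; ++i) {
    const int s = sire_idx[i], d = dam_idx[i];
    Rbyte *a1 = &A1(0, i), *a2 = &A2(0, i);
    if (s == 0) {
      std::fill(a1, a1 + L, (Rbyte)(++lab));
    } else {
      const Rbyte *p1 = &A1(0, s - 1), *p2 = &A2(0, s - 1);
      uint32_t r = 0;
      for (int j = 0; j < L; ++j) {
        if ((j & 31) == 0) r = rand_bits32();
        a1[j] = (r & 1u) ? p1[j] : p2[j];
        r >>= 1;
      }
    }
    if (d == 0) {
      std::fill(a2, a2 + L, (Rbyte)(++lab));
    } else {
      const Rbyte *p1 = &A1(0, d - 1), *p2 = &A2(0, d - 1);
      uint32_t r = 0;
      for (int j = 0; j < L; ++j) {
        if ((j & 31) == 0) r = rand_bits32();
        a2[j] = (r & 1u) ? p1[j] : p2[j];
        r >>= 1;
      }
    }
  }
  return List::create(_["A1"] = A1, _["A2"] = A2, _["n_lab"] = lab);
}

// Write the allele pairs of newborns directly into the state matrices:
// one uniformly random allele from each parent per locus.
// [[Rcpp::export]]
void cpp_inherit_alleles(RawMatrix A1, RawMatrix A2,
                         IntegerVector sires, IntegerVector dams,
                         IntegerVector slots) {
  const int n = slots.size(), L = A1.nrow();
  for (int i = 0; i < n; ++i) {
    const int s = sires[i] - 1, d = dams[i] - 1, t = slots[i] - 1;
    const Rbyte *s1 = &A1(0, s), *s2 = &A2(0, s);
    const Rbyte *d1 = &A1(0, d), *d2 = &A2(0, d);
    Rbyte *t1 = &A1(0, t), *t2 = &A2(0, t);
    uint32_t rs = 0, rd = 0;
    for (int j = 0; j < L; ++j) {
      if ((j & 31) == 0) { rs = rand_bits32(); rd = rand_bits32(); }
      t1[j] = (rs & 1u) ? s1[j] : s2[j];
      t2[j] = (rd & 1u) ? d1[j] : d2[j];
      rs >>= 1; rd >>= 1;
    }
  }
}

// Kinship estimate between paired individuals a[i], b[i]: the fraction of
// identical-by-label allele comparisons across loci (unbiased for the
// pedigree kinship coefficient because founder alleles are uniquely
// labelled).
static inline int pair_matches(const Rbyte *x1, const Rbyte *x2,
                               const Rbyte *y1, const Rbyte *y2, int L) {
  int m = 0;
  for (int j = 0; j < L; ++j) {
    const Rbyte p1 = x1[j], p2 = x2[j], q1 = y1[j], q2 = y2[j];
    m += (p1 == q1) + (p1 == q2) + (p2 == q1) + (p2 == q2);
  }
  return m;
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_pair_kinship(RawMatrix A1, RawMatrix A2,
                               IntegerVector a, IntegerVector b) {
  const int n = a.size(), L = A1.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const int x = a[i] - 1, y = b[i] - 1;
    out[i] = pair_matches(&A1(0, x), &A2(0, x), &A1(0, y), &A2(0, y), L) /
      (4.0 * L);
  }
  return out;
}

// Full pairwise kinship-estimate matrix between two (small) sets of slots.
// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_cross_kinship(RawMatrix A1, RawMatrix A2,
                                IntegerVector rows, IntegerVector cols) {
  const int nr = rows.size(), nc = cols.size(), L = A1.nrow();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    const int y = cols[c] - 1;
    const Rbyte *y1 = &A1(0, y), *y2 = &A2(0, y);
    for (int r = 0; r < nr; ++r) {
      const int x = rows[r] - 1;
      out(r, c) = pair_matches(&A1(0, x), &A2(0, x), y1, y2, L) / (4.0 * L);
    }
  }
  return out;
}

// Mean kinship of each candidate to a reference set, via per-locus allele
// counts of the reference set: O((|set| + |cand|) * L) instead of pairwise.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_mean_kinship_to_set(RawMatrix A1, RawMatrix A2,
                                      IntegerVector cand, IntegerVector set,
                                      int n_lab) {
  const int L = A1.nrow(), ns = set.size(), nc = cand.size();
  std::vector<int> counts((size_t)n_lab * L, 0);
  for (int i = 0; i < ns; ++i) {
    const int x = set[i] - 1;
    const Rbyte *x1 = &A1(0, x), *x2 = &A2(0, x);
    for (int j = 0; j < L; ++j) {
      int *cj = &counts[(size_t)j * n_lab];
      cj[x1[j] - 1]++;
      cj[x2[j] - 1]++;
    }
  }
  NumericVector out(nc);
  for (int i = 0; i < nc; ++i) {
    const int x = cand[i] - 1;
    const Rbyte *x1 = &A1(0, x), *x2 = &A2(0, x);
    long m = 0;
    for (int j = 0; j < L; ++j) {
      const int *cj = &counts[(size_t)j * n_lab];
      m += cj[x1[j] - 1] + cj[x2[j] - 1];
    }
    out[i] = m / (4.0 * L * ns);
  }
  return out;
}

// Gene diversity (1 - expected homozygosity of the pooled alleles, averaged
// over loci) of a set of slots; equals 1 minus the mean kinship of the set
// over ordered pairs including self-pairs, in expectation.
// [[Rcpp::export(rng = false)]]
double cpp_gd(RawMatrix A1, RawMatrix A2, IntegerVector idx,
              int n_lab) {
  const int L = A1.nrow(), n = idx.size();
  if (n == 0) return NA_REAL;
  std::vector<int> counts((size_t)n_lab * L, 0);
  for (int i = 0; i < n; ++i) {
    const int x = idx[i] - 1;
    const Rbyte *x1 = &A1(0, x), *x2 = &A2(0, x);
    for (int j = 0; j < L; ++j) {
      int *cj = &counts[(size_t)j * n_lab];
      cj[x1[j] - 1]++;
      cj[x2[j] - 1]++;
    }
  }
  const double tot = 2.0 * n;
  double acc = 0.0;
  for (int j = 0; j < L; ++j) {
    const int *cj = &counts[(size_t)j * n_lab];
    double ss = 0.0;
    for (int k = 0; k < n_lab; ++k) {
      const double p = cj[k] / tot;
      ss += p * p;
    }
    acc += 1.0 - ss;
  }
  return acc / L;
}

// Indices of living individuals at a location (1 wild, 2 captive).
// [[Rcpp::export(rng = false)]]
IntegerVector cpp_living(LogicalVector alive, IntegerVector loc, int code) {
  const int n = alive.size();
  std::vector<int> out;
  out.reserve(512);
  for (int i = 0; i < n; ++i) {
    if (alive[i] && loc[i] == code) out.push_back(i + 1);
  }
  return wrap(out);
}

// Survival draws for the individuals in w: death probability is the
// adjusted age-class rate (columns of `rates`: female, male; rows: pup,
// yearling, adult) with survival multiplied by `sev`; individuals at or
// beyond max_age die. One uniform draw per individual, in order.
// [[Rcpp::export]]
IntegerVector cpp_mortality_draw(IntegerVector w, IntegerVector age,
                                 IntegerVector sex, NumericMatrix rates,
                                 double sev, int max_age) {
  const int n = w.size();
  std::vector<int> dead;
  for (int i = 0; i < n; ++i) {
    const int x = w[i] - 1;
    const int cls = age[x] >= 2 ? 2 : age[x];
    const double surv = (1.0 - rates(cls, sex[x] - 1)) * sev;
    const bool d = (unif_rand() >= surv) || age[x] >= max_age;
    if (d) dead.push_back(w[i]);
  }
  return wrap(dead);
}

// Random matching of unpaired females to unpaired males with kin exclusion
// (no parent-offspring, no full siblings). Each female scans a random
// permutation of the remaining males and takes the first permissible one.
// Returns the matched male slot per female (0 = none available).
// [[Rcpp::export]]
IntegerVector cpp_match_pairs(IntegerVector fem, IntegerVector mal,
                              IntegerVector sire_id, IntegerVector dam_id,
                              IntegerVector id, bool kin_exclusion) {
  const int nf = fem.size();
  std::vector<int> pool(mal.begin(), mal.end());
  IntegerVector out(nf);
  for (int i = 0; i < nf; ++i) {
    const int f = fem[i] - 1;
    int chosen = 0;
    int avail = (int)pool.size();
    // partial Fisher-Yates: draw without replacement until permissible
    for (int t = 0; t < avail; ++t) {
      const int r = t + (int)(unif_rand() * (avail - t));
      std::swap(pool[t], pool[r]);
      const int m = pool[t] - 1;
      bool forb = false;
      if (kin_exclusion) {
        forb = (sire_id[f] == id[m]) || (dam_id[m] == id[f]) ||
          (sire_id[f] > 0 && dam_id[f] > 0 &&
           sire_id[f] == sire_id[m] && dam_id[f] == dam_id[m]);
      }
      if (!forb) {
        chosen = pool[t];
        pool.erase(pool.begin() + t);
        break;
      }
    }
    out[i] = chosen;
  }
  return out;
}

// Age increment plus wild census: returns (N wild, newly effective releases,
// wild females, wild males) and marks newly effective released individuals.
// [[Rcpp::export(rng = false)]]
IntegerVector cpp_age_census(LogicalVector alive, IntegerVector loc,
                             IntegerVector age, IntegerVector sex,
                             LogicalVector released, LogicalVector rel_counted,
                             int fba) {
  const int n = alive.size();
  int nw = 0, neff = 0, nf = 0, nm = 0;
  for (int i = 0; i < n; ++i) {
    if (!alive[i]) continue;
    age[i] += 1;
    if (loc[i] == 1) {
      ++nw;
      if (sex[i] == 1) ++nf; else ++nm;
      if (released[i] && !rel_counted[i] && age[i] >= fba) {
        rel_counted[i] = true;
        ++neff;
      }
    }
  }
  return IntegerVector::create(nw, neff, nf, nm);
}

// Create newborns: allocates slots from the state's free stack (capacity
// must be ensured by the caller), fills all per-slot fields, draws sexes and
// transmits alleles. Returns the new slots.
// [[Rcpp::export]]
IntegerVector cpp_newborns(Environment st, IntegerVector sires,
                           IntegerVector dams, NumericVector Fi, int loc,
                           double sex_ratio, int year) {
  const int n = sires.size();
  LogicalVector alive = st["alive"], fed = st["fed"],
    released = st["released"], rel_counted = st["rel_counted"];
  IntegerVector locv = st["loc"], sex = st["sex"], age = st["age"],
    id = st["id"], sire_id = st["sire_id"], dam_id = st["dam_id"],
    pair = st["pair"], byear = st["byear"], free_stack = st["free_stack"];
  NumericVector fi = st["Fi"];
  RawMatrix A1 = st["A1"], A2 = st["A2"];
  const int L = A1.nrow();
  int free_top = st["free_top"], next_id = st["next_id"];
  IntegerVector slots(n);
  for (int i = 0; i < n; ++i) {
    const int t = free_stack[free_top - n + i] - 1;
    slots[i] = t + 1;
    const int s = sires[i] - 1, d = dams[i] - 1;
    alive[t] = true;
    locv[t] = loc;
    sex[t] = (unif_rand() < sex_ratio) ? 1 : 2;
    age[t] = 0;
    fi[t] = Fi[i];
    id[t] = next_id++;
    sire_id[t] = id[s];
    dam_id[t] = id[d];
    pair[t] = 0;
    fed[t] = false;
    byear[t] = year;
    released[t] = false;
    rel_counted[t] = false;
    const Rbyte *s1 = &A1(0, s), *s2 = &A2(0, s);
    const Rbyte *d1 = &A1(0, d), *d2 = &A2(0, d);
    Rbyte *t1 = &A1(0, t), *t2 = &A2(0, t);
    uint32_t rs = 0, rd = 0;
    for (int j = 0; j < L; ++j) {
      if ((j & 31) == 0) { rs = rand_bits32(); rd = rand_bits32(); }
      t1[j] = (rs & 1u) ? s1[j] : s2[j];
      t2[j] = (rd & 1u) ? d1[j] : d2[j];
      rs >>= 1; rd >>= 1;
    }
  }
  st["free_top"] = free_top - n;
  st["next_id"] = next_id;
  return slots;
}

// Kill individuals: clears fields, unpairs surviving partners, returns the
// slots to the free stack.
// [[Rcpp::export(rng = false)]]
void cpp_kill(Environment st, IntegerVector slots) {
  const int n = slots.size();
  if (n == 0) return;
  LogicalVector alive = st["alive"], fed = st["fed"];
  IntegerVector locv = st["loc"], pair = st["pair"],
    free_stack = st["free_stack"];
  int free_top = st["free_top"];
  for (int i = 0; i < n; ++i) {
    const int t = slots[i] - 1;
    const int mate = pair[t];
    if (mate > 0) { pair[mate - 1] = 0; fed[mate - 1] = false; }
    alive[t] = false;
    locv[t] = 0;
    pair[t] = 0;
    fed[t] = false;
    free_stack[free_top++] = t + 1;
  }
  st["free_top"] = free_top;
}

// k distinct elements of w, uniformly at random (partial Fisher-Yates).
// [[Rcpp::export]]
IntegerVector cpp_sample_k(IntegerVector w, int k) {
  const int n = w.size();
  if (k > n) k = n;
  std::vector<int> pool(w.begin(), w.end());
  IntegerVector out(k);
  for (int t = 0; t < k; ++t) {
    const int r = t + (int)(unif_rand() * (n - t));
    std::swap(pool[t], pool[r]);
    out[t] = pool[t];
  }
  return out;
}

static inline int rstoch_round_c(double x) {
  const double f = std::floor(x);
  return (int)f + ((unif_rand() < (x - f)) ? 1 : 0);
}

// One year of pair formation: existing pairs persist with probability
// `persistence`; unpaired adult females are then matched to unpaired adult
// males (random matching, kin exclusion) until the target proportion of
// adult females is paired; new pairs draw pack feeding status.
// [[Rcpp::export]]
void cpp_form_pairs(Environment st, double persistence, double rate,
                    double fed_fraction, int fba, bool kin_exclusion) {
  LogicalVector alive = st["alive"], fed = st["fed"];
  IntegerVector loc = st["loc"], sex = st["sex"], age = st["age"],
    pair = st["pair"], id = st["id"], sire_id = st["sire_id"],
    dam_id = st["dam_id"];
  const int n = alive.size();
  // dissolve non-persistent pairs
  for (int i = 0; i < n; ++i) {
    if (alive[i] && loc[i] == 1 && pair[i] > i + 1) {
      if (unif_rand() >= persistence) {
        const int m = pair[i] - 1;
        pair[i] = 0; pair[m] = 0;
        fed[i] = false; fed[m] = false;
      }
    }
  }
  std::vector<int> fem, mal;
  int n_af = 0, paired_f = 0;
  for (int i = 0; i < n; ++i) {
    if (!alive[i] || loc[i] != 1 || age[i] < fba) continue;
    if (sex[i] == 1) {
      ++n_af;
      if (pair[i] > 0) ++paired_f; else fem.push_back(i);
    } else if (pair[i] == 0) {
      mal.push_back(i);
    }
  }
  if (n_af == 0 || mal.empty() || fem.empty()) return;
  const int target = rstoch_round_c(rate * n_af);
  int need = target - paired_f;
  if (need <= 0) return;
  if (need > (int)fem.size()) need = (int)fem.size();
  const int nf = (int)fem.size();
  for (int t = 0; t < need; ++t) {  // partial Fisher-Yates female selection
    const int r = t + (int)(unif_rand() * (nf - t));
    std::swap(fem[t], fem[r]);
  }
  int avail = (int)mal.size();
  for (int i = 0; i < need && avail > 0; ++i) {
    const int f = fem[i];
    for (int t = 0; t < avail; ++t) {
      const int r = t + (int)(unif_rand() * (avail - t));
      std::swap(mal[t], mal[r]);
      const int m = mal[t];
      bool forb = false;
      if (kin_exclusion) {
        forb = (sire_id[f] == id[m]) || (dam_id[m] == id[f]) ||
          (sire_id[f] > 0 && dam_id[f] > 0 &&
           sire_id[f] == sire_id[m] && dam_id[f] == dam_id[m]);
      }
      if (!forb) {
        pair[f] = m + 1;
        pair[m] = f + 1;
        const bool fd = unif_rand() < fed_fraction;
        fed[f] = fd; fed[m] = fd;
        mal.erase(mal.begin() + t);
        --avail;
        break;
      }
    }
  }
}

// One year of reproduction over the current breeding pairs. The effective
// inbreeding load F* is zero for fed packs, else the pair's allele-sharing
// kinship estimate; whelping succeeds with probability
// (1 - whelp_fail_base) exp(-b_fail F*) age_fecundity[age] repro_mult and
// litter sizes drawn from litter_dist are binomially thinned by
// exp(-b_size F*). Pups receive F = the pair kinship estimate.
// [[Rcpp::export]]
void cpp_reproduce(Environment st, double whelp_fail_base, double b_fail,
                   double b_size, NumericVector age_fecundity,
                   double repro_mult, NumericVector litter_dist,
                   double sex_ratio, int fba, int max_age, int loc_code,
                   int year) {
  LogicalVector alive = st["alive"], fed = st["fed"],
    released = st["released"], rel_counted = st["rel_counted"];
  IntegerVector loc = st["loc"], sex = st["sex"], age = st["age"],
    pair = st["pair"], id = st["id"], sire_id = st["sire_id"],
    dam_id = st["dam_id"], byear = st["byear"];
  NumericVector fiv = st["Fi"];
  RawMatrix A1 = st["A1"], A2 = st["A2"];
  const int n = alive.size(), L = A1.nrow();
  const int max_litter = litter_dist.size() - 1;
  std::vector<int> sires, dams;
  std::vector<double> fis;
  for (int i = 0; i < n; ++i) {
    if (!alive[i] || loc[i] != loc_code || sex[i] != 1 || pair[i] == 0 ||
        age[i] < fba) continue;
    const int m = pair[i] - 1;
    const double fhat =
      pair_matches(&A1(0, i), &A2(0, i), &A1(0, m), &A2(0, m), L) / (4.0 * L);
    const double fstar = fed[i] ? 0.0 : fhat;
    const int a = age[i] > max_age ? max_age : age[i];
    const double wp = (1.0 - whelp_fail_base) * std::exp(-b_fail * fstar) *
      age_fecundity[a] * repro_mult;
    if (unif_rand() >= wp) continue;
    // litter size by inverse-CDF draw, then binomial thinning
    double u = unif_rand();
    int sz = 0;
    for (int k = 0; k <= max_litter; ++k) {
      u -= litter_dist[k];
      if (u <= 0) { sz = k; break; }
      if (k == max_litter) sz = max_litter;
    }
    const double keep = std::exp(-b_size * fstar);
    if (keep < 1.0) sz = (int)R::rbinom(sz, keep);
    for (int k = 0; k < sz; ++k) {
      sires.push_back(m + 1);
      dams.push_back(i + 1);
      fis.push_back(fhat);
    }
  }
  if (sires.empty()) return;
  // newborn creation needs free capacity; grow via the R helper if short
  // (growth replaces the state's vectors, so re-fetch everything after)
  const int nb = (int)sires.size();
  int free_top = st["free_top"];
  if (free_top < nb) {
    Function grow = Environment::namespace_env("wolfpva")["grow_state"];
    grow(st, nb - free_top);
    cpp_newborns(st, wrap(sires), wrap(dams), wrap(fis), loc_code, sex_ratio,
                 year);
    return;
  }
  IntegerVector free_stack = st["free_stack"];
  int next_id = st["next_id"];
  for (int i = 0; i < nb; ++i) {
    const int t = free_stack[free_top - nb + i] - 1;
    const int s = sires[i] - 1, d = dams[i] - 1;
    alive[t] = true;
    loc[t] = loc_code;
    sex[t] = (unif_rand() < sex_ratio) ? 1 : 2;
    age[t] = 0;
    fiv[t] = fis[i];
    id[t] = next_id++;
    sire_id[t] = id[s];
    dam_id[t] = id[d];
    pair[t] = 0;
    fed[t] = false;
    byear[t] = year;
    released[t] = false;
    rel_counted[t] = false;
    const Rbyte *s1 = &A1(0, s), *s2 = &A2(0, s);
    const Rbyte *d1 = &A1(0, d), *d2 = &A2(0, d);
    Rbyte *t1 = &A1(0, t), *t2 = &A2(0, t);
    uint32_t rs = 0, rd = 0;
    for (int j = 0; j < L; ++j) {
      if ((j & 31) == 0) { rs = rand_bits32(); rd = rand_bits32(); }
      t1[j] = (rs & 1u) ? s1[j] : s2[j];
      t2[j] = (rd & 1u) ? d1[j] : d2[j];
      rs >>= 1; rd >>= 1;
    }
  }
  st["free_top"] = free_top - nb;
  st["next_id"] = next_id;
}

// One year of age-class mortality and disease over a location: death with
// the (clamped) adjusted rates, survival multiplied by `sev` in outbreak
// years, certain death at max_age.
// [[Rcpp::export]]
void cpp_mortality(Environment st, NumericMatrix rates, double sev,
                   int max_age, int loc_code) {
  LogicalVector alive = st["alive"], fed = st["fed"];
  IntegerVector loc = st["loc"], sex = st["sex"], age = st["age"],
    pair = st["pair"], free_stack = st["free_stack"];
  const int n = alive.size();
  int free_top = st["free_top"];
  for (int i = 0; i < n; ++i) {
    if (!alive[i] || loc[i] != loc_code) continue;
    const int cls = age[i] >= 2 ? 2 : age[i];
    const double surv = (1.0 - rates(cls, sex[i] - 1)) * sev;
    if (unif_rand() >= surv || age[i] >= max_age) {
      const int mate = pair[i];
      if (mate > 0) { pair[mate - 1] = 0; fed[mate - 1] = false; }
      alive[i] = false;
      loc[i] = 0;
      pair[i] = 0;
      fed[i] = false;
      free_stack[free_top++] = i + 1;
    }
  }
  st["free_top"] = free_top;
}

// Observed heterozygosity: fraction of individuals whose two alleles differ,
// averaged over loci.
// [[Rcpp::export(rng = false)]]
double cpp_ho(RawMatrix A1, RawMatrix A2, IntegerVector idx) {
  const int L = A1.nrow(), n = idx.size();
  if (n == 0) return NA_REAL;
  long het = 0;
  for (int i = 0; i < n; ++i) {
    const int x = idx[i] - 1;
    const Rbyte *x1 = &A1(0, x), *x2 = &A2(0, x);
    for (int j = 0; j < L; ++j) het += (x1[j] != x2[j]);
  }
  return het / (double)(n * (double)L);
}
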