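// Forward Wright-Fisher simulator of three diverged populations with an
// optional hard sweep in the focal population. Haplotypes are sorted vectors
// of positions carrying the derived allele (infinite-sites on 1..L, active
// duplicate positions re-drawn). Uses R's RNG throughout, so a single
// set.seed() upstream makes the whole run deterministic.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <climits>

using namespace Rcpp;

typedef std::vector<int> Hap;

static Hap gamete(const Hap &a, const Hap &b, double rho_l, int L) {
  int k = (int) R::rpois(rho_l);
  bool use_b = unif_rand() < 0.5;
  if (k == 0) return use_b ? b : a;
  std::vector<int> bps(k);
  for (int i = 0; i < k; ++i) bps[i] = 1 + (int)(unif_rand() * (L - 1));
  std::sort(bps.begin(), bps.end());
  Hap out;
  out.reserve(std::max(a.size(), b.size()) + 4);
  int start = 1;
  for (int i = 0; i <= k; ++i) {
    int end = (i < k) ? bps[i] : L;
    if (end >= start) {
      const Hap &src = use_b ? b : a;
      Hap::const_iterator lo = std::lower_bound(src.begin(), src.end(), start);
      Hap::const_iterator hi = std::upper_bound(lo, src.end(), end);
      out.insert(out.end(), lo, hi);
    }
    use_b = !use_b;
    start = end + 1;
  }
  return out;
}

static void mutate(Hap &h, double mu_l, int L,
                   std::unordered_set<int> &active) {
  int m = (int) R::rpois(mu_l);
  for (int i = 0; i < m; ++i) {
    int pos = 0, guard = 0;
    do {
      pos = 1 + (int)(unif_rand() * L);
    } while (active.count(pos) && ++guard < 10000);
    if (active.count(pos)) continue; // saturated chromosome; skip
    active.insert(pos);
    h.insert(std::lower_bound(h.begin(), h.end(), pos), pos);
  }
}

static bool carries(const Hap &h, int pos) {
  return std::binary_search(h.begin(), h.end(), pos);
}

// one generation: children drawn from parents, optional viability selection
// (fitness 1 / 1+h*s / 1+s by derived dose at sel_pos)
static std::vector<Hap> wf_step(const std::vector<Hap> &par, int n_child,
                                double rho_l, double mu_l, int L,
                                std::unordered_set<int> &active,
                                int sel_pos, double s, double hdom) {
  int n_par = (int) par.size() / 2;
  bool sel = sel_pos >= 0 && s > 0;
  std::vector<double> cum(n_par);
  double tot = 0.0;
  for (int i = 0; i < n_par; ++i) {
    double w = 1.0;
    if (sel) {
      int dose = (carries(par[2 * i], sel_pos) ? 1 : 0) +
                 (carries(par[2 * i + 1], sel_pos) ? 1 : 0);
      w = dose == 2 ? 1.0 + s : (dose == 1 ? 1.0 + hdom * s : 1.0);
    }
    tot += w;
    cum[i] = tot;
  }
  std::vector<Hap> child(2 * n_child);
  for (int j = 0; j < n_child; ++j) {
    for (int g = 0; g < 2; ++g) {
      double u = unif_rand() * tot;
      int p = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (p >= n_par) p = n_par - 1;
      Hap hap = gamete(par[2 * p], par[2 * p + 1], rho_l, L);
      mutate(hap, mu_l, L, active);
      child[2 * j + g] = hap;
    }
  }
  return child;
}

// drop sites fixed across every listed population; rebuild the active set
static void prune(std::vector<std::vector<Hap> *> &pops,
                  std::unordered_set<int> &active, int L) {
  std::vector<int> cnt(L + 2, 0);
  int total = 0;
  for (size_t p = 0; p < pops.size(); ++p) {
    total += (int) pops[p]->size();
    for (size_t i = 0; i < pops[p]->size(); ++i)
      for (size_t j = 0; j < (*pops[p])[i].size(); ++j)
        cnt[(*pops[p])[i][j]]++;
  }
  bool any_fixed = false;
  std::unordered_set<int> segregating;
  for (int pos = 1; pos <= L; ++pos) {
    if (cnt[pos] == 0) continue;
    if (cnt[pos] == total) any_fixed = true;
    else segregating.insert(pos);
  }
  if (any_fixed) {
    for (size_t p = 0; p < pops.size(); ++p)
      for (size_t i = 0; i < pops[p]->size(); ++i) {
        Hap &h = (*pops[p])[i];
        Hap nh;
        nh.reserve(h.size());
        for (size_t j = 0; j < h.size(); ++j)
          if (cnt[h[j]] != total) nh.push_back(h[j]);
        h.swap(nh);
      }
  }
  active.swap(segregating);
}

// standing variant nearest L/2 with pool frequency in [lo, hi]; fallback:
// any polymorphic site nearest L/2; ties broken toward the smaller position
static int choose_selected(const std::vector<Hap> &pool, int L,
                           double lo, double hi) {
  std::unordered_map<int, int> cnt;
  for (size_t i = 0; i < pool.size(); ++i)
    for (size_t j = 0; j < pool[i].size(); ++j) cnt[pool[i][j]]++;
  int H = (int) pool.size();
  long center = L / 2;
  int best = -1, best_any = -1;
  long bd = LONG_MAX, bd_any = LONG_MAX;
  for (std::unordered_map<int, int>::iterator it = cnt.begin();
       it != cnt.end(); ++it) {
    if (it->second <= 0 || it->second >= H) continue;
    long d = labs((long) it->first - center);
    double f = (double) it->second / H;
    if (f >= lo && f <= hi &&
        (d < bd || (d == bd && it->first < best))) { bd = d; best = it->first; }
    if (d < bd_any || (d == bd_any && it->first < best_any)) {
      bd_any = d; best_any = it->first;
    }
  }
  return best >= 0 ? best : best_any;
}

// partial Fisher-Yates: k distinct indices from 0..n-1
static std::vector<int> sample_without_replacement(int n, int k) {
  std::vector<int> v(n);
  for (int i = 0; i < n; ++i) v[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(v[i], v[j]);
  }
  v.resize(k);
  return v;
}

static double pop_freq(const std::vector<Hap> &pop, int pos) {
  if (pos < 0) return NA_REAL;
  int c = 0;
  for (size_t i = 0; i < pop.size(); ++i) if (carries(pop[i], pos)) ++c;
  return (double) c / (double) pop.size();
}

// [[Rcpp::export]]
List wf_sim_cpp(int n_anc, int n_pop, int t_split1, int t_split2,
                int L, double mu, double rho, double s, double hdom,
                int sweep_start, int n_sample, int burn_in,
                double mu_post_factor, double sel_freq_lo,
                double sel_freq_hi) {
  double mu_l = mu * L, rho_l = rho * L;
  double mu_l_post = mu_l * mu_post_factor;
  std::unordered_set<int> active;
  std::vector<Hap> anc(2 * n_anc), focal, canc, c1, c2;

  for (int g = 0; g < burn_in; ++g) {
    anc = wf_step(anc, n_anc, rho_l, mu_l, L, active, -1, 0.0, hdom);
    if (g % 10 == 9) {
      std::vector<std::vector<Hap> *> ps;
      ps.push_back(&anc);
      prune(ps, active, L);
    }
  }
  {
    std::vector<std::vector<Hap> *> ps;
    ps.push_back(&anc);
    prune(ps, active, L);
  }
  std::vector<int> split_positions(active.begin(), active.end());
  std::sort(split_positions.begin(), split_positions.end());

  int sel_pos = -1;
  double sel_init_freq = NA_REAL;
  bool split2_done = false;
  for (int t = t_split1 - 1; t >= 0; --t) {
    bool first = (t == t_split1 - 1);
    // the tracked central site is chosen even under neutrality (s = 0) so
    // drift at a known site can be audited; fitness is applied only if s>0
    if (sel_pos < 0 && t == sweep_start - 1) {
      const std::vector<Hap> &pool = first ? anc : focal;
      sel_pos = choose_selected(pool, L, sel_freq_lo, sel_freq_hi);
      if (sel_pos >= 0) sel_init_freq = pop_freq(pool, sel_pos);
    }
    int fsel = (s > 0 && sel_pos >= 0 && t <= sweep_start - 1) ? sel_pos : -1;
    if (first) {
      focal = wf_step(anc, n_pop, rho_l, mu_l_post, L, active, fsel, s, hdom);
      canc = wf_step(anc, n_pop, rho_l, mu_l_post, L, active, -1, 0.0, hdom);
      anc.clear();
    } else {
      focal = wf_step(focal, n_pop, rho_l, mu_l_post, L, active, fsel, s, hdom);
      if (!split2_done && t == t_split2 - 1) {
        // first generation of the two separate control lineages, both drawn
        // from the common control ancestor at time t_split2
        c1 = wf_step(canc, n_pop, rho_l, mu_l_post, L, active, -1, 0.0, hdom);
        c2 = wf_step(canc, n_pop, rho_l, mu_l_post, L, active, -1, 0.0, hdom);
        canc.clear();
        split2_done = true;
      } else if (!split2_done) {
        canc = wf_step(canc, n_pop, rho_l, mu_l_post, L, active, -1, 0.0, hdom);
      } else {
        c1 = wf_step(c1, n_pop, rho_l, mu_l_post, L, active, -1, 0.0, hdom);
        c2 = wf_step(c2, n_pop, rho_l, mu_l_post, L, active, -1, 0.0, hdom);
      }
    }
    if (t % 10 == 0) {
      std::vector<std::vector<Hap> *> ps;
      ps.push_back(&focal);
      if (!split2_done) ps.push_back(&canc);
      else { ps.push_back(&c1); ps.push_back(&c2); }
      prune(ps, active, L);
    }
  }
  if (!split2_done) {
    // t_split2 == 0: the two control samples are disjoint draws from the
    // common control ancestor at the present
    std::vector<int> idx = sample_without_replacement((int) canc.size() / 2,
                                                      std::min(2 * n_sample,
                                                               (int) canc.size() / 2));
    c1.clear(); c2.clear();
    for (int i = 0; i < (int) idx.size(); ++i) {
      std::vector<Hap> &dst = (i < n_sample) ? c1 : c2;
      dst.push_back(canc[2 * idx[i]]);
      dst.push_back(canc[2 * idx[i] + 1]);
    }
    canc.clear();
  }

  double freq_focal_pop = pop_freq(focal, sel_pos);

  // draw the diploid samples
  std::vector<Hap> samp;
  samp.reserve(6 * n_sample);
  std::vector<std::vector<Hap> *> pools;
  pools.push_back(&focal);
  pools.push_back(&c1);
  pools.push_back(&c2);
  for (int p = 0; p < 3; ++p) {
    std::vector<Hap> &pool = *pools[p];
    int n_ind = (int) pool.size() / 2;
    if (n_ind < n_sample)
      stop("population too small to draw %d diploid samples", n_sample);
    std::vector<int> idx = sample_without_replacement(n_ind, n_sample);
    std::sort(idx.begin(), idx.end());
    for (int i = 0; i < n_sample; ++i) {
      samp.push_back(pool[2 * idx[i]]);
      samp.push_back(pool[2 * idx[i] + 1]);
    }
  }

  // union of derived positions across the sample
  std::unordered_set<int> pos_set;
  for (size_t i = 0; i < samp.size(); ++i)
    for (size_t j = 0; j < samp[i].size(); ++j) pos_set.insert(samp[i][j]);
  std::vector<int> positions(pos_set.begin(), pos_set.end());
  std::sort(positions.begin(), positions.end());
  std::unordered_map<int, int> col_of;
  for (size_t j = 0; j < positions.size(); ++j) col_of[positions[j]] = (int) j;

  IntegerMatrix al((int) samp.size(), (int) positions.size());
  for (size_t i = 0; i < samp.size(); ++i)
    for (size_t j = 0; j < samp[i].size(); ++j)
      al((int) i, col_of[samp[i][j]]) = 1;

  NumericVector sample_freq(3);
  for (int p = 0; p < 3; ++p) {
    if (sel_pos < 0) { sample_freq[p] = NA_REAL; continue; }
    int c = 0;
    for (int i = 2 * n_sample * p; i < 2 * n_sample * (p + 1); ++i)
      if (carries(samp[i], sel_pos)) ++c;
    sample_freq[p] = (double) c / (2.0 * n_sample);
  }

  return List::create(
    _["alleles"] = al,
    _["positions"] = IntegerVector(positions.begin(), positions.end()),
    _["selected_pos"] = sel_pos,
    _["sel_init_freq"] = sel_init_freq,
    _["focal_pop_freq"] = freq_focal_pop,
    _["sample_freq"] = sample_freq,
    _["split_positions"] = IntegerVector(split_positions.begin(),
                                         split_positions.end()));
}
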