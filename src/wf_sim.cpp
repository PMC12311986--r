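#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Forward diploid Wright-Fisher simulator with infinite-sites mutation on a
// finite coordinate grid, uniform recombination and optional partial
// selfing. Haplotypes live in flat row-major byte buffers (one byte per
// derived allele, stride = column capacity) so a generation is a handful of
// sequential memcpys. The site registry (1-based positions) is shared by
// all populations: a mutation in one population implicitly adds an
// ancestral (0) column to the others. All randomness comes from R's RNG,
// so set.seed() in R gives full determinism.

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Pop {
  int nhap;
  size_t cap;
  std::vector<unsigned char> data, buf;
  Pop() : nhap(0), cap(0) {}
  unsigned char *row(int i) { return data.data() + (size_t)i * cap; }
  const unsigned char *row(int i) const {
    return data.data() + (size_t)i * cap;
  }
};

static void ensure_cap(std::vector<Pop *> &pops, size_t S, size_t need) {
  size_t cap0 = pops[0]->cap;
  if (need <= cap0) return;
  size_t newcap = cap0 ? cap0 : 1024;
  while (newcap < need) newcap *= 2;
  for (size_t q = 0; q < pops.size(); ++q) {
    Pop &p = *pops[q];
    std::vector<unsigned char> nd((size_t)p.nhap * newcap, 0);
    for (int i = 0; i < p.nhap; ++i)
      std::memcpy(nd.data() + (size_t)i * newcap, p.row(i), S);
    p.data.swap(nd);
    p.cap = newcap;
  }
}

static void gamete(const Pop &p, int parent, double recomb, double L,
                   const std::vector<int> &pos, unsigned char *out) {
  int s = runif_int(2);
  const unsigned char *ha = p.row(2 * parent + s);
  size_t S = pos.size();
  int ncross = (int)R::rpois(recomb * L);
  if (ncross == 0) { std::memcpy(out, ha, S); return; }
  const unsigned char *hb = p.row(2 * parent + 1 - s);
  double cuts[8];
  std::vector<double> cuts_big;
  double *cp = cuts;
  if (ncross > 8) { cuts_big.resize(ncross); cp = cuts_big.data(); }
  for (int c = 0; c < ncross; ++c) cp[c] = unif_rand() * L;
  for (size_t j = 0; j < S; ++j) {
    int par = 0;
    for (int c = 0; c < ncross; ++c) if (cp[c] < pos[j]) ++par;
    out[j] = (par & 1) ? hb[j] : ha[j];
  }
}

static void reproduce(Pop &p, int n_new, double selfing, double recomb,
                      double L, const std::vector<int> &pos) {
  int n_old = p.nhap / 2;
  p.buf.resize((size_t)(2 * n_new) * p.cap);
  for (int k = 0; k < n_new; ++k) {
    int p1 = runif_int(n_old);
    int p2 = (selfing > 0 && unif_rand() < selfing) ? p1 : runif_int(n_old);
    gamete(p, p1, recomb, L, pos, p.buf.data() + (size_t)(2 * k) * p.cap);
    gamete(p, p2, recomb, L, pos, p.buf.data() + (size_t)(2 * k + 1) * p.cap);
  }
  p.data.swap(p.buf);
  p.nhap = 2 * n_new;
}

static void mutate(std::vector<Pop *> &pops, int target, double mu, double L,
                   std::vector<int> &pos, std::unordered_set<int> &used,
                   int &collisions) {
  Pop &tp = *pops[target];
  int nm = (int)R::rpois((double)tp.nhap * mu * L);
  if (nm == 0) return;
  std::vector<int> newpos;
  newpos.reserve(nm);
  for (int m = 0; m < nm; ++m) {
    int p = 1 + runif_int((int)L);
    if (used.count(p)) { ++collisions; continue; }
    used.insert(p);
    newpos.push_back(p);
  }
  if (newpos.empty()) return;
  ensure_cap(pops, pos.size(), pos.size() + newpos.size());
  for (size_t m = 0; m < newpos.size(); ++m) {
    size_t col = pos.size();
    for (size_t q = 0; q < pops.size(); ++q) {
      Pop &p = *pops[q];
      for (int i = 0; i < p.nhap; ++i) p.row(i)[col] = 0;
    }
    tp.row(runif_int(tp.nhap))[col] = 1;
    pos.push_back(newpos[m]);
  }
}

// Drop columns lost everywhere; optionally also columns fixed everywhere
// (counted as substitutions -- the ancestral state is redefined, which is
// only allowed while a single ancestral population exists).
static void purge(std::vector<Pop *> &pops, std::vector<int> &pos,
                  std::unordered_set<int> &used, bool drop_fixed,
                  int &substitutions) {
  size_t S = pos.size();
  if (S == 0) return;
  std::vector<long> tot(S, 0);
  long rows = 0;
  for (size_t q = 0; q < pops.size(); ++q) {
    Pop &p = *pops[q];
    rows += p.nhap;
    for (int i = 0; i < p.nhap; ++i) {
      const unsigned char *h = p.row(i);
      for (size_t j = 0; j < S; ++j) tot[j] += h[j];
    }
  }
  std::vector<int> keep;
  keep.reserve(S);
  for (size_t j = 0; j < S; ++j) {
    if (tot[j] == 0) { used.erase(pos[j]); continue; }
    if (drop_fixed && tot[j] == rows) {
      ++substitutions; used.erase(pos[j]); continue;
    }
    keep.push_back((int)j);
  }
  if (keep.size() == S) return;
  for (size_t q = 0; q < pops.size(); ++q) {
    Pop &p = *pops[q];
    for (int i = 0; i < p.nhap; ++i) {
      unsigned char *h = p.row(i);
      for (size_t k = 0; k < keep.size(); ++k) h[k] = h[keep[k]];
    }
  }
  std::vector<int> np(keep.size());
  for (size_t k = 0; k < keep.size(); ++k) np[k] = pos[keep[k]];
  pos.swap(np);
}

static IntegerMatrix sample_haps(Pop &pop, const std::vector<int> &ind,
                                 const std::vector<int> &site_order) {
  size_t S = site_order.size();
  IntegerMatrix out(2 * ind.size(), S);
  for (size_t i = 0; i < ind.size(); ++i)
    for (int a = 0; a < 2; ++a) {
      const unsigned char *h = pop.row(2 * ind[i] + a);
      for (size_t j = 0; j < S; ++j)
        out(2 * i + a, j) = h[site_order[j]];
    }
  return out;
}

static void sample_individuals(int n_avail, int n_take, std::vector<int> &out) {
  std::vector<int> perm(n_avail);
  for (int i = 0; i < n_avail; ++i) perm[i] = i;
  for (int i = 0; i < n_take; ++i) {
    int j = i + runif_int(n_avail - i);
    std::swap(perm[i], perm[j]);
    out[i] = perm[i];
  }
}

// [[Rcpp::export]]
List wf_sim_cpp(int n_anc, int burnin, IntegerVector traj_x,
                IntegerVector traj_y, double mu, double recomb, double L,
                double selfing_x, double selfing_y, int sample_x,
                int sample_y, int purge_every) {
  if (n_anc < 1) stop("ancestral population size must be >= 1");
  for (int g = 0; g < traj_x.size(); ++g)
    if (traj_x[g] < 1 || traj_y[g] < 1) stop("population sizes must be >= 1");
  std::vector<int> pos;
  std::unordered_set<int> used;
  int collisions = 0, substitutions = 0;

  Pop anc;
  anc.nhap = 2 * n_anc;
  anc.cap = 1024;
  anc.data.assign((size_t)anc.nhap * anc.cap, 0);
  std::vector<Pop *> live;
  live.push_back(&anc);
  for (int g = 0; g < burnin; ++g) {
    reproduce(anc, n_anc, 0.0, recomb, L, pos);
    mutate(live, 0, mu, L, pos, used, collisions);
    if ((g + 1) % purge_every == 0)
      purge(live, pos, used, true, substitutions);
  }
  purge(live, pos, used, true, substitutions);

  int t_split = traj_x.size();
  Pop px, py;
  std::vector<int> ind_x(sample_x), ind_y(sample_y);
  Pop *out_x = &anc, *out_y = &anc;
  if (t_split > 0) {
    px = anc; py = anc;
    live.clear(); live.push_back(&px); live.push_back(&py);
    for (int g = 0; g < t_split; ++g) {
      reproduce(px, traj_x[g], selfing_x, recomb, L, pos);
      reproduce(py, traj_y[g], selfing_y, recomb, L, pos);
      mutate(live, 0, mu, L, pos, used, collisions);
      mutate(live, 1, mu, L, pos, used, collisions);
      if ((g + 1) % purge_every == 0)
        purge(live, pos, used, false, substitutions);
    }
    purge(live, pos, used, false, substitutions);
    if (sample_x > px.nhap / 2 || sample_y > py.nhap / 2)
      stop("sample size exceeds final population size");
    sample_individuals(px.nhap / 2, sample_x, ind_x);
    sample_individuals(py.nhap / 2, sample_y, ind_y);
    out_x = &px; out_y = &py;
  } else {
    // no divergence: both samples drawn (disjointly) from the one pool
    if (sample_x + sample_y > n_anc)
      stop("sample sizes exceed ancestral population size");
    std::vector<int> both(sample_x + sample_y);
    sample_individuals(n_anc, sample_x + sample_y, both);
    for (int i = 0; i < sample_x; ++i) ind_x[i] = both[i];
    for (int i = 0; i < sample_y; ++i) ind_y[i] = both[sample_x + i];
  }

  size_t S = pos.size();
  std::vector<int> site_order(S);
  for (size_t j = 0; j < S; ++j) site_order[j] = (int)j;
  std::sort(site_order.begin(), site_order.end(),
            [&pos](int a, int b) { return pos[a] < pos[b]; });
  IntegerVector out_pos(S);
  for (size_t j = 0; j < S; ++j) out_pos[j] = pos[site_order[j]];

  return List::create(
    _["pos"] = out_pos,
    _["hap_x"] = sample_haps(*out_x, ind_x, site_order),
    _["hap_y"] = sample_haps(*out_y, ind_y, site_order),
    _["n_collisions"] = collisions,
    _["n_substitutions"] = substitutions);
}
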