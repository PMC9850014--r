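#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Internal state for one simulated genealogy. Node ids are 0-based:
// tips 0..(n-1), internal nodes n..(2n-2). Times in generations before present.
struct Genealogy {
  int n_tips;
  std::vector<double> node_time;
  std::vector<int> left, right;   // children of internal nodes (size 2n-1, -1 for tips)
  std::vector<int> parent;        // -1 for root
};

// Serial-sampling n-coalescent with piecewise-constant diploid size N(t).
// epoch_starts: strictly increasing, first = 0; epoch i spans
// [epoch_starts[i], epoch_starts[i+1]). Coalescence rate among k active
// lineages is k(k-1)/(4N). Lineages sampled at time t enter at t.
static Genealogy simulate_genealogy(const std::vector<double>& epoch_starts,
                                    const std::vector<double>& epoch_sizes,
                                    const std::vector<double>& samp_times,
                                    const std::vector<int>& samp_counts) {
  int n = 0;
  for (size_t i = 0; i < samp_counts.size(); ++i) n += samp_counts[i];
  Genealogy g;
  g.n_tips = n;
  int n_nodes = 2 * n - 1;
  g.node_time.assign(n_nodes, 0.0);
  g.left.assign(n_nodes, -1);
  g.right.assign(n_nodes, -1);
  g.parent.assign(n_nodes, -1);

  // tips ordered by sampling event, then index within event
  std::vector<double> tip_time(n);
  {
    int id = 0;
    for (size_t e = 0; e < samp_times.size(); ++e)
      for (int j = 0; j < samp_counts[e]; ++j) tip_time[id++] = samp_times[e];
  }
  // pending sampling events sorted by time
  std::vector<size_t> ev_order(samp_times.size());
  for (size_t i = 0; i < ev_order.size(); ++i) ev_order[i] = i;
  std::sort(ev_order.begin(), ev_order.end(),
            [&](size_t a, size_t b) { return samp_times[a] < samp_times[b]; });

  std::vector<int> active;
  active.reserve(n);
  size_t next_ev = 0;
  // tip ids grouped by event in original order
  std::vector<std::vector<int> > ev_tips(samp_times.size());
  {
    int id = 0;
    for (size_t e = 0; e < samp_times.size(); ++e)
      for (int j = 0; j < samp_counts[e]; ++j) ev_tips[e].push_back(id++);
  }

  double t = samp_times[ev_order[0]];
  // enter all events at exactly t
  while (next_ev < ev_order.size() && samp_times[ev_order[next_ev]] <= t) {
    const std::vector<int>& tips = ev_tips[ev_order[next_ev]];
    active.insert(active.end(), tips.begin(), tips.end());
    ++next_ev;
  }
  int next_internal = n;
  size_t epoch = 0;
  while (epoch + 1 < epoch_starts.size() && epoch_starts[epoch + 1] <= t) ++epoch;

  while ((int)active.size() > 1 || next_ev < ev_order.size()) {
    double t_next_sample = (next_ev < ev_order.size())
                               ? samp_times[ev_order[next_ev]] : R_PosInf;
    if ((int)active.size() < 2) {
      // must wait for more lineages
      t = t_next_sample;
      while (epoch + 1 < epoch_starts.size() && epoch_starts[epoch + 1] <= t) ++epoch;
      const std::vector<int>& tips = ev_tips[ev_order[next_ev]];
      active.insert(active.end(), tips.begin(), tips.end());
      ++next_ev;
      continue;
    }
    double N = epoch_sizes[epoch];
    double k = (double)active.size();
    double rate = k * (k - 1.0) / (4.0 * N);
    double w = ::Rf_rexp(1.0) / rate;
    double t_epoch_end = (epoch + 1 < epoch_starts.size())
                             ? epoch_starts[epoch + 1] : R_PosInf;
    double boundary = std::min(t_epoch_end, t_next_sample);
    if (t + w < boundary) {
      t += w;
      // coalesce two distinct uniformly chosen active lineages
      int i = (int)(::unif_rand() * active.size());
      if (i >= (int)active.size()) i = active.size() - 1;
      int j = (int)(::unif_rand() * (active.size() - 1));
      if (j >= (int)active.size() - 1) j = active.size() - 2;
      if (j >= i) ++j;
      int a = active[i], b = active[j];
      int p = next_internal++;
      g.node_time[p] = t;
      g.left[p] = a;
      g.right[p] = b;
      g.parent[a] = p;
      g.parent[b] = p;
      // remove both, add parent
      if (i > j) std::swap(i, j);
      active[i] = p;
      active.erase(active.begin() + j);
    } else {
      t = boundary;
      if (t_next_sample <= t_epoch_end && next_ev < ev_order.size() &&
          samp_times[ev_order[next_ev]] <= t) {
        const std::vector<int>& tips = ev_tips[ev_order[next_ev]];
        active.insert(active.end(), tips.begin(), tips.end());
        ++next_ev;
      } else {
        ++epoch;
      }
    }
  }
  for (int i = 0; i < n; ++i) g.node_time[i] = tip_time[i];
  return g;
}

// [[Rcpp::export]]
List cpp_genealogy(NumericVector epoch_starts, NumericVector epoch_sizes,
                   NumericVector samp_times, IntegerVector samp_counts) {
  std::vector<double> es(epoch_starts.begin(), epoch_starts.end());
  std::vector<double> en(epoch_sizes.begin(), epoch_sizes.end());
  std::vector<double> st(samp_times.begin(), samp_times.end());
  std::vector<int> sc(samp_counts.begin(), samp_counts.end());
  Genealogy g = simulate_genealogy(es, en, st, sc);
  int n_nodes = 2 * g.n_tips - 1;
  return List::create(
      _["n_tips"] = g.n_tips,
      _["node_time"] = NumericVector(g.node_time.begin(), g.node_time.end()),
      _["left"] = IntegerVector(g.left.begin(), g.left.begin() + n_nodes),
      _["right"] = IntegerVector(g.right.begin(), g.right.begin() + n_nodes),
      _["parent"] = IntegerVector(g.parent.begin(), g.parent.begin() + n_nodes));
}

// Drop one mutation uniformly on total branch length; derived allele = tips
// below the mutated branch. Returns derived indicator per tip.
static void drop_mutation(const Genealogy& g, std::vector<int>& derived) {
  int n_nodes = 2 * g.n_tips - 1;
  int root = n_nodes - 1;
  double total = 0.0;
  std::vector<double> blen(n_nodes, 0.0);
  for (int v = 0; v < n_nodes; ++v) {
    if (g.parent[v] >= 0) {
      blen[v] = g.node_time[g.parent[v]] - g.node_time[v];
      total += blen[v];
    }
  }
  double u = ::unif_rand() * total;
  int hit = -1;
  for (int v = 0; v < n_nodes; ++v) {
    if (v == root) continue;
    u -= blen[v];
    if (u <= 0) { hit = v; break; }
  }
  if (hit < 0) hit = root - 1;  // numeric edge case
  derived.assign(g.n_tips, 0);
  std::vector<int> stack;
  stack.push_back(hit);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    if (v < g.n_tips) derived[v] = 1;
    else { stack.push_back(g.left[v]); stack.push_back(g.right[v]); }
  }
}

// Simulate unlinked single-SNP loci: one genealogy per locus, one mutation per
// locus (fixed-S ascertainment). Lineages 2i, 2i+1 belong to diploid i.
// [[Rcpp::export]]
IntegerMatrix cpp_sim_snps(NumericVector epoch_starts, NumericVector epoch_sizes,
                           NumericVector samp_times, IntegerVector samp_diploids,
                           int n_loci, int retry_cap) {
  std::vector<double> es(epoch_starts.begin(), epoch_starts.end());
  std::vector<double> en(epoch_sizes.begin(), epoch_sizes.end());
  std::vector<double> st(samp_times.begin(), samp_times.end());
  std::vector<int> sc(samp_diploids.size());
  int n_ind = 0;
  for (int i = 0; i < samp_diploids.size(); ++i) {
    sc[i] = 2 * samp_diploids[i];
    n_ind += samp_diploids[i];
  }
  IntegerMatrix geno(n_ind, n_loci);
  std::vector<int> derived;
  for (int l = 0; l < n_loci; ++l) {
    bool ok = false;
    for (int attempt = 0; attempt < retry_cap && !ok; ++attempt) {
      Genealogy g = simulate_genealogy(es, en, st, sc);
      drop_mutation(g, derived);
      int alt = 0;
      for (int v = 0; v < g.n_tips; ++v) alt += derived[v];
      if (alt == 0 || alt == g.n_tips) continue;  // monomorphic: redraw
      for (int i = 0; i < n_ind; ++i)
        geno(i, l) = derived[2 * i] + derived[2 * i + 1];
      ok = true;
    }
    if (!ok) stop("ascertainment failure: no polymorphic site after %d attempts", retry_cap);
  }
  return geno;
}

// Forward-time diploid Wright-Fisher stepping-stone on a line of demes.
// Each child picks its mother's and father's deme independently: stays with
// prob 1-m, moves to each adjacent deme with prob m/2 (edge mass reflects
// home). All demes founded from a common pool with per-locus allele
// frequencies init_freq. Returns genotype matrix of the final generation,
// individuals ordered by deme.
// [[Rcpp::export]]
IntegerMatrix cpp_stepping_stone(int n_demes, int deme_size, double m,
                                 int generations, int n_loci,
                                 NumericVector init_freq) {
  if (init_freq.size() != n_loci) stop("init_freq length must equal n_loci");
  int n_ind = n_demes * deme_size;
  // alleles: [deme][2*deme_size hap][locus], flattened
  std::vector<unsigned char> cur((size_t)n_ind * 2 * n_loci);
  std::vector<unsigned char> nxt(cur.size());
  size_t idx = 0;
  for (int i = 0; i < n_ind * 2; ++i)
    for (int l = 0; l < n_loci; ++l)
      cur[idx++] = (::unif_rand() < init_freq[l]) ? 1 : 0;

  auto pick_deme = [&](int d) {
    double u = ::unif_rand();
    if (u < m / 2.0 && d > 0) return d - 1;
    if (u < m && d + 1 < n_demes) return d + 1;
    return d;
  };
  for (int gen = 0; gen < generations; ++gen) {
    for (int d = 0; d < n_demes; ++d) {
      for (int c = 0; c < deme_size; ++c) {
        int dm = pick_deme(d), df = pick_deme(d);
        int mi = dm * deme_size + (int)(::unif_rand() * deme_size);
        int fi = df * deme_size + (int)(::unif_rand() * deme_size);
        if (mi >= (dm + 1) * deme_size) mi = (dm + 1) * deme_size - 1;
        if (fi >= (df + 1) * deme_size) fi = (df + 1) * deme_size - 1;
        int child = d * deme_size + c;
        size_t c0 = (size_t)(2 * child) * n_loci;
        size_t c1 = (size_t)(2 * child + 1) * n_loci;
        size_t m0 = (size_t)(2 * mi) * n_loci;
        size_t f0 = (size_t)(2 * fi) * n_loci;
        for (int l = 0; l < n_loci; ++l) {
          nxt[c0 + l] = cur[m0 + (::unif_rand() < 0.5 ? 0 : (size_t)n_loci) + l];
          nxt[c1 + l] = cur[f0 + (::unif_rand() < 0.5 ? 0 : (size_t)n_loci) + l];
        }
      }
    }
    cur.swap(nxt);
  }
  IntegerMatrix geno(n_ind, n_loci);
  for (int i = 0; i < n_ind; ++i) {
    size_t a0 = (size_t)(2 * i) * n_loci, a1 = (size_t)(2 * i + 1) * n_loci;
    for (int l = 0; l < n_loci; ++l) geno(i, l) = cur[a0 + l] + cur[a1 + l];
  }
  return geno;
}
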