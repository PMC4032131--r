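// Structured-coalescent core: exact event-driven simulation of genealogies
// under a piecewise-constant deme/migration model, plus branch-pattern
// accumulators and infinite-sites mutation dropping.
//
// Time runs backward from the present (t = 0) in generations.  The model is
// compiled on the R side into epochs [b_{e-1}, b_e) with per-epoch deme sizes
// and migration matrices; lineage-movement actions (deme mergers, colonization
// reversals, admixture pulses) fire when the simulation crosses an epoch
// boundary.  All randomness comes from R's RNG so set.seed() governs
// reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Union-find over demes connected by nonzero migration in the current epoch.
// Used to decide when no pair of lineages can ever co-locate before the next
// checkpoint, in which case migration can be fast-forwarded analytically.
struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[a] = b;
  }
};

int sample_categorical(const std::vector<double> &w, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int n = (int)w.size();
  for (int i = 0; i < n; ++i) {
    acc += w[i];
    if (u <= acc) return i;
  }
  return n - 1;
}

} // namespace

// Simulate one genealogy.
//
// sizes:  n_demes x n_epochs matrix of diploid deme sizes (pairwise
//         coalescence rate 1/(2N) per generation within a deme).
// migs:   list of n_epochs migration matrices; migs[e](i,j) is the backward
//         per-lineage rate of moving from deme i to deme j.
// breaks: epoch boundaries, strictly increasing, length n_epochs - 1.
// actions: per boundary, a list(from=, to=, frac=) of lineage moves applied
//         (in order) when the boundary is crossed; frac = 1 empties a deme.
// samp_deme / samp_time: per-leaf sampling deme (0-based) and time.
//
// Returns parent pointers (0-based; root = -1) and node times for the
// 2n - 1 nodes; leaves 0..n-1 in sample order, internal nodes in
// coalescence-time order.
// [[Rcpp::export]]
List sim_genealogy_cpp(NumericMatrix sizes, List migs, NumericVector breaks,
                       List actions, IntegerVector samp_deme,
                       NumericVector samp_time, double max_time) {
  const int K = sizes.nrow();
  const int n_epochs = sizes.ncol();
  const int n = samp_deme.size();
  const int n_nodes = 2 * n - 1;

  std::vector<int> parent(n_nodes, -1);
  std::vector<double> node_time(n_nodes, 0.0);
  for (int i = 0; i < n; ++i) node_time[i] = samp_time[i];

  // pending leaves sorted by sampling time
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return samp_time[a] < samp_time[b];
  });

  std::vector<int> lin_node;  // active lineage -> node id
  std::vector<int> lin_deme;  // active lineage -> deme
  size_t next_pending = 0;
  double t = 0.0;
  int next_node = n;
  int epoch = 0;

  // activate leaves sampled at t = 0
  while (next_pending < order.size() && samp_time[order[next_pending]] <= 0.0) {
    lin_node.push_back(order[next_pending]);
    lin_deme.push_back(samp_deme[order[next_pending]]);
    ++next_pending;
  }

  arma::mat M(K, K);  // current epoch migration matrix
  std::vector<double> out_rate(K);
  auto load_epoch = [&](int e) {
    NumericMatrix m = migs[e];
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) {
        double v = (i == j) ? 0.0 : m(i, j);
        M(i, j) = v;
        s += v;
      }
      out_rate[i] = s;
    }
  };
  load_epoch(0);

  std::vector<int> deme_count(K);
  std::vector<double> coal_w(K), mig_w;

  while ((int)lin_node.size() > 1 || next_pending < order.size()) {
    // next checkpoint: epoch boundary or leaf activation
    double t_break = (epoch < n_epochs - 1) ? breaks[epoch] : R_PosInf;
    double t_samp = (next_pending < order.size())
                        ? samp_time[order[next_pending]] : R_PosInf;
    double t_check = std::min(std::min(t_break, t_samp), max_time);

    const int L = (int)lin_node.size();

    // per-deme lineage counts and rates
    std::fill(deme_count.begin(), deme_count.end(), 0);
    for (int l = 0; l < L; ++l) deme_count[lin_deme[l]]++;
    double coal_total = 0.0;
    for (int d = 0; d < K; ++d) {
      int k = deme_count[d];
      double w = (k > 1) ? (double)k * (k - 1) / 2.0 / (2.0 * sizes(d, epoch))
                         : 0.0;
      coal_w[d] = w;
      coal_total += w;
    }
    double mig_total = 0.0;
    for (int l = 0; l < L; ++l) mig_total += out_rate[lin_deme[l]];
    double total = coal_total + mig_total;

    bool jumped = false;
    if (coal_total == 0.0 && L > 0) {
      // can any two lineages meet through migration before the checkpoint?
      UnionFind uf(K);
      for (int i = 0; i < K; ++i)
        for (int j = 0; j < K; ++j)
          if (i != j && (M(i, j) > 0.0 || M(j, i) > 0.0)) uf.unite(i, j);
      std::vector<int> comp_count(K, 0);
      bool can_meet = false;
      for (int l = 0; l < L; ++l) {
        int c = uf.find(lin_deme[l]);
        if (++comp_count[c] > 1) { can_meet = true; break; }
      }
      if (!can_meet) {
        // fast-forward: migrations cannot produce a coalescence before the
        // checkpoint, so draw each lineage's deme at the checkpoint from the
        // matrix exponential of the migration generator.
        double dt = t_check - t;
        if (dt > 0.0 && mig_total > 0.0 && std::isfinite(dt)) {
          arma::mat Q = M;
          for (int i = 0; i < K; ++i) Q(i, i) = -out_rate[i];
          arma::mat P = arma::expmat(Q * dt);
          for (int l = 0; l < L; ++l) {
            int d = lin_deme[l];
            if (out_rate[d] <= 0.0) continue;
            std::vector<double> row(K);
            double s = 0.0;
            for (int j = 0; j < K; ++j) {
              double p = P(d, j);
              row[j] = (p > 0.0) ? p : 0.0;
              s += row[j];
            }
            lin_deme[l] = sample_categorical(row, s);
          }
        }
        t = t_check;
        jumped = true;
      }
    }

    if (!jumped) {
      double dt = (total > 0.0) ? exp_rand() / total : R_PosInf;
      if (t + dt >= t_check) {
        t = t_check;
        jumped = true;
      } else {
        t += dt;
        if (unif_rand() * total < coal_total) {
          // coalescence: pick deme, then an unordered pair within it
          int d = sample_categorical(coal_w, coal_total);
          int k = deme_count[d];
          int a = (int)(unif_rand() * k);
          int b = (int)(unif_rand() * (k - 1));
          if (b >= a) ++b;
          // a-th and b-th lineage within deme d
          int ia = -1, ib = -1, seen = 0;
          for (int l = 0; l < L; ++l) {
            if (lin_deme[l] == d) {
              if (seen == a) ia = l;
              if (seen == b) ib = l;
              ++seen;
            }
          }
          int node = next_node++;
          node_time[node] = t;
          parent[lin_node[ia]] = node;
          parent[lin_node[ib]] = node;
          lin_node[ia] = node;
          lin_node.erase(lin_node.begin() + ib);
          lin_deme.erase(lin_deme.begin() + ib);
        } else {
          // migration: pick lineage weighted by its out-rate, then target
          mig_w.resize(L);
          for (int l = 0; l < L; ++l) mig_w[l] = out_rate[lin_deme[l]];
          int l = sample_categorical(mig_w, mig_total);
          int d = lin_deme[l];
          std::vector<double> row(K);
          for (int j = 0; j < K; ++j) row[j] = M(d, j);
          lin_deme[l] = sample_categorical(row, out_rate[d]);
        }
        continue;
      }
    }

    if (t >= max_time) {
      stop("lineages failed to coalesce before the maximum time horizon "
           "(%g generations); the deme graph may be disconnected", max_time);
    }

    // process the checkpoint we just reached
    if (epoch < n_epochs - 1 && t >= breaks[epoch]) {
      List act = actions[epoch];
      IntegerVector from = act["from"];
      IntegerVector to = act["to"];
      NumericVector frac = act["frac"];
      for (int a = 0; a < from.size(); ++a) {
        for (size_t l = 0; l < lin_deme.size(); ++l) {
          if (lin_deme[l] == from[a] &&
              (frac[a] >= 1.0 || unif_rand() < frac[a])) {
            lin_deme[l] = to[a];
          }
        }
      }
      ++epoch;
      load_epoch(epoch);
    }
    while (next_pending < order.size() &&
           samp_time[order[next_pending]] <= t) {
      lin_node.push_back(order[next_pending]);
      lin_deme.push_back(samp_deme[order[next_pending]]);
      ++next_pending;
    }
  }

  IntegerVector parent_out(n_nodes);
  NumericVector time_out(n_nodes);
  for (int i = 0; i < n_nodes; ++i) {
    parent_out[i] = parent[i] + 1;  // 1-based; 0 marks the root
    time_out[i] = node_time[i];
  }
  return List::create(_["parent"] = parent_out, _["time"] = time_out);
}

namespace {

// descendant-leaf bitmasks per node (requires <= 64 leaves; internal node
// ids strictly increase with time so a single forward pass suffices).
// parent is 1-based with 0 marking the root, as stored in genealogy objects.
void leaf_masks(const IntegerVector &parent, int n_leaves,
                std::vector<uint64_t> &mask) {
  int n_nodes = parent.size();
  mask.assign(n_nodes, 0);
  for (int i = 0; i < n_leaves; ++i) mask[i] = (uint64_t)1 << i;
  for (int i = 0; i < n_nodes; ++i) {
    if (parent[i] > 0) mask[parent[i] - 1] |= mask[i];
  }
}

inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

} // namespace

// Accumulate, over a collection of genealogies, the total length of branches
// whose descendant leaves are exactly {all Neandertal leaves} plus i European
// leaves (no chimp, no African), for i = 1..nE.  This is the branch-length
// (mutation-rate-free) expectation of the doubly conditioned spectrum.
//
// role: per leaf, 0 = chimp, 1 = neandertal, 2 = african, 3 = european.
// [[Rcpp::export]]
NumericVector branch_dcfs_weights_cpp(List trees, IntegerVector role) {
  int n_leaves = role.size();
  if (n_leaves > 64) stop("at most 64 sampled chromosomes are supported");
  uint64_t chimp = 0, nea = 0, afr = 0, eur = 0;
  for (int i = 0; i < n_leaves; ++i) {
    uint64_t b = (uint64_t)1 << i;
    switch (role[i]) {
      case 0: chimp |= b; break;
      case 1: nea |= b; break;
      case 2: afr |= b; break;
      case 3: eur |= b; break;
      default: stop("unknown leaf role");
    }
  }
  int nE = popcount64(eur);
  NumericVector w(nE);
  std::vector<uint64_t> mask;
  for (int k = 0; k < trees.size(); ++k) {
    List tr = trees[k];
    IntegerVector parent = tr["parent"];
    NumericVector time = tr["time"];
    leaf_masks(parent, n_leaves, mask);
    int n_nodes = parent.size();
    for (int i = 0; i < n_nodes; ++i) {
      if (parent[i] <= 0) continue;
      uint64_t m = mask[i];
      if ((m & nea) != nea) continue;       // must carry the Neandertal
      if (m & (chimp | afr)) continue;      // African keeps the chimp allele
      int ic = popcount64(m & eur);
      if (ic >= 1 && ic <= nE) w[ic - 1] += time[parent[i] - 1] - time[i];
    }
  }
  return w;
}

// ABBA / BABA branch weights for a four-taxon panel extracted from the
// sample: branches ancestral to exactly {Neandertal, chosen European}
// (ABBA) or {Neandertal, chosen African} (BABA), never the chimp.  Leaves
// outside the panel are ignored (marginalized), so larger panels reduce to
// a chosen chromosome each.
//
// eur_leaf / afr_leaf: 0-based leaf indices of the panel's European and
// African chromosome.
// [[Rcpp::export]]
NumericVector branch_abba_baba_cpp(List trees, IntegerVector role,
                                   int eur_leaf, int afr_leaf) {
  int n_leaves = role.size();
  if (n_leaves > 64) stop("at most 64 sampled chromosomes are supported");
  uint64_t chimp = 0, nea = 0;
  for (int i = 0; i < n_leaves; ++i) {
    uint64_t b = (uint64_t)1 << i;
    if (role[i] == 0) chimp |= b;
    if (role[i] == 1) nea |= b;
  }
  uint64_t e = (uint64_t)1 << eur_leaf;
  uint64_t a = (uint64_t)1 << afr_leaf;
  double abba = 0.0, baba = 0.0;
  std::vector<uint64_t> mask;
  for (int k = 0; k < trees.size(); ++k) {
    List tr = trees[k];
    IntegerVector parent = tr["parent"];
    NumericVector time = tr["time"];
    leaf_masks(parent, n_leaves, mask);
    int n_nodes = parent.size();
    for (int i = 0; i < n_nodes; ++i) {
      if (parent[i] <= 0) continue;
      uint64_t m = mask[i];
      if (m & chimp) continue;
      if ((m & nea) != nea) continue;
      bool has_e = (m & e) != 0, has_a = (m & a) != 0;
      double len = time[parent[i] - 1] - time[i];
      if (has_e && !has_a) abba += len;
      else if (has_a && !has_e) baba += len;
    }
  }
  return NumericVector::create(abba, baba);
}

// Frequency-weighted ABBA / BABA branch weights over the full African and
// European panels: a branch of length L carrying the Neandertal (never the
// chimp) with derived-allele frequencies xA among African and xE among
// European leaves contributes L * xE * (1 - xA) to ABBA and
// L * xA * (1 - xE) to BABA.  This equals the single-chromosome weights
// averaged over all (African, European) panel pairs and reduces Monte Carlo
// variance without changing the expectation.
// [[Rcpp::export]]
NumericVector branch_abba_baba_freq_cpp(List trees, IntegerVector role) {
  int n_leaves = role.size();
  if (n_leaves > 64) stop("at most 64 sampled chromosomes are supported");
  uint64_t chimp = 0, nea = 0, afr = 0, eur = 0;
  for (int i = 0; i < n_leaves; ++i) {
    uint64_t b = (uint64_t)1 << i;
    if (role[i] == 0) chimp |= b;
    if (role[i] == 1) nea |= b;
    if (role[i] == 2) afr |= b;
    if (role[i] == 3) eur |= b;
  }
  double nA = popcount64(afr), nE = popcount64(eur);
  if (nA < 1 || nE < 1) stop("panel needs African and European leaves");
  double abba = 0.0, baba = 0.0;
  std::vector<uint64_t> mask;
  for (int k = 0; k < trees.size(); ++k) {
    List tr = trees[k];
    IntegerVector parent = tr["parent"];
    NumericVector time = tr["time"];
    leaf_masks(parent, n_leaves, mask);
    int n_nodes = parent.size();
    for (int i = 0; i < n_nodes; ++i) {
      if (parent[i] <= 0) continue;
      uint64_t m = mask[i];
      if (m & chimp) continue;
      if ((m & nea) != nea) continue;
      double xa = popcount64(m & afr) / nA;
      double xe = popcount64(m & eur) / nE;
      double len = time[parent[i] - 1] - time[i];
      abba += len * xe * (1.0 - xa);
      baba += len * xa * (1.0 - xe);
    }
  }
  return NumericVector::create(abba, baba);
}

// Infinite-sites mutation dropping: Poisson(mu * branch length) mutations per
// branch; each mutation defines one biallelic site whose derived carriers are
// the branch's descendant leaves.  Returns a sites x leaves 0/1 matrix
// (0 = ancestral).
// [[Rcpp::export]]
IntegerMatrix drop_mutations_cpp(IntegerVector parent, NumericVector time,
                                 int n_leaves, double mu) {
  if (n_leaves > 64) stop("at most 64 sampled chromosomes are supported");
  std::vector<uint64_t> mask;
  leaf_masks(parent, n_leaves, mask);
  int n_nodes = parent.size();
  std::vector<uint64_t> site_mask;
  for (int i = 0; i < n_nodes; ++i) {
    if (parent[i] <= 0) continue;
    double len = time[parent[i] - 1] - time[i];
    int k = (len > 0.0) ? (int)R::rpois(mu * len) : 0;
    for (int s = 0; s < k; ++s) site_mask.push_back(mask[i]);
  }
  IntegerMatrix out((int)site_mask.size(), n_leaves);
  for (size_t s = 0; s < site_mask.size(); ++s)
    for (int j = 0; j < n_leaves; ++j)
      out((int)s, j) = (site_mask[s] >> j) & 1;
  return out;
}

// Total branch length of one genealogy (generations).
// [[Rcpp::export]]
double total_branch_length_cpp(IntegerVector parent, NumericVector time) {
  double s = 0.0;
  for (int i = 0; i < parent.size(); ++i)
    if (parent[i] > 0) s += time[parent[i] - 1] - time[i];
  return s;
}
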