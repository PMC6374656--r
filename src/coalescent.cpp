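// Coalescent simulation of microsatellites under strict single-step
// stepwise mutation on a fixed population tree, plus the summary-statistic
// kernels used to build ABC reference tables at scale.
//
// Branch indexing: a tree over P leaf populations has 2P-1 branches;
// 0..P-1 are leaves, branch P+j is created by merge event j (events sorted
// by ascending time).  Each branch carries its own diploid effective size.
// Coalescence within a branch of size N proceeds at rate k(k-1)/(4N) per
// generation for k lineages (continuous-time approximation).

#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

static const int ROOT_SIZE = 100; // repeat units at the root

struct GeneTree {
  std::vector<int> parent;
  std::vector<double> time;
};

// simulate the gene tree of one locus; copies = gene copies per leaf pop
static GeneTree sim_gene_tree(const std::vector<int>& copies,
                              const IntegerMatrix& merges,
                              const NumericVector& merge_times,
                              const NumericVector& branch_N) {
  const int P = copies.size();
  int S = 0;
  for (int i = 0; i < P; ++i) S += copies[i];
  GeneTree gt;
  gt.parent.assign(2 * S - 1, -1);
  gt.time.assign(2 * S - 1, 0.0);
  int next_node = S;

  // lineages per active branch
  std::vector<std::vector<int>> lin(2 * P - 1);
  int node = 0;
  for (int i = 0; i < P; ++i)
    for (int c = 0; c < copies[i]; ++c) lin[i].push_back(node++);

  std::vector<double> branch_start(2 * P - 1, 0.0);
  for (int j = 0; j < merges.nrow(); ++j) branch_start[P + j] = merge_times[j];

  // coalesce lineages of branch b from t0 to t1 (t1 may be +inf)
  auto coalesce = [&](int b, double t0, double t1) {
    double tcur = t0;
    double N = branch_N[b];
    while ((int)lin[b].size() >= 2) {
      double k = (double)lin[b].size();
      double rate = k * (k - 1.0) / (4.0 * N);
      double dt = R::rexp(1.0 / rate);
      if (tcur + dt >= t1) return;
      tcur += dt;
      int i = (int)(R::unif_rand() * lin[b].size());
      int j = (int)(R::unif_rand() * (lin[b].size() - 1));
      if (j >= i) ++j;
      int anc = next_node++;
      gt.parent[lin[b][i]] = anc;
      gt.parent[lin[b][j]] = anc;
      gt.time[anc] = tcur;
      if (i > j) std::swap(i, j);
      lin[b][i] = anc;
      lin[b].erase(lin[b].begin() + j);
    }
  };

  double tprev = 0.0;
  for (int j = 0; j < merges.nrow(); ++j) {
    double tj = merge_times[j];
    // advance every active branch to the event time
    for (int b = 0; b < 2 * P - 1; ++b)
      if (!lin[b].empty())
        coalesce(b, std::max(tprev, branch_start[b]), tj);
    int a = merges(j, 0), bb = merges(j, 1), nb = P + j;
    lin[nb].reserve(lin[a].size() + lin[bb].size());
    lin[nb].insert(lin[nb].end(), lin[a].begin(), lin[a].end());
    lin[nb].insert(lin[nb].end(), lin[bb].begin(), lin[bb].end());
    lin[a].clear(); lin[bb].clear();
    tprev = tj;
  }
  int root_branch = 2 * P - 2;
  coalesce(root_branch, std::max(tprev, branch_start[root_branch]),
           R_PosInf);
  if ((int)lin[root_branch].size() != 1)
    stop("internal error: unmerged lineages above the root");
  // pad: with S copies the tree has exactly 2S-1 nodes
  return gt;
}

// net +/-1 steps of m mutations
static inline int net_steps(int m) {
  if (m == 0) return 0;
  int up = (int)R::rbinom((double)m, 0.5);
  return 2 * up - m;
}

// allele sizes of the S sampled copies of one locus
static void locus_sizes(const GeneTree& gt, double mu, int S, int* out) {
  int n_nodes = 2 * S - 1;
  std::vector<int> size(n_nodes);
  size[n_nodes - 1] = ROOT_SIZE;
  for (int v = n_nodes - 2; v >= 0; --v) {
    double len = gt.time[gt.parent[v]] - gt.time[v];
    int m = (int)R::rpois(mu * len);
    size[v] = size[gt.parent[v]] + net_steps(m);
  }
  for (int v = 0; v < S; ++v) out[v] = size[v];
}

// [[Rcpp::export]]
IntegerMatrix cpp_sim_msat(IntegerVector sample_ind, IntegerMatrix merges,
                           NumericVector merge_times, NumericVector branch_N,
                           NumericVector mus) {
  const int P = sample_ind.size();
  std::vector<int> copies(P);
  int S = 0;
  for (int i = 0; i < P; ++i) { copies[i] = 2 * sample_ind[i]; S += copies[i]; }
  const int L = mus.size();
  IntegerMatrix out(S, L);
  for (int l = 0; l < L; ++l) {
    GeneTree gt = sim_gene_tree(copies, merges, merge_times, branch_N);
    locus_sizes(gt, mus[l], S, &out(0, l));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Summary statistics on an S x L matrix of allele sizes with pop labels

struct PopLocus {
  std::vector<int> alleles;            // sorted observed sizes (copies)
  std::vector<std::pair<int,double>> freq; // size -> frequency
  double het;                          // unbiased expected heterozygosity
  int k;                               // distinct alleles
  double var;                          // sample variance of sizes
  double M;                            // Garza-Williamson
};

static PopLocus pop_locus_stats(const int* sizes, const std::vector<int>& idx) {
  PopLocus pl;
  int n = idx.size();
  pl.alleles.resize(n);
  for (int i = 0; i < n; ++i) pl.alleles[i] = sizes[idx[i]];
  std::sort(pl.alleles.begin(), pl.alleles.end());
  double sum = 0, sumsq = 0;
  for (int a : pl.alleles) { sum += a; sumsq += (double)a * a; }
  double mean = sum / n;
  pl.var = n > 1 ? (sumsq - n * mean * mean) / (n - 1) : 0.0;
  double p2 = 0;
  pl.k = 0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && pl.alleles[j] == pl.alleles[i]) ++j;
    double p = (double)(j - i) / n;
    pl.freq.push_back(std::make_pair(pl.alleles[i], p));
    p2 += p * p;
    ++pl.k;
    i = j;
  }
  pl.het = n > 1 ? (1.0 - p2) * n / (n - 1.0) : 0.0;
  int range = pl.alleles[n - 1] - pl.alleles[0];
  pl.M = (double)pl.k / (range + 1);
  return pl;
}

static double lookup_freq(const PopLocus& pl, int a) {
  for (size_t i = 0; i < pl.freq.size(); ++i)
    if (pl.freq[i].first == a) return pl.freq[i].second;
  return -1.0;
}

// Nei GST-style pairwise FST averaged over loci (uncorrected gene diversity)
static double fst_pair(const std::vector<PopLocus>& pi,
                       const std::vector<PopLocus>& pj) {
  double HS = 0, HT = 0;
  int L = pi.size();
  for (int l = 0; l < L; ++l) {
    double hs_i = 0, hs_j = 0, ht = 0;
    for (size_t a = 0; a < pi[l].freq.size(); ++a)
      hs_i += pi[l].freq[a].second * pi[l].freq[a].second;
    for (size_t a = 0; a < pj[l].freq.size(); ++a)
      hs_j += pj[l].freq[a].second * pj[l].freq[a].second;
    // pooled mean frequencies over the union of alleles
    std::vector<std::pair<int,double>> pool;
    for (size_t a = 0; a < pi[l].freq.size(); ++a)
      pool.push_back(std::make_pair(pi[l].freq[a].first,
                                    pi[l].freq[a].second / 2.0));
    for (size_t a = 0; a < pj[l].freq.size(); ++a) {
      bool found = false;
      for (size_t b = 0; b < pool.size(); ++b)
        if (pool[b].first == pj[l].freq[a].first) {
          pool[b].second += pj[l].freq[a].second / 2.0;
          found = true; break;
        }
      if (!found)
        pool.push_back(std::make_pair(pj[l].freq[a].first,
                                      pj[l].freq[a].second / 2.0));
    }
    double pp2 = 0;
    for (size_t b = 0; b < pool.size(); ++b)
      pp2 += pool[b].second * pool[b].second;
    ht = 1.0 - pp2;
    HS += (1.0 - hs_i + 1.0 - hs_j) / 2.0;
    HT += ht;
  }
  HS /= L; HT /= L;
  if (HT <= 0) return 0.0;
  double f = (HT - HS) / HT;
  return f < 0 ? 0.0 : f;
}

// mean log-likelihood of pop i's diploid genotypes under pop j's frequencies
static double assign_loglik(const IntegerMatrix& sizes,
                            const std::vector<int>& idx_i,
                            const std::vector<PopLocus>& pj,
                            int nj_copies) {
  int n_ind = idx_i.size() / 2;
  int L = sizes.ncol();
  double floor_f = 1.0 / (2.0 * (nj_copies / 2) + 1.0);
  double total = 0.0;
  for (int ind = 0; ind < n_ind; ++ind) {
    double ll = 0.0;
    for (int l = 0; l < L; ++l) {
      int a = sizes(idx_i[2 * ind], l);
      int b = sizes(idx_i[2 * ind + 1], l);
      double pa = lookup_freq(pj[l], a); if (pa < 0) pa = floor_f;
      double pb = lookup_freq(pj[l], b); if (pb < 0) pb = floor_f;
      ll += (a == b) ? 2.0 * std::log(pa) : std::log(2.0 * pa * pb);
    }
    total += ll;
  }
  return total / n_ind;
}

// set: 1 = Beaumont (per pop: mean k, He, size variance),
//      2 = Cornuet-Miller (per pop: mean k, He, M; per unordered pair FST;
//          per ordered pair mean assignment log-likelihood)
// [[Rcpp::export]]
NumericVector cpp_msat_summaries(IntegerMatrix sizes, IntegerVector pop,
                                 int set) {
  int P = max(pop);
  int L = sizes.ncol();
  std::vector<std::vector<int>> idx(P);
  for (int i = 0; i < pop.size(); ++i) idx[pop[i] - 1].push_back(i);
  std::vector<std::vector<PopLocus>> st(P);
  for (int p = 0; p < P; ++p) {
    st[p].reserve(L);
    for (int l = 0; l < L; ++l)
      st[p].push_back(pop_locus_stats(&sizes(0, l), idx[p]));
  }
  std::vector<double> out;
  if (set == 1) {
    for (int p = 0; p < P; ++p) {
      double mk = 0, mh = 0, mv = 0;
      for (int l = 0; l < L; ++l) {
        mk += st[p][l].k; mh += st[p][l].het; mv += st[p][l].var;
      }
      out.push_back(mk / L); out.push_back(mh / L); out.push_back(mv / L);
    }
  } else {
    for (int p = 0; p < P; ++p) {
      double mk = 0, mh = 0, mm = 0;
      for (int l = 0; l < L; ++l) {
        mk += st[p][l].k; mh += st[p][l].het; mm += st[p][l].M;
      }
      out.push_back(mk / L); out.push_back(mh / L); out.push_back(mm / L);
    }
    for (int i = 0; i < P; ++i)
      for (int j = i + 1; j < P; ++j)
        out.push_back(fst_pair(st[i], st[j]));
    for (int i = 0; i < P; ++i)
      for (int j = 0; j < P; ++j) {
        if (i == j) continue;
        out.push_back(assign_loglik(sizes, idx[i], st[j],
                                    (int)idx[j].size()));
      }
  }
  return wrap(out);
}

// ---------------------------------------------------------------------------
// ABC reference table: draw parameters from the priors, simulate, summarise.
// Columns: merge times (P-1), branch sizes (1 if shared_N else 2P-1),
// mean mutation rate, then Beaumont stats, then Cornuet-Miller stats.

// [[Rcpp::export]]
NumericMatrix cpp_abc_table(int n_sims, IntegerVector sample_ind,
                            IntegerMatrix merges, int n_loci,
                            double n_min, double n_max,
                            double t_min, double t_max,
                            bool shared_N) {
  const int P = sample_ind.size();
  const int n_merge = merges.nrow();
  const int n_branch = 2 * P - 1;
  const int nN = shared_N ? 1 : n_branch;
  const int n_par = n_merge + nN + 1;
  const int nb = 3 * P;
  const int ncm = 3 * P + P * (P - 1) / 2 + P * (P - 1);
  NumericMatrix out(n_sims, n_par + nb + ncm);

  std::vector<int> copies(P);
  for (int i = 0; i < P; ++i) copies[i] = 2 * sample_ind[i];

  NumericVector merge_times(n_merge), branch_N(n_branch), mus(n_loci);
  IntegerVector pop(std::accumulate(copies.begin(), copies.end(), 0));
  {
    int v = 0;
    for (int i = 0; i < P; ++i)
      for (int c = 0; c < copies[i]; ++c) pop[v++] = i + 1;
  }

  for (int s = 0; s < n_sims; ++s) {
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
    // merge times: uniform integers, resampled until tree-ordered
    for (;;) {
      for (int j = 0; j < n_merge; ++j)
        merge_times[j] = std::floor(R::runif(t_min, t_max + 1.0));
      bool ok = true;
      for (int j = 0; j < n_merge && ok; ++j)
        for (int c = 0; c < 2; ++c) {
          int child = merges(j, c);
          if (child >= P && merge_times[child - P] >= merge_times[j])
            { ok = false; break; }
        }
      if (ok) break;
    }
    if (shared_N) {
      double N = std::floor(R::runif(n_min, n_max + 1.0));
      for (int b = 0; b < n_branch; ++b) branch_N[b] = N;
    } else {
      for (int b = 0; b < n_branch; ++b)
        branch_N[b] = std::floor(R::runif(n_min, n_max + 1.0));
    }
    double log_mu_bar = R::runif(-4.0, -3.0);
    for (int l = 0; l < n_loci; ++l) {
      double lm = R::runif(log_mu_bar - 1.0, log_mu_bar + 1.0);
      if (lm < -5.0) lm = -5.0;
      if (lm > -2.0) lm = -2.0;
      mus[l] = std::pow(10.0, lm);
    }
    IntegerMatrix sizes = cpp_sim_msat(sample_ind, merges, merge_times,
                                       branch_N, mus);
    NumericVector sb = cpp_msat_summaries(sizes, pop, 1);
    NumericVector sc = cpp_msat_summaries(sizes, pop, 2);
    int c = 0;
    for (int j = 0; j < n_merge; ++j) out(s, c++) = merge_times[j];
    if (shared_N) out(s, c++) = branch_N[0];
    else for (int b = 0; b < n_branch; ++b) out(s, c++) = branch_N[b];
    out(s, c++) = std::pow(10.0, log_mu_bar);
    for (int k = 0; k < nb; ++k) out(s, c++) = sb[k];
    for (int k = 0; k < ncm; ++k) out(s, c++) = sc[k];
  }
  return out;
}
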