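// Structured coalescent for three populations with divergence and admixture.
//
// Conventions (ms-style scaling):
//   * time runs backward from the present in units of 4*Ne generations;
//   * within a population of k lineages the total coalescence rate is
//     k*(k-1) (pairwise rate 2 per unit time);
//   * mutations fall on the genealogy at rate theta per lineage per unit
//     time (infinite sites), so E[S] = theta * a_n for a panmictic sample;
//   * a migration epoch with rate M = 4Nm moves each lineage of the focal
//     (backward) population to the destination at rate M per unit time;
//   * a pulse moves each lineage of the focal population independently
//     with probability F at the event time.
//
// All event containers use BACKWARD-time semantics; the R layer translates
// the forward-time model conventions into these.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Breakpoint {
  double time;
  int kind;   // 0 = rate change only, 1 = merge, 2 = pulse
  int idx;    // row in merges / pulses
};

struct Tree {
  std::vector<double> node_time;
  std::vector<int> left, right;  // children (-1 for leaves)
  int root;
  int n_leaves;
};

// Simulate one genealogy under the demography. Populations are 1-based.
Tree sim_tree(const NumericMatrix& merges,   // time, from, to
              const NumericMatrix& epochs,   // start, end, pop, dest, rate
              const NumericMatrix& pulses,   // time, pop, dest, prob
              const IntegerVector& nseq) {   // per-population sample sizes
  const int npop = nseq.size();
  int n = 0;
  for (int p = 0; p < npop; ++p) n += nseq[p];

  Tree tr;
  tr.n_leaves = n;
  tr.node_time.assign(2 * n - 1, 0.0);
  tr.left.assign(2 * n - 1, -1);
  tr.right.assign(2 * n - 1, -1);

  std::vector<int> pop(2 * n - 1, 0);
  std::vector<int> active;
  active.reserve(n);
  {
    int id = 0;
    for (int p = 0; p < npop; ++p)
      for (int i = 0; i < nseq[p]; ++i) { pop[id] = p + 1; active.push_back(id); ++id; }
  }

  std::vector<Breakpoint> bps;
  for (int i = 0; i < merges.nrow(); ++i) bps.push_back({merges(i, 0), 1, i});
  for (int i = 0; i < pulses.nrow(); ++i) bps.push_back({pulses(i, 0), 2, i});
  for (int i = 0; i < epochs.nrow(); ++i) {
    bps.push_back({epochs(i, 0), 0, i});
    bps.push_back({epochs(i, 1), 0, i});
  }
  std::stable_sort(bps.begin(), bps.end(),
                   [](const Breakpoint& a, const Breakpoint& b) { return a.time < b.time; });

  double t = 0.0;
  std::size_t bp = 0;
  int next_node = n;
  std::vector<int> kcount(npop + 1, 0);

  while ((int)active.size() > 1) {
    std::fill(kcount.begin(), kcount.end(), 0);
    for (int id : active) ++kcount[pop[id]];

    double crate = 0.0;
    for (int p = 1; p <= npop; ++p) crate += (double)kcount[p] * (kcount[p] - 1);

    double mrate = 0.0;
    for (int i = 0; i < epochs.nrow(); ++i)
      if (epochs(i, 0) <= t && t < epochs(i, 1))
        mrate += kcount[(int)epochs(i, 2)] * epochs(i, 4);

    double tot = crate + mrate;
    double tnext = (bp < bps.size()) ? bps[bp].time : R_PosInf;

    if (tot <= 0.0) {
      if (!R_FINITE(tnext))
        stop("demography leaves isolated lineages with no remaining events");
      t = tnext;
    } else {
      double dt = R::rexp(1.0 / tot);
      if (t + dt < tnext) {
        t += dt;
        double u = R::runif(0.0, tot);
        if (u < crate) {
          // coalescence: choose population weighted by k*(k-1)
          double acc = 0.0;
          int cp = 1;
          for (int p = 1; p <= npop; ++p) {
            acc += (double)kcount[p] * (kcount[p] - 1);
            if (u < acc) { cp = p; break; }
          }
          // choose two distinct lineages in cp
          std::vector<int> pos;
          for (std::size_t i = 0; i < active.size(); ++i)
            if (pop[active[i]] == cp) pos.push_back((int)i);
          int a = (int)(R::unif_rand() * pos.size());
          if (a >= (int)pos.size()) a = (int)pos.size() - 1;
          int b = (int)(R::unif_rand() * (pos.size() - 1));
          if (b >= (int)pos.size() - 1) b = (int)pos.size() - 2;
          if (b >= a) ++b;
          int ia = pos[a], ib = pos[b];
          if (ia > ib) std::swap(ia, ib);
          int ca = active[ia], cb = active[ib];
          int anc = next_node++;
          tr.node_time[anc] = t;
          tr.left[anc] = ca;
          tr.right[anc] = cb;
          pop[anc] = cp;
          active[ia] = anc;
          active.erase(active.begin() + ib);
        } else {
          // migration: choose epoch weighted by k[pop]*rate, move one lineage
          double target = u - crate;
          double acc = 0.0;
          for (int i = 0; i < epochs.nrow(); ++i) {
            if (!(epochs(i, 0) <= t && t < epochs(i, 1))) continue;
            int p = (int)epochs(i, 2);
            acc += kcount[p] * epochs(i, 4);
            if (target < acc) {
              std::vector<int> pos;
              for (int id : active) if (pop[id] == p) pos.push_back(id);
              int j = (int)(R::unif_rand() * pos.size());
              if (j >= (int)pos.size()) j = (int)pos.size() - 1;
              pop[pos[j]] = (int)epochs(i, 3);
              break;
            }
          }
        }
        continue;
      }
      t = tnext;
    }

    // apply every breakpoint scheduled at this time
    while (bp < bps.size() && bps[bp].time <= t) {
      const Breakpoint& e = bps[bp];
      if (e.kind == 1) {
        int from = (int)merges(e.idx, 1), to = (int)merges(e.idx, 2);
        for (int id : active) if (pop[id] == from) pop[id] = to;
      } else if (e.kind == 2) {
        int from = (int)pulses(e.idx, 1), to = (int)pulses(e.idx, 2);
        double pr = pulses(e.idx, 3);
        for (int id : active)
          if (pop[id] == from && R::unif_rand() < pr) pop[id] = to;
      }
      ++bp;
    }
  }

  tr.root = active[0];
  tr.node_time[tr.root] = tr.node_time[tr.root]; // root time already set
  return tr;
}

// parents from children
std::vector<int> parents_of(const Tree& tr) {
  std::vector<int> par(tr.node_time.size(), -1);
  for (std::size_t v = 0; v < tr.node_time.size(); ++v) {
    if (tr.left[v] >= 0) par[tr.left[v]] = (int)v;
    if (tr.right[v] >= 0) par[tr.right[v]] = (int)v;
  }
  return par;
}

// Drop infinite-sites mutations on the tree; returns sites x n 0/1 matrix.
IntegerMatrix mutate_tree(const Tree& tr, double theta) {
  const int n = tr.n_leaves;
  std::vector<int> par = parents_of(tr);
  const int nn = (int)tr.node_time.size();

  std::vector<double> cum(nn, 0.0);
  double L = 0.0;
  for (int v = 0; v < nn; ++v) {
    double len = (par[v] >= 0) ? tr.node_time[par[v]] - tr.node_time[v] : 0.0;
    L += len;
    cum[v] = L;
  }

  int S = (L > 0.0) ? (int)R::rpois(theta * L) : 0;
  IntegerMatrix out(S, n);
  std::vector<int> stack;
  for (int s = 0; s < S; ++s) {
    double x = R::unif_rand() * L;
    int v = (int)(std::lower_bound(cum.begin(), cum.end(), x) - cum.begin());
    if (v >= nn) v = nn - 1;
    stack.clear();
    stack.push_back(v);
    while (!stack.empty()) {
      int w = stack.back(); stack.pop_back();
      if (tr.left[w] < 0) out(s, w) = 1;
      else { stack.push_back(tr.left[w]); stack.push_back(tr.right[w]); }
    }
  }
  return out;
}

inline bool informative_pair(int ci, int ni, int cj, int nj) {
  int cc = ci + cj;
  return cc > 0 && cc < ni + nj;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_sim_locus")]]
IntegerMatrix cpp_sim_locus(NumericMatrix merges, NumericMatrix epochs,
                            NumericMatrix pulses, IntegerVector nseq,
                            double theta) {
  Tree tr = sim_tree(merges, epochs, pulses, nseq);
  return mutate_tree(tr, theta);
}

// Per-locus Wakeley-Hey category statistics, full 13-entry layout:
// fixed/shared/private for pairs (1,2),(1,3),(2,3); S1,S2,S3; S_total.
// [[Rcpp::export(name = ".cpp_locus_stats")]]
NumericVector cpp_locus_stats(IntegerMatrix sites, IntegerVector nseq) {
  const int S = sites.nrow();
  const int n1 = nseq[0], n2 = nseq[1], n3 = nseq[2];
  int off2 = n1, off3 = n1 + n2, ntot = n1 + n2 + n3;

  int fixed[3] = {0, 0, 0}, shared[3] = {0, 0, 0}, priv[3] = {0, 0, 0},
      denom[3] = {0, 0, 0};
  int spop[3] = {0, 0, 0}, stot = 0;

  for (int s = 0; s < S; ++s) {
    int c1 = 0, c2 = 0, c3 = 0;
    for (int j = 0; j < n1; ++j) c1 += sites(s, j);
    for (int j = 0; j < n2; ++j) c2 += sites(s, off2 + j);
    for (int j = 0; j < n3; ++j) c3 += sites(s, off3 + j);
    bool p1 = c1 > 0 && c1 < n1, p2 = c2 > 0 && c2 < n2, p3 = c3 > 0 && c3 < n3;
    if (p1) ++spop[0];
    if (p2) ++spop[1];
    if (p3) ++spop[2];
    int ct = c1 + c2 + c3;
    if (ct > 0 && ct < ntot) ++stot;

    const int ci[3] = {c1, c1, c2}, cj[3] = {c2, c3, c3};
    const int ni[3] = {n1, n1, n2}, nj[3] = {n2, n3, n3};
    const bool pi[3] = {p1, p1, p2}, pj[3] = {p2, p3, p3};
    for (int k = 0; k < 3; ++k) {
      if (!informative_pair(ci[k], ni[k], cj[k], nj[k])) continue;
      ++denom[k];
      if (pi[k] && pj[k]) ++shared[k];
      else if (pi[k] || pj[k]) ++priv[k];
      else ++fixed[k];  // both monomorphic, necessarily for different alleles
    }
  }

  NumericVector out(13);
  for (int k = 0; k < 3; ++k) {
    double d = denom[k] > 0 ? (double)denom[k] : 1.0;
    out[3 * k] = denom[k] > 0 ? fixed[k] / d : 0.0;
    out[3 * k + 1] = denom[k] > 0 ? shared[k] / d : 0.0;
    out[3 * k + 2] = denom[k] > 0 ? priv[k] / d : 0.0;
  }
  out[9] = spop[0]; out[10] = spop[1]; out[11] = spop[2];
  out[12] = stot;
  return out;
}

// Simulate n_loci independent loci and return the n_loci x 13 per-locus
// statistic matrix (the hot path for reference-table construction).
// [[Rcpp::export(name = ".cpp_sim_locus_stats")]]
NumericMatrix cpp_sim_locus_stats(NumericMatrix merges, NumericMatrix epochs,
                                  NumericMatrix pulses, IntegerVector nseq,
                                  double theta, int n_loci) {
  NumericMatrix out(n_loci, 13);
  for (int l = 0; l < n_loci; ++l) {
    Tree tr = sim_tree(merges, epochs, pulses, nseq);
    IntegerMatrix sites = mutate_tree(tr, theta);
    NumericVector st = cpp_locus_stats(sites, nseq);
    for (int j = 0; j < 13; ++j) out(l, j) = st[j];
  }
  return out;
}

// Simulate n_loci loci and return the list of site matrices.
// [[Rcpp::export(name = ".cpp_sim_loci")]]
List cpp_sim_loci(NumericMatrix merges, NumericMatrix epochs,
                  NumericMatrix pulses, IntegerVector nseq, double theta,
                  int n_loci) {
  List out(n_loci);
  for (int l = 0; l < n_loci; ++l) {
    Tree tr = sim_tree(merges, epochs, pulses, nseq);
    out[l] = mutate_tree(tr, theta);
  }
  return out;
}
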