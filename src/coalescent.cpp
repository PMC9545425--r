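#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Backward-in-time Kingman coalescent over a set of demes with a fixed event
// schedule (population merges, pulse admixtures, size changes), conditioned on
// exactly one segregating site per locus: a single mutation is placed uniformly
// at random on the total branch length of each gene tree, so every emitted SNP
// is polymorphic in the pooled sample by construction.
//
// Conventions:
//  - time is continuous, in generations, increasing into the past; t = 0 is the
//    sampling time;
//  - demes are 0-based indices over the extant populations; ancestral branches
//    are represented by the deme that "continues" after a merge;
//  - within a deme of diploid size N, k lineages coalesce at rate k(k-1)/(4N).
//
// Event encoding (rows of `events`, sorted by time, ties in row order):
//   col 0: time (generations)
//   col 1: type: 0 = merge (all lineages in deme a move to deme b),
//                1 = admix (each lineage in deme a moves to deme b with
//                    probability r, else to deme c),
//                2 = size change (deme a's diploid size becomes N)
//   col 2: a, col 3: b, col 4: c (deme indices; unused slots = -1)
//   col 5: r (admixture probability; unused = 0)
//   col 6: N (new diploid size; unused = 0)
//
// Uses R's RNG (unif_rand / exp_rand) so set.seed() in R governs all draws.

namespace {

struct Lineage {
  int deme;
  double birth;               // time the lineage came into existence
  std::vector<int> leaves;    // 0-based haploid sample indices below it
};

struct Branch {
  double length;
  std::vector<int> leaves;
};

}  // namespace

// Simulate `n_loci` independent gene trees and return the derived-allele
// dosage matrix (diploid samples x loci) plus per-locus TMRCA.
// sample_sizes: number of DIPLOID samples per deme; pop_sizes: diploid N per
// deme at time 0.
// [[Rcpp::export(name = ".sim_loci_cpp")]]
List sim_loci_cpp(int n_loci, IntegerVector sample_sizes, NumericVector pop_sizes,
                  NumericMatrix events) {
  const int n_demes = sample_sizes.size();
  if (pop_sizes.size() != n_demes)
    stop("sample_sizes and pop_sizes must have the same length");
  int n_dip = 0;
  for (int d = 0; d < n_demes; ++d) n_dip += sample_sizes[d];
  const int n_hap = 2 * n_dip;
  const int n_ev = events.nrow();

  IntegerMatrix dosage(n_dip, n_loci);
  NumericVector tmrca(n_loci);

  RNGScope scope;

  for (int locus = 0; locus < n_loci; ++locus) {
    std::vector<double> N(pop_sizes.begin(), pop_sizes.end());
    std::vector<Lineage> act;
    act.reserve(n_hap);
    {
      int idx = 0;
      for (int d = 0; d < n_demes; ++d)
        for (int s = 0; s < 2 * sample_sizes[d]; ++s) {
          Lineage L;
          L.deme = d;
          L.birth = 0.0;
          L.leaves.push_back(idx++);
          act.push_back(L);
        }
    }
    std::vector<Branch> branches;
    branches.reserve(n_hap * 2);

    double t = 0.0;
    int ev = 0;
    std::vector<int> kcount(n_demes);

    while ((int)act.size() > 1) {
      std::fill(kcount.begin(), kcount.end(), 0);
      for (const Lineage& L : act) kcount[L.deme]++;

      double rate_tot = 0.0;
      for (int d = 0; d < n_demes; ++d) {
        if (kcount[d] >= 2) {
          if (N[d] <= 0.0)
            stop("lineages present in a deme with non-positive size");
          rate_tot += kcount[d] * (kcount[d] - 1) / (4.0 * N[d]);
        }
      }
      double t_next_ev = (ev < n_ev) ? events(ev, 0) : R_PosInf;
      double t_coal = (rate_tot > 0.0) ? t + exp_rand() / rate_tot : R_PosInf;

      if (t_coal < t_next_ev) {
        // choose deme proportional to its coalescence rate
        double u = unif_rand() * rate_tot, acc = 0.0;
        int deme = -1;
        for (int d = 0; d < n_demes; ++d) {
          if (kcount[d] >= 2) {
            acc += kcount[d] * (kcount[d] - 1) / (4.0 * N[d]);
            if (u <= acc) { deme = d; break; }
          }
        }
        if (deme < 0) deme = n_demes - 1;
        // choose an unordered pair uniformly within the deme
        int k = kcount[deme];
        int i1 = (int)(unif_rand() * k); if (i1 >= k) i1 = k - 1;
        int i2 = (int)(unif_rand() * (k - 1)); if (i2 >= k - 1) i2 = k - 2;
        if (i2 >= i1) i2++;
        int a = -1, b = -1, seen = 0;
        for (int i = 0; i < (int)act.size(); ++i) {
          if (act[i].deme == deme) {
            if (seen == i1) a = i;
            if (seen == i2) b = i;
            seen++;
          }
        }
        t = t_coal;
        Branch ba; ba.length = t - act[a].birth; ba.leaves = act[a].leaves;
        Branch bb; bb.length = t - act[b].birth; bb.leaves = act[b].leaves;
        branches.push_back(std::move(ba));
        branches.push_back(std::move(bb));
        Lineage par;
        par.deme = deme;
        par.birth = t;
        par.leaves.reserve(act[a].leaves.size() + act[b].leaves.size());
        par.leaves.insert(par.leaves.end(), act[a].leaves.begin(), act[a].leaves.end());
        par.leaves.insert(par.leaves.end(), act[b].leaves.begin(), act[b].leaves.end());
        if (a < b) std::swap(a, b);      // erase higher index first
        act.erase(act.begin() + a);
        act.erase(act.begin() + b);
        act.push_back(std::move(par));
      } else if (R_finite(t_next_ev)) {
        t = t_next_ev;
        int type = (int)events(ev, 1);
        int A = (int)events(ev, 2), B = (int)events(ev, 3), C = (int)events(ev, 4);
        if (type == 0) {                 // merge: A -> B
          for (Lineage& L : act) if (L.deme == A) L.deme = B;
          N[A] = -1.0;                   // A no longer exists
        } else if (type == 1) {          // admix: A -> B w.p. r else C
          double r = events(ev, 5);
          for (Lineage& L : act)
            if (L.deme == A) L.deme = (unif_rand() < r) ? B : C;
          N[A] = -1.0;
        } else if (type == 2) {          // size change
          N[A] = events(ev, 6);
        } else {
          stop("unknown event type");
        }
        ev++;
      } else {
        stop("lineages cannot coalesce: scenario does not reach a common ancestor");
      }
    }
    tmrca[locus] = t;

    // place one mutation uniformly on the total branch length
    double total = 0.0;
    for (const Branch& b : branches) total += b.length;
    double u = unif_rand() * total, acc = 0.0;
    int hit = (int)branches.size() - 1;
    for (int i = 0; i < (int)branches.size(); ++i) {
      acc += branches[i].length;
      if (u <= acc) { hit = i; break; }
    }
    // haploid leaves below the mutated branch carry the derived allele;
    // diploid dosage pairs haplotypes (2j, 2j+1)
    for (int leaf : branches[hit].leaves) dosage(leaf / 2, locus) += 1;
  }

  return List::create(_["dosage"] = dosage, _["tmrca"] = tmrca);
}
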