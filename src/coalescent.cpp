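// Structured coalescent for a single RAD tag: two demes of constant relative
// size (nu1, nu2) merging into an ancestral deme of size 1 at the last epoch
// boundary.  Time is measured backwards from the present in units of 2*N_ref
// generations, so a lineage pair in a deme of relative size nu coalesces at
// rate 1/nu and each lineage migrates to the other deme at rate M = 2*N_ref*m
// while migration is active.  Uses R's RNG so set.seed() governs everything.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct Lineage {
  int deme;
  double birth;               // time the lineage came into existence
  std::vector<int> leaves;    // sample haplotypes (0-based) below this lineage
};

// epoch_end: ascending boundaries, last one = T_total (deme merge time).
// epoch_mig: per-lineage migration rate active while t < epoch_end[e].
// Returns a list with the per-cell branch lengths B[(d1, d2)] (matrix
// (k1+1) x (k2+1), cell = total length of branches subtending d1 pop-1 and
// d2 pop-2 haplotypes) and, if want_muts, integer carrier vectors for each
// Poisson-placed infinite-sites mutation (theta_tag/2 per unit branch time).
// [[Rcpp::export]]
List coal_tag_cpp(int k1, int k2, double nu1, double nu2,
                  NumericVector epoch_end, NumericVector epoch_mig,
                  double theta_tag, bool want_muts) {
  int n = k1 + k2;
  std::vector<Lineage> act;
  act.reserve(2 * n);
  for (int i = 0; i < k1; ++i) act.push_back({0, 0.0, {i}});
  for (int i = 0; i < k2; ++i) act.push_back({1, 0.0, {k1 + i}});

  NumericMatrix B(k1 + 1, k2 + 1);
  // closed (coalesced) branch segments, kept only when mutations are wanted
  std::vector<std::vector<int> > seg_leaves;
  std::vector<double> seg_len;

  int ne = epoch_end.size();
  int ep = 0;
  bool merged = false;
  double t = 0.0;
  double T_total = epoch_end[ne - 1];

  while ((int)act.size() > 1) {
    int c1 = 0, c2 = 0;
    for (size_t i = 0; i < act.size(); ++i) (act[i].deme == 0) ? ++c1 : ++c2;
    double rc1, rc2, rm;
    if (!merged) {
      rc1 = c1 * (c1 - 1) / 2.0 / nu1;
      rc2 = c2 * (c2 - 1) / 2.0 / nu2;
      rm  = epoch_mig[ep] * (c1 + c2);
    } else {
      rc1 = (c1 + c2) * (c1 + c2 - 1) / 2.0;  // ancestral size 1
      rc2 = 0.0; rm = 0.0;
    }
    double rate = rc1 + rc2 + rm;
    double dt = (rate > 0.0) ? R::rexp(1.0 / rate) : R_PosInf;
    if (!merged && t + dt > epoch_end[ep]) {
      t = epoch_end[ep];
      if (t >= T_total) { merged = true; for (size_t i = 0; i < act.size(); ++i) act[i].deme = 0; }
      else ++ep;
      continue;
    }
    t += dt;
    double u = R::unif_rand() * rate;
    if (u < rc1 + rc2) {
      int deme = (merged || u < rc1) ? 0 : 1;
      // pick an unordered pair uniformly within the deme
      std::vector<int> idx;
      for (size_t i = 0; i < act.size(); ++i)
        if (act[i].deme == deme) idx.push_back((int)i);
      int k = (int)idx.size();
      int a = (int)(R::unif_rand() * k); if (a >= k) a = k - 1;
      int b = (int)(R::unif_rand() * (k - 1)); if (b >= k - 1) b = k - 2;
      if (b >= a) ++b;
      int ia = idx[a], ib = idx[b];
      for (int which = 0; which < 2; ++which) {
        Lineage &L = which ? act[ib] : act[ia];
        double len = t - L.birth;
        if (len > 0) {
          int d1 = 0, d2 = 0;
          for (size_t q = 0; q < L.leaves.size(); ++q)
            (L.leaves[q] < k1) ? ++d1 : ++d2;
          B(d1, d2) += len;
          if (want_muts) { seg_leaves.push_back(L.leaves); seg_len.push_back(len); }
        }
      }
      Lineage par;
      par.deme = deme; par.birth = t;
      par.leaves = act[ia].leaves;
      par.leaves.insert(par.leaves.end(), act[ib].leaves.begin(), act[ib].leaves.end());
      if (ia < ib) { act.erase(act.begin() + ib); act.erase(act.begin() + ia); }
      else         { act.erase(act.begin() + ia); act.erase(act.begin() + ib); }
      act.push_back(par);
    } else {
      int j = (int)(R::unif_rand() * act.size());
      if (j >= (int)act.size()) j = (int)act.size() - 1;
      act[j].deme = 1 - act[j].deme;
    }
  }

  List out;
  out["branch"] = B;
  if (want_muts) {
    double tot = 0.0;
    for (size_t i = 0; i < seg_len.size(); ++i) tot += seg_len[i];
    int nmut = (tot > 0 && theta_tag > 0) ? (int)R::rpois(tot * theta_tag / 2.0) : 0;
    List muts(nmut);
    for (int m = 0; m < nmut; ++m) {
      double u = R::unif_rand() * tot, acc = 0.0;
      size_t pick = seg_len.size() - 1;
      for (size_t i = 0; i < seg_len.size(); ++i) {
        acc += seg_len[i];
        if (u <= acc) { pick = i; break; }
      }
      IntegerVector carriers(seg_leaves[pick].size());
      for (size_t q = 0; q < seg_leaves[pick].size(); ++q)
        carriers[q] = seg_leaves[pick][q] + 1;  // 1-based for R
      muts[m] = carriers;
    }
    out["mutations"] = muts;
  }
  return out;
}

// Accumulate mean branch-length spectra over many replicate tags; returns the
// per-cell sum and sum of squares across replicates (for Monte-Carlo SEs).
// When fold = true each replicate spectrum is folded onto minor-allele
// classes before accumulation, so the SEs are exact for the folded spectrum.
// [[Rcpp::export]]
List coal_branch_reps_cpp(int n_reps, int k1, int k2, double nu1, double nu2,
                          NumericVector epoch_end, NumericVector epoch_mig,
                          NumericVector epoch_mig_alt, double q_alt,
                          bool fold) {
  NumericMatrix s1(k1 + 1, k2 + 1), s2(k1 + 1, k2 + 1);
  int half2 = k1 + k2;  // fold line: 2*(i+j) vs k1+k2
  for (int r = 0; r < n_reps; ++r) {
    bool alt = (q_alt > 0.0) && (R::unif_rand() < q_alt);
    List res = coal_tag_cpp(k1, k2, nu1, nu2, epoch_end,
                            alt ? epoch_mig_alt : epoch_mig, 0.0, false);
    NumericMatrix B = res["branch"];
    if (fold) {
      NumericMatrix Bf(k1 + 1, k2 + 1);
      for (int i = 0; i <= k1; ++i)
        for (int j = 0; j <= k2; ++j) {
          int tot2 = 2 * (i + j);
          if (tot2 < half2) Bf(i, j) += B(i, j) + B(k1 - i, k2 - j);
          else if (tot2 == half2)
            Bf(i, j) += 0.5 * (B(i, j) + B(k1 - i, k2 - j));
        }
      B = Bf;
    }
    for (int i = 0; i <= k1; ++i)
      for (int j = 0; j <= k2; ++j) {
        s1(i, j) += B(i, j);
        s2(i, j) += B(i, j) * B(i, j);
      }
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["sum"] = s1, _["sumsq"] = s2, _["n"] = n_reps);
}
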