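#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

// Haplotype-group refinement along a chromosome. Group ids are remapped to a
// dense 0..k-1 range at every step, so ids never grow with walk length.
// Returns the pooled-sample EHH: sum over groups of C(c,2) / C(n,2).
static double refine_groups(std::vector<int>& g, const std::vector<int>& allele) {
  const int n = (int)g.size();
  std::unordered_map<long, int> remap;
  remap.reserve(n * 2);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    long key = ((long)g[i] << 1) | (long)allele[i];
    auto it = remap.find(key);
    if (it == remap.end()) {
      remap.emplace(key, k);
      g[i] = k++;
    } else {
      g[i] = it->second;
    }
  }
  std::vector<int> cnt(k, 0);
  for (int i = 0; i < n; ++i) cnt[g[i]]++;
  double pairs = 0.0;
  for (int c : cnt) pairs += (double)c * (double)(c - 1);
  return pairs / ((double)n * (double)(n - 1));
}

// Integrated EHH for every core on one chromosome, for target and reference
// panels jointly. Extension away from the core stops when the EHH of the
// pooled two-population sample first falls below `cutoff` (shared stopping:
// both populations' integrals end at the same extension), at the chromosome
// edge, or past `max_extend` bp from the core. Each inter-SNP step
// contributes a trapezoid of width min(gap, gap_cap) to each population's
// integral; the step at which pooled EHH crosses the cutoff is included.
// [[Rcpp::export]]
Rcpp::List xpehh_chrom_cpp(Rcpp::IntegerMatrix ht, Rcpp::IntegerMatrix hr,
                           Rcpp::NumericVector pos, double cutoff,
                           double max_extend, double gap_cap) {
  const int S = pos.size();
  const int nt = ht.nrow();
  const int nr = hr.nrow();
  const int np = nt + nr;
  Rcpp::NumericVector ihh_t(S), ihh_r(S);

  std::vector<int> at(nt), ar(nr), ap(np);

  for (int core = 0; core < S; ++core) {
    double area_t = 0.0, area_r = 0.0;
    for (int dir = -1; dir <= 1; dir += 2) {
      // identity is over [core..x] inclusive: groups start split by the
      // core SNP's own alleles (EHH at distance 0 is 1 by convention)
      std::vector<int> gt(nt), gr(nr), gp(np);
      for (int i = 0; i < nt; ++i) gt[i] = ht(i, core);
      for (int i = 0; i < nr; ++i) gr[i] = hr(i, core);
      for (int i = 0; i < nt; ++i) gp[i] = gt[i];
      for (int i = 0; i < nr; ++i) gp[nt + i] = gr[i];
      double et = 1.0, er = 1.0;
      double prev = 0.0;
      for (int j = core + dir; j >= 0 && j < S; j += dir) {
        double dist = std::fabs(pos[j] - pos[core]);
        if (dist > max_extend) break;
        for (int i = 0; i < nt; ++i) at[i] = ht(i, j);
        for (int i = 0; i < nr; ++i) ar[i] = hr(i, j);
        for (int i = 0; i < nt; ++i) ap[i] = at[i];
        for (int i = 0; i < nr; ++i) ap[nt + i] = ar[i];
        double et2 = refine_groups(gt, at);
        double er2 = refine_groups(gr, ar);
        double ep2 = refine_groups(gp, ap);
        double w = std::min(dist - prev, gap_cap);
        area_t += w * (et + et2) / 2.0;
        area_r += w * (er + er2) / 2.0;
        et = et2;
        er = er2;
        prev = dist;
        if (ep2 < cutoff || ep2 <= 0.0) break;
      }
    }
    ihh_t[core] = area_t;
    ihh_r[core] = area_r;
  }
  return Rcpp::List::create(Rcpp::Named("ihh_t") = ihh_t,
                            Rcpp::Named("ihh_r") = ihh_r);
}
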