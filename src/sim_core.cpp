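#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Batch meiosis: one recombinant gamete per row of `parents`, whose two
// columns give the row indices (0-based) of the parental haplotypes in
// `pop`. Crossover count per chromosome is Poisson in its genetic length;
// crossover positions are uniform in bp. Uses the R RNG, so results are
// reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix meiosis_batch_core(IntegerMatrix pop, IntegerMatrix parents,
                                 NumericVector pos, IntegerVector chrom_start,
                                 double genetic_length, double bp_length) {
  int n_gam = parents.nrow();
  int L = pop.ncol();
  int n_chrom = chrom_start.size() - 1;
  IntegerMatrix out(n_gam, L);
  std::vector<double> xo;
  for (int g = 0; g < n_gam; ++g) {
    int rA = parents(g, 0), rB = parents(g, 1);
    for (int c = 0; c < n_chrom; ++c) {
      int lo = chrom_start[c], hi = chrom_start[c + 1];
      int k = (int)R::rpois(genetic_length);
      int strand = unif_rand() < 0.5 ? 0 : 1;
      if (k == 0) {
        int src = strand ? rB : rA;
        for (int l = lo; l < hi; ++l) out(g, l) = pop(src, l);
      } else {
        xo.resize(k);
        for (int i = 0; i < k; ++i) xo[i] = unif_rand() * bp_length;
        std::sort(xo.begin(), xo.end());
        int seg = 0;
        for (int l = lo; l < hi; ++l) {
          while (seg < k && pos[l] > xo[seg]) { ++seg; strand ^= 1; }
          out(g, l) = strand ? pop(rB, l) : pop(rA, l);
        }
      }
    }
  }
  return out;
}
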