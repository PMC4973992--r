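#include <Rcpp.h>
using namespace Rcpp;

// Nested method-of-moments components for one locus, given per-sample
// allele-count sums accumulated by the caller. Group sizes are fixed by
// the design (labels are shuffled, never dropped), so degrees of freedom
// and EMS coefficients arrive precomputed.
struct DesignInfo {
  const IntegerVector &samp;          // gamete -> sample slot (0-based)
  const IntegerVector &cell_of_samp;  // sample -> cell
  const IntegerVector &line_of_cell;  // cell -> line
  const NumericVector &g_s;           // gametes per sample
  const NumericVector &n_c;           // gametes per cell
  const NumericVector &n_l;           // gametes per line
  const NumericVector &df;            // df_G, df_S, df_R, df_L
  const NumericVector &coef;          // cS, cRS, cR, cLS, cLR, cL
  double n_tot;
};

// Compute sigma_L (num) and the component total (den) for one locus from
// the gamete values of column col under row permutation perm.
static inline void locus_theta_parts(const int *ycol, const int *perm,
                                     int G, const DesignInfo &D,
                                     std::vector<double> &sampsum,
                                     std::vector<double> &cellsum,
                                     std::vector<double> &linesum,
                                     double &num, double &den) {
  std::fill(sampsum.begin(), sampsum.end(), 0.0);
  std::fill(cellsum.begin(), cellsum.end(), 0.0);
  std::fill(linesum.begin(), linesum.end(), 0.0);
  for (int g = 0; g < G; ++g) sampsum[D.samp[g]] += ycol[perm[g]];
  double U_S = 0.0;
  for (size_t s = 0; s < sampsum.size(); ++s) {
    U_S += sampsum[s] * sampsum[s] / D.g_s[s];
    cellsum[D.cell_of_samp[s]] += sampsum[s];
  }
  double U_C = 0.0, T = 0.0;
  for (size_t c = 0; c < cellsum.size(); ++c) {
    U_C += cellsum[c] * cellsum[c] / D.n_c[c];
    linesum[D.line_of_cell[c]] += cellsum[c];
  }
  double U_L = 0.0;
  for (size_t l = 0; l < linesum.size(); ++l) {
    U_L += linesum[l] * linesum[l] / D.n_l[l];
    T += linesum[l];
  }
  double U_T = T * T / D.n_tot;
  double SS_G = T - U_S;  // 0/1 data: sum of squares equals the sum
  double SS_S = U_S - U_C;
  double SS_R = U_C - U_L;
  double SS_L = U_L - U_T;
  double sG = D.df[0] > 0 ? SS_G / D.df[0] : 0.0;
  double sS = D.df[1] > 0 ? (SS_S / D.df[1] - sG) / D.coef[0] : 0.0;
  double sR = D.df[2] > 0 ?
    (SS_R / D.df[2] - sG - D.coef[1] * sS) / D.coef[2] : 0.0;
  double sL = (SS_L / D.df[3] - sG - D.coef[3] * sS -
               (D.df[2] > 0 ? D.coef[4] * sR : 0.0)) / D.coef[5];
  num = sL;
  den = sL + sR + sS + sG;
}

// Genome-wide maximum of the windowed theta (ratio of window sums of the
// between-line component over the component total) for the identity
// permutation or a shuffle. Windows span w consecutive loci within a
// chromosome; windows whose denominator is not positive are skipped.
static double max_windowed_theta(const std::vector<double> &num,
                                 const std::vector<double> &den,
                                 const IntegerVector &chrom, int w) {
  int L = num.size();
  double best = R_NegInf;
  int start = 0;
  while (start < L) {
    int end = start;
    while (end < L && chrom[end] == chrom[start]) ++end;
    int n = end - start;
    if (n >= w) {
      double sn = 0.0, sd = 0.0;
      for (int i = 0; i < w; ++i) { sn += num[start + i]; sd += den[start + i]; }
      if (sd > 0 && sn / sd > best) best = sn / sd;
      for (int i = w; i < n; ++i) {
        sn += num[start + i] - num[start + i - w];
        sd += den[start + i] - den[start + i - w];
        if (sd > 0 && sn / sd > best) best = sn / sd;
      }
    }
    start = end;
  }
  return best;
}

// [[Rcpp::export]]
NumericVector perm_max_theta_core(IntegerMatrix Y, IntegerVector samp,
                                  IntegerVector cell_of_samp,
                                  IntegerVector line_of_cell,
                                  NumericVector g_s, NumericVector n_c,
                                  NumericVector n_l, NumericVector df,
                                  NumericVector coef, IntegerVector chrom,
                                  int w, int nperm, int mode) {
  int G = Y.nrow(), L = Y.ncol();
  DesignInfo D{samp, cell_of_samp, line_of_cell, g_s, n_c, n_l, df, coef,
               (double)G};
  std::vector<double> sampsum(g_s.size()), cellsum(n_c.size()),
      linesum(n_l.size()), num(L), den(L);
  std::vector<int> perm(G), ind(G / 2);
  NumericVector out(nperm);
  for (int p = 0; p < nperm; ++p) {
    if (mode == 0) {  // gamete-level shuffle
      for (int i = 0; i < G; ++i) perm[i] = i;
      for (int i = G - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        std::swap(perm[i], perm[j]);
      }
    } else {          // individual-level shuffle keeps gamete pairs together
      int n = G / 2;
      for (int i = 0; i < n; ++i) ind[i] = i;
      for (int i = n - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        std::swap(ind[i], ind[j]);
      }
      for (int i = 0; i < n; ++i) {
        perm[2 * i] = 2 * ind[i];
        perm[2 * i + 1] = 2 * ind[i] + 1;
      }
    }
    for (int l = 0; l < L; ++l)
      locus_theta_parts(&Y(0, l), perm.data(), G, D, sampsum, cellsum,
                        linesum, num[l], den[l]);
    out[p] = max_windowed_theta(num, den, chrom, w);
  }
  return out;
}

// Observed per-locus components through the identical code path used by
// the permutations (identity permutation); returns a 2 x L matrix with
// rows (sigma_L, component total).
// [[Rcpp::export]]
NumericMatrix observed_theta_parts_core(IntegerMatrix Y, IntegerVector samp,
                                        IntegerVector cell_of_samp,
                                        IntegerVector line_of_cell,
                                        NumericVector g_s, NumericVector n_c,
                                        NumericVector n_l, NumericVector df,
                                        NumericVector coef) {
  int G = Y.nrow(), L = Y.ncol();
  DesignInfo D{samp, cell_of_samp, line_of_cell, g_s, n_c, n_l, df, coef,
               (double)G};
  std::vector<double> sampsum(g_s.size()), cellsum(n_c.size()),
      linesum(n_l.size());
  std::vector<int> perm(G);
  for (int i = 0; i < G; ++i) perm[i] = i;
  NumericMatrix out(2, L);
  double num, den;
  for (int l = 0; l < L; ++l) {
    locus_theta_parts(&Y(0, l), perm.data(), G, D, sampsum, cellsum, linesum,
                      num, den);
    out(0, l) = num;
    out(1, l) = den;
  }
  return out;
}
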