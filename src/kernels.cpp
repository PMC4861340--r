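#include <Rcpp.h>
using namespace Rcpp;

// Shared conventions for the Cox kernels:
//  - `ord` holds 0-based row indices of the data sorted by decreasing time, so
//    walking it front-to-back grows the risk set sample by sample.
//  - `time_s`, `status_s`, `woff_s` are already in that sorted order; `woff_s`
//    is exp(offset - max(offset)) so risk-set ratios are computed stably.
//  - Tied event times are handled by the Breslow convention: all members of a
//    tie group enter the risk sums before any event in the group contributes.

// Score U_j and observed information I_j at gamma_j = 0 for every genotype
// column j, given a fixed offset (through woff_s). This is the selection scan
// of componentwise boosting and the building block of the score tests.
// [[Rcpp::export]]
List cpp_score_info_all(IntegerMatrix X, IntegerVector ord,
                        NumericVector time_s, IntegerVector status_s,
                        NumericVector woff_s) {
  const int n = X.nrow(), L = X.ncol();
  NumericVector U(L), I(L);
  for (int j = 0; j < L; j++) {
    const int *xcol = &X(0, j);
    double s0 = 0.0, s1 = 0.0, s2 = 0.0, u = 0.0, info = 0.0;
    int i = 0;
    while (i < n) {
      int g = i;
      while (g < n && time_s[g] == time_s[i]) g++;
      for (int k = i; k < g; k++) {
        double w = woff_s[k];
        int x = xcol[ord[k]];
        s0 += w;
        if (x) { s1 += w * x; s2 += w * x * x; }
      }
      for (int k = i; k < g; k++) {
        if (status_s[k]) {
          double m = s1 / s0;
          u += xcol[ord[k]] - m;
          info += s2 / s0 - m * m;
        }
      }
      i = g;
    }
    U[j] = u;
    I[j] = info;
  }
  return List::create(_["U"] = U, _["I"] = I);
}

// One-dimensional Newton-Raphson Cox fit per genotype column with the linear
// predictor of the mandatory covariates as fixed offset: the `offset_fast`
// univariate screen. Genotypes take only the values 0/1/2, so exp(b * x) is a
// three-entry lookup and no per-sample exponentials are needed.
// [[Rcpp::export]]
List cpp_uni_cox_all(IntegerMatrix X, IntegerVector ord,
                     NumericVector time_s, IntegerVector status_s,
                     NumericVector woff_s, double tol, int maxit) {
  const int n = X.nrow(), L = X.ncol();
  NumericVector beta(L), se(L);
  LogicalVector conv(L);
  for (int j = 0; j < L; j++) {
    const int *xcol = &X(0, j);
    double b = 0.0, u = 0.0, info = 0.0;
    bool ok = false, degenerate = false;
    for (int it = 0; it < maxit; it++) {
      double eb1 = std::exp(b);
      double ebx[3] = {1.0, eb1, eb1 * eb1};
      double s0 = 0.0, s1 = 0.0, s2 = 0.0;
      u = 0.0; info = 0.0;
      int i = 0;
      while (i < n) {
        int g = i;
        while (g < n && time_s[g] == time_s[i]) g++;
        for (int k = i; k < g; k++) {
          int x = xcol[ord[k]];
          double w = woff_s[k] * ebx[x];
          s0 += w;
          if (x) { s1 += w * x; s2 += w * x * x; }
        }
        for (int k = i; k < g; k++) {
          if (status_s[k]) {
            double m = s1 / s0;
            u += xcol[ord[k]] - m;
            info += s2 / s0 - m * m;
          }
        }
        i = g;
      }
      if (info < 1e-10) { degenerate = (it == 0); break; }
      double delta = u / info;
      if (delta > 1.0) delta = 1.0;            // damp large steps
      if (delta < -1.0) delta = -1.0;
      b += delta;
      if (std::fabs(b) > 15.0) break;          // monotone likelihood
      if (std::fabs(delta) < tol) { ok = true; break; }
    }
    if (ok) {
      beta[j] = b;
      se[j] = 1.0 / std::sqrt(info);
      conv[j] = true;
    } else {
      beta[j] = NA_REAL;
      se[j] = NA_REAL;
      conv[j] = false;
      (void)degenerate;
    }
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["converged"] = conv);
}

// Same quantities as cpp_score_info_all, but laid out for the boosting loop:
// `Xt` holds the genotypes transposed (SNPs x samples) with samples already
// in decreasing-time order, so the per-sample risk-set updates stream through
// memory and vectorize across SNPs. `inv_s0` carries 1/(risk-set weight sum)
// at each position, evaluated at its tie group's end (Breslow).
// [[Rcpp::export]]
List cpp_boost_scan(IntegerMatrix Xt, NumericVector time_s,
                    IntegerVector status_s, NumericVector woff_s,
                    NumericVector inv_s0) {
  const int L = Xt.nrow(), n = Xt.ncol();
  NumericVector U(L), I(L);
  std::vector<double> s1(L, 0.0), s2(L, 0.0);
  double *u = REAL(U), *info = REAL(I);
  double *ps1 = s1.data(), *ps2 = s2.data();
  int i = 0;
  while (i < n) {
    int g = i;
    while (g < n && time_s[g] == time_s[i]) g++;
    for (int k = i; k < g; k++) {
      const int *xk = &Xt(0, k);
      const double w = woff_s[k];
      for (int j = 0; j < L; j++) {
        const double x = xk[j];
        ps1[j] += w * x;
        ps2[j] += w * x * x;
      }
    }
    for (int k = i; k < g; k++) {
      if (status_s[k]) {
        const int *xk = &Xt(0, k);
        const double inv = inv_s0[k];
        for (int j = 0; j < L; j++) {
          const double m = ps1[j] * inv;
          u[j] += xk[j] - m;
          info[j] += ps2[j] * inv - m * m;
        }
      }
    }
    i = g;
  }
  return List::create(_["U"] = U, _["I"] = I);
}

static inline int draw_genotype(double q0, double q1) {
  double u = unif_rand();
  return (u < q0) ? 0 : ((u < q1) ? 1 : 2);
}

// Block-correlated genotype generation: within each gene the first SNP is a
// fresh Binomial(2, maf) draw per subject; every later SNP copies the value of
// its left neighbor with probability p_within (p_boundary when it opens a new
// block) and otherwise draws fresh. Genes are mutually independent.
// [[Rcpp::export]]
IntegerMatrix cpp_sim_genotypes(int n, int n_genes, int blocks_per_gene,
                                int block_size, double maf,
                                double p_within, double p_boundary) {
  const int gene_size = blocks_per_gene * block_size;
  const int L = n_genes * gene_size;
  const double q0 = (1.0 - maf) * (1.0 - maf);
  const double q1 = q0 + 2.0 * maf * (1.0 - maf);
  IntegerMatrix G(n, L);
  GetRNGstate();
  for (int g = 0; g < n_genes; g++) {
    for (int s = 0; s < gene_size; s++) {
      int col = g * gene_size + s;
      int *cur = &G(0, col);
      if (s == 0) {
        for (int i = 0; i < n; i++) cur[i] = draw_genotype(q0, q1);
      } else {
        const int *prev = &G(0, col - 1);
        double p_copy = (s % block_size == 0) ? p_boundary : p_within;
        for (int i = 0; i < n; i++) {
          cur[i] = (unif_rand() < p_copy) ? prev[i] : draw_genotype(q0, q1);
        }
      }
    }
  }
  PutRNGstate();
  return G;
}
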