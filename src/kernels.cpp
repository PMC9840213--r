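#include <Rcpp.h>
using namespace Rcpp;

// Hot numerical kernels. Everything here consumes and returns plain dense
// doubles; all validation happens on the R side.

// Refill an existing matrix in place with dosages ~ Binomial(2, af), iid.
// One uniform per entry via the inverse CDF, consuming R's RNG stream in
// column-major order so results are reproducible given set.seed(). In-place
// refill lets long simulation loops reuse one allocation per scenario.
// [[Rcpp::export(name = ".fill_genotypes_cpp")]]
void fill_genotypes_cpp(NumericMatrix G, double af) {
  const double p0 = (1.0 - af) * (1.0 - af);
  const double p01 = p0 + 2.0 * af * (1.0 - af);
  double *g = REAL(G);
  const R_xlen_t N = (R_xlen_t)G.nrow() * G.ncol();
  for (R_xlen_t i = 0; i < N; i++) {
    const double u = unif_rand();
    g[i] = (u > p0) + (u > p01);
  }
}

// Draw a fresh n x m dosage matrix (same scheme as the in-place refill).
// [[Rcpp::export(name = ".sim_genotypes_cpp")]]
NumericMatrix sim_genotypes_cpp(int n, int m, double af) {
  NumericMatrix G(n, m);
  fill_genotypes_cpp(G, af);
  return G;
}

// Per-block sufficient statistics for per-SNP simple linear regression of a
// phenotype y on each dosage column: block-wise sums of g, g^2 and g*y
// (n_block x m), plus block-wise sums of y, y^2 and block sizes.
// A leave-one-block-out scan is then column totals minus the held-out
// block's row; the full-sample scan is the column totals themselves.
// [[Rcpp::export(name = ".block_suffstats_cpp")]]
List block_suffstats_cpp(NumericMatrix G, NumericVector y,
                         IntegerVector block, int n_block) {
  const int n = G.nrow(), m = G.ncol();
  NumericMatrix Sg(n_block, m), Sgg(n_block, m), Sgy(n_block, m);
  NumericVector sy(n_block), syy(n_block);
  IntegerVector nb(n_block);
  for (int i = 0; i < n; i++) {
    const int b = block[i] - 1;
    sy[b] += y[i];
    syy[b] += y[i] * y[i];
    nb[b] += 1;
  }
  for (int j = 0; j < m; j++) {
    const double *col = &G(0, j);
    double *sg = &Sg(0, j), *sgg = &Sgg(0, j), *sgy = &Sgy(0, j);
    for (int i = 0; i < n; i++) {
      const double g = col[i];
      const int b = block[i] - 1;
      sg[b] += g;
      sgg[b] += g * g;
      sgy[b] += g * y[i];
    }
  }
  return List::create(_["sg"] = Sg, _["sgg"] = Sgg, _["sgy"] = Sgy,
                      _["sy"] = sy, _["syy"] = syy, _["nb"] = nb);
}

// Accumulate weighted allele scores over a row subset, in place:
//   score[rows[i]] += sum_k G(rows[i], cols[k]) * w[k]
// rows and cols are 1-based. Nested P-value thresholds are scored
// incrementally: each call adds only the SNPs newly selected at the current
// threshold, and (for the jackknife) only over the held-out block's rows.
// [[Rcpp::export(name = ".accumulate_scores_cpp")]]
void accumulate_scores_cpp(NumericMatrix G, IntegerVector rows,
                           IntegerVector cols, NumericVector w,
                           NumericVector score) {
  const int nr = rows.size(), nc = cols.size();
  for (int k = 0; k < nc; k++) {
    const double *col = &G(0, cols[k] - 1);
    const double wk = w[k];
    for (int i = 0; i < nr; i++) {
      const int r = rows[i] - 1;
      score[r] += col[r] * wk;
    }
  }
}
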