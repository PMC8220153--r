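#include <Rcpp.h>
using namespace Rcpp;

// Genotype simulation and single-SNP regression kernels.  These are the two
// hot loops of the simulation engine: everything else in the package is
// ordinary vectorised R.  Both use R's RNG / are deterministic given the R
// seed, so replicates are reproducible from set.seed() alone.

// Draw an n x m dosage matrix under HWE and linkage equilibrium: column j is
// iid Binomial(2, maf[j]), realised as the sum of two Bernoulli allele draws.
// [[Rcpp::export(name = ".gen_genotypes_cpp")]]
NumericMatrix gen_genotypes_cpp(int n, NumericVector maf) {
  int m = maf.size();
  NumericMatrix G(n, m);
  for (int j = 0; j < m; ++j) {
    double p = maf[j];
    double *col = &G(0, j);
    for (int i = 0; i < n; ++i) {
      col[i] = (unif_rand() < p) + (unif_rand() < p);
    }
  }
  return G;
}

// Per-column simple linear regression of y on G[, j]: slope, its standard
// error (residual-variance based, df = n - 2) and the centred genotype sum
// of squares (zero flags a monomorphic column for the caller to drop).
// [[Rcpp::export(name = ".gwas_kernel_cpp")]]
List gwas_kernel_cpp(NumericMatrix G, NumericVector y) {
  int n = G.nrow(), m = G.ncol();
  double ybar = 0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double syy = 0;
  for (int i = 0; i < n; ++i) {
    double d = y[i] - ybar;
    syy += d * d;
  }
  NumericVector beta(m), se(m), sgg_out(m);
  for (int j = 0; j < m; ++j) {
    double *col = &G(0, j);
    double s1 = 0, s2 = 0, sxy = 0;
    for (int i = 0; i < n; ++i) {
      s1 += col[i];
      s2 += col[i] * col[i];
      sxy += col[i] * y[i];
    }
    double sgg = s2 - s1 * s1 / n;
    sgg_out[j] = sgg;
    if (sgg <= 0) {
      beta[j] = NA_REAL;
      se[j] = NA_REAL;
      continue;
    }
    double sgy = sxy - s1 * ybar;
    double b = sgy / sgg;
    double rss = syy - b * sgy;
    if (rss < 0) rss = 0;
    double s2e = rss / (n - 2);
    beta[j] = b;
    se[j] = sqrt(s2e / sgg);
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["sgg"] = sgg_out);
}

// Column means and sample standard deviations (denominator n - 1) in one
// pass, avoiding the large temporaries colSums(G * G) would allocate.
// [[Rcpp::export(name = ".col_moments_cpp")]]
List col_moments_cpp(NumericMatrix G) {
  int n = G.nrow(), m = G.ncol();
  NumericVector mu(m), sd(m);
  for (int j = 0; j < m; ++j) {
    double *col = &G(0, j);
    double s1 = 0, s2 = 0;
    for (int i = 0; i < n; ++i) {
      s1 += col[i];
      s2 += col[i] * col[i];
    }
    mu[j] = s1 / n;
    double ss = s2 - s1 * s1 / n;
    sd[j] = (ss > 0 && n > 1) ? sqrt(ss / (n - 1)) : 0.0;
  }
  return List::create(_["mean"] = mu, _["sd"] = sd);
}
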