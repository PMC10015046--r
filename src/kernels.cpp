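#include <Rcpp.h>
using namespace Rcpp;

// Dosages are stored as a raw matrix (individuals x SNPs), one byte per
// genotype in {0,1,2}. Columns (SNPs) are contiguous, so every kernel
// streams SNP blocks with per-SNP accumulators and never materialises a
// numeric copy of the full matrix.

// Small fast uniform stream (xoshiro256+) for the genotype draws. The state
// is seeded from R's RNG by the caller, so set.seed() still governs every
// draw; this only avoids per-draw R API call overhead in the hot loop.
namespace {
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97F4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline double next01() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return (double)(result >> 11) * 1.1102230246251565e-16; // 2^-53
  }
};
} // namespace

// Draw Hardy-Weinberg dosages for n individuals at M sites and accumulate the
// standardized genetic liability sum(beta_j * (d_ij - 2p_j)/sd_j) on the fly.
// One uniform per genotype, inversion on the HW class probabilities.
// [[Rcpp::export]]
List cpp_simulate_genotypes(NumericVector maf, NumericVector beta_std, int n,
                            NumericVector seed2) {
  const R_xlen_t M = maf.size();
  if (beta_std.size() != M) stop("maf and beta_std lengths differ");
  if (n < 1) stop("n must be >= 1");
  if (seed2.size() != 2) stop("seed2 must have two components");
  Xoshiro rng(((uint64_t)(uint32_t)seed2[0] << 32) ^ (uint64_t)(uint32_t)seed2[1]);
  RawMatrix dos(n, M);
  NumericVector g(n);
  for (R_xlen_t j = 0; j < M; ++j) {
    const double p = maf[j];
    const double q0 = (1.0 - p) * (1.0 - p);
    const double q01 = q0 + 2.0 * p * (1.0 - p);
    const double mu = 2.0 * p;
    const double sd = std::sqrt(2.0 * p * (1.0 - p));
    const double w = (beta_std[j] != 0.0 && sd > 0.0) ? beta_std[j] / sd : 0.0;
    Rbyte* col = &dos[(R_xlen_t)n * j];
    if (w != 0.0) {
      for (int i = 0; i < n; ++i) {
        const double u = rng.next01();
        const Rbyte d = (Rbyte)((u >= q0) + (u >= q01)); // branchless HW class
        col[i] = d;
        g[i] += w * ((double)d - mu);
      }
    } else {
      for (int i = 0; i < n; ++i) {
        const double u = rng.next01();
        col[i] = (Rbyte)((u >= q0) + (u >= q01));
      }
    }
  }
  return List::create(_["dosages"] = dos, _["g"] = g);
}

// Per-SNP OLS of a 0/1 phenotype on allele dosage for columns [j0, j1]
// (1-based, inclusive), restricted to `rows` (1-based; empty = all rows).
// Returns columns: beta, se, z, polymorphic. Monomorphic columns get
// beta = se = z = 0 (p = 1 downstream).
// [[Rcpp::export]]
NumericMatrix cpp_gwas_range(RawMatrix dos, NumericVector y, IntegerVector rows,
                             int j0, int j1) {
  const int ntot = dos.nrow();
  const R_xlen_t M = dos.ncol();
  if (j0 < 1 || j1 > M || j0 > j1) stop("invalid SNP column range");
  const bool subset = rows.size() > 0;
  const int n = subset ? (int)rows.size() : ntot;
  if ((int)y.size() != n) stop("phenotype length does not match rows");
  if (n < 3) stop("at least 3 individuals are required");
  double sy = 0.0, syy = 0.0;
  for (int i = 0; i < n; ++i) { sy += y[i]; syy += y[i] * y[i]; }
  const double Syy = syy - sy * sy / n;
  if (Syy <= 0) stop("phenotype is constant");

  const int nj = j1 - j0 + 1;
  NumericMatrix out(nj, 4);
  for (int jj = 0; jj < nj; ++jj) {
    const R_xlen_t j = (R_xlen_t)(j0 - 1 + jj);
    const Rbyte* col = &dos[(R_xlen_t)ntot * j];
    double sx = 0.0, sxx = 0.0, sxy = 0.0;
    if (subset) {
      for (int i = 0; i < n; ++i) {
        const double d = (double)col[rows[i] - 1];
        sx += d; sxx += d * d; sxy += d * y[i];
      }
    } else {
      for (int i = 0; i < n; ++i) {
        const double d = (double)col[i];
        sx += d; sxx += d * d; sxy += d * y[i];
      }
    }
    const double Sxx = sxx - sx * sx / n;
    if (Sxx <= 0) { // monomorphic in this sample
      out(jj, 0) = 0.0; out(jj, 1) = 0.0; out(jj, 2) = 0.0; out(jj, 3) = 0.0;
      continue;
    }
    const double Sxy = sxy - sx * sy / n;
    const double beta = Sxy / Sxx;
    double rss = Syy - beta * Sxy;
    if (rss < 0) rss = 0;
    const double sigma2 = rss / (n - 2);
    const double se = std::sqrt(sigma2 / Sxx);
    out(jj, 0) = beta;
    out(jj, 1) = se;
    out(jj, 2) = (se > 0) ? beta / se : 0.0;
    out(jj, 3) = 1.0;
  }
  return out;
}

// Weighted dosage sums: scores[i, t] = sum_j W[j, t] * dos[i, j], restricted
// to `rows` (1-based; empty = all). Zero weights are skipped, so sparse
// inclusion masks cost only the included columns.
// [[Rcpp::export]]
NumericMatrix cpp_score(RawMatrix dos, NumericMatrix W, IntegerVector rows) {
  const int ntot = dos.nrow();
  const R_xlen_t M = dos.ncol();
  if (W.nrow() != M) stop("weight matrix rows must equal SNP count");
  const int T = W.ncol();
  const bool subset = rows.size() > 0;
  const int n = subset ? (int)rows.size() : ntot;
  NumericMatrix out(n, T);
  for (R_xlen_t j = 0; j < M; ++j) {
    const Rbyte* col = &dos[(R_xlen_t)ntot * j];
    for (int t = 0; t < T; ++t) {
      const double w = W(j, t);
      if (w == 0.0) continue;
      double* sc = &out[(R_xlen_t)n * t];
      if (subset) {
        for (int i = 0; i < n; ++i) sc[i] += w * (double)col[rows[i] - 1];
      } else {
        for (int i = 0; i < n; ++i) sc[i] += w * (double)col[i];
      }
    }
  }
  return out;
}

// Row-subset copy of a raw dosage matrix (1-based indices).
// [[Rcpp::export]]
RawMatrix cpp_subset_rows(RawMatrix dos, IntegerVector rows) {
  const int ntot = dos.nrow();
  const R_xlen_t M = dos.ncol();
  const int n = rows.size();
  RawMatrix out(n, M);
  for (R_xlen_t j = 0; j < M; ++j) {
    const Rbyte* col = &dos[(R_xlen_t)ntot * j];
    Rbyte* oc = &out[(R_xlen_t)n * j];
    for (int i = 0; i < n; ++i) oc[i] = col[rows[i] - 1];
  }
  return out;
}

// Stack two raw dosage matrices with identical SNP columns.
// [[Rcpp::export]]
RawMatrix cpp_rbind_raw(RawMatrix a, RawMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  const R_xlen_t M = a.ncol();
  if (b.ncol() != M) stop("SNP counts differ");
  RawMatrix out(na + nb, M);
  for (R_xlen_t j = 0; j < M; ++j) {
    const Rbyte* ca = &a[(R_xlen_t)na * j];
    const Rbyte* cb = &b[(R_xlen_t)nb * j];
    Rbyte* oc = &out[(R_xlen_t)(na + nb) * j];
    for (int i = 0; i < na; ++i) oc[i] = ca[i];
    for (int i = 0; i < nb; ++i) oc[na + i] = cb[i];
  }
  return out;
}

// Per-SNP sample allele frequency (mean dosage / 2) over `rows`.
// [[Rcpp::export]]
NumericVector cpp_allele_freq(RawMatrix dos, IntegerVector rows) {
  const int ntot = dos.nrow();
  const R_xlen_t M = dos.ncol();
  const bool subset = rows.size() > 0;
  const int n = subset ? (int)rows.size() : ntot;
  NumericVector out(M);
  for (R_xlen_t j = 0; j < M; ++j) {
    const Rbyte* col = &dos[(R_xlen_t)ntot * j];
    double s = 0.0;
    if (subset) for (int i = 0; i < n; ++i) s += (double)col[rows[i] - 1];
    else        for (int i = 0; i < n; ++i) s += (double)col[i];
    out[j] = s / (2.0 * n);
  }
  return out;
}

// Integer copy of a SNP column block [j0, j1] for user-facing block access.
// [[Rcpp::export]]
IntegerMatrix cpp_block_int(RawMatrix dos, int j0, int j1) {
  const int n = dos.nrow();
  const R_xlen_t M = dos.ncol();
  if (j0 < 1 || j1 > M || j0 > j1) stop("invalid SNP column range");
  const int nj = j1 - j0 + 1;
  IntegerMatrix out(n, nj);
  for (int jj = 0; jj < nj; ++jj) {
    const Rbyte* col = &dos[(R_xlen_t)n * (R_xlen_t)(j0 - 1 + jj)];
    for (int i = 0; i < n; ++i) out(i, jj) = (int)col[i];
  }
  return out;
}
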