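#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the univariate animal model
//   y = X beta + Z a + e,  a ~ N(0, sigma2_a * H),  e ~ N(0, sigma2_e * I)
// parameterised by H^-1 = A^-1 (sparse, CSC slots) plus a dense correction
// block B = G^-1 - A22^-1 over the genotyped animals. w = H^-1 a is
// maintained incrementally, split into the sparse part (all animals) and a
// contiguous dense part (genotyped block), and refreshed periodically
// against floating-point drift.
//
// Location effects: flat prior on beta; a from its normal full conditional.
// Variances: scaled inverse chi-square full conditionals via the quadratic
// forms a'H^-1 a and e'e. Loop order fixed: beta columns, then animals in
// pedigree order. Uses R's RNG, so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".gibbs_ssgblup")]]
List gibbs_ssgblup(NumericVector y,
                   NumericMatrix X,
                   IntegerVector rec_animal,   // 1-based animal per record
                   IntegerVector Ap,           // dgCMatrix col pointers
                   IntegerVector Ai,           // dgCMatrix row indices (0-based)
                   NumericVector Ax,           // dgCMatrix values
                   NumericMatrix B,            // ng x ng correction (0x0 if none)
                   IntegerVector gidx,         // 1-based full positions of genotyped
                   int n_animals,
                   int n_iter, int burn_in, int thin,
                   double nu_a, double S_a, double nu_e, double S_e,
                   double sigma2_a0, double sigma2_e0,
                   bool fix_variances) {
  const int n_rec = y.size();
  const int p = X.ncol();
  const int ng = gidx.size();
  if (burn_in >= n_iter) stop("burn_in must be smaller than the chain length");

  // records grouped by animal (CSR-like)
  std::vector<int> cnt(n_animals, 0);
  for (int r = 0; r < n_rec; ++r) cnt[rec_animal[r] - 1]++;
  std::vector<int> rptr(n_animals + 1, 0);
  for (int i = 0; i < n_animals; ++i) rptr[i + 1] = rptr[i] + cnt[i];
  std::vector<int> ridx(n_rec);
  {
    std::vector<int> pos(rptr.begin(), rptr.end() - 1);
    for (int r = 0; r < n_rec; ++r) ridx[pos[rec_animal[r] - 1]++] = r;
  }

  // genotyped position of each animal, -1 if ungenotyped
  std::vector<int> gpos(n_animals, -1);
  for (int k = 0; k < ng; ++k) gpos[gidx[k] - 1] = k;

  // sparse columns of X (CG indicators are mostly zero)
  std::vector<int> xptr(p + 1, 0);
  std::vector<int> xrow;
  std::vector<double> xval;
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int r = 0; r < n_rec; ++r) {
      double v = X(r, j);
      if (v != 0.0) { xrow.push_back(r); xval.push_back(v); s += v * v; }
    }
    xptr[j + 1] = (int)xrow.size();
    if (s <= 0) stop("design column %d has zero sum of squares", j + 1);
    xtx[j] = s;
  }

  // diagonal of H^-1
  std::vector<double> hdiag(n_animals, 0.0);
  for (int j = 0; j < n_animals; ++j)
    for (int k = Ap[j]; k < Ap[j + 1]; ++k)
      if (Ai[k] == j) hdiag[j] += Ax[k];
  for (int k = 0; k < ng; ++k) hdiag[gidx[k] - 1] += B(k, k);

  std::vector<double> beta(p, 0.0), a(n_animals, 0.0);
  std::vector<double> wA(n_animals, 0.0); // sparse part of H^-1 a
  std::vector<double> wB(ng, 0.0);        // dense-correction part, genotyped order
  std::vector<double> r(n_rec);
  for (int i = 0; i < n_rec; ++i) r[i] = y[i];

  const double *Bp = ng ? &B(0, 0) : nullptr;
  double sigma2_a = sigma2_a0, sigma2_e = sigma2_e0;

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix samples(n_keep, 3); // iteration, sigma2_a, sigma2_e
  std::vector<double> beta_sum(p, 0.0), a_sum(n_animals, 0.0);
  int kept = 0;

  RNGScope scope;

  auto refresh_w = [&]() {
    std::fill(wA.begin(), wA.end(), 0.0);
    for (int j = 0; j < n_animals; ++j) {
      double aj = a[j];
      if (aj == 0.0) continue;
      for (int k = Ap[j]; k < Ap[j + 1]; ++k) wA[Ai[k]] += Ax[k] * aj;
    }
    std::fill(wB.begin(), wB.end(), 0.0);
    for (int kg = 0; kg < ng; ++kg) {
      double ag = a[gidx[kg] - 1];
      if (ag == 0.0) continue;
      const double *col = Bp + (size_t)kg * ng;
      for (int ig = 0; ig < ng; ++ig) wB[ig] += col[ig] * ag;
    }
  };

  for (int iter = 1; iter <= n_iter; ++iter) {
    // fixed effects (sparse columns)
    for (int j = 0; j < p; ++j) {
      double rhs = 0.0;
      for (int k = xptr[j]; k < xptr[j + 1]; ++k) rhs += xval[k] * r[xrow[k]];
      rhs += xtx[j] * beta[j];
      double bnew = rhs / xtx[j] + ::norm_rand() * std::sqrt(sigma2_e / xtx[j]);
      double delta = bnew - beta[j];
      beta[j] = bnew;
      if (delta != 0.0)
        for (int k = xptr[j]; k < xptr[j + 1]; ++k) r[xrow[k]] -= delta * xval[k];
    }

    // animal effects, pedigree order
    const double inv_se = 1.0 / sigma2_e, inv_sa = 1.0 / sigma2_a;
    for (int i = 0; i < n_animals; ++i) {
      double ai = a[i];
      int gi = gpos[i];
      double wi = wA[i] + (gi >= 0 ? wB[gi] : 0.0);
      double lhs = cnt[i] * inv_se + hdiag[i] * inv_sa;
      double rhs = -(wi - hdiag[i] * ai) * inv_sa;
      for (int k = rptr[i]; k < rptr[i + 1]; ++k)
        rhs += (r[ridx[k]] + ai) * inv_se;
      double anew = rhs / lhs + ::norm_rand() / std::sqrt(lhs);
      double delta = anew - ai;
      if (delta == 0.0) continue;
      a[i] = anew;
      for (int k = rptr[i]; k < rptr[i + 1]; ++k) r[ridx[k]] -= delta;
      for (int k = Ap[i]; k < Ap[i + 1]; ++k) wA[Ai[k]] += Ax[k] * delta;
      if (gi >= 0) {
        const double *col = Bp + (size_t)gi * ng;
        for (int ig = 0; ig < ng; ++ig) wB[ig] += col[ig] * delta;
      }
    }

    if (iter % 200 == 0) refresh_w();

    if (!fix_variances) {
      double qa = 0.0;
      for (int i = 0; i < n_animals; ++i) qa += a[i] * wA[i];
      for (int kg = 0; kg < ng; ++kg) qa += a[gidx[kg] - 1] * wB[kg];
      if (qa < -1e-8) stop("quadratic form a'H^-1 a negative: H^-1 not positive definite");
      if (qa < 0) qa = 0;
      sigma2_a = (qa + nu_a * S_a) / ::Rf_rchisq((double)n_animals + nu_a);
      double qe = 0.0;
      for (int rr = 0; rr < n_rec; ++rr) qe += r[rr] * r[rr];
      sigma2_e = (qe + nu_e * S_e) / ::Rf_rchisq((double)n_rec + nu_e);
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0 && kept < n_keep) {
      samples(kept, 0) = iter;
      samples(kept, 1) = sigma2_a;
      samples(kept, 2) = sigma2_e;
      for (int j = 0; j < p; ++j) beta_sum[j] += beta[j];
      for (int i = 0; i < n_animals; ++i) a_sum[i] += a[i];
      ++kept;
    }
  }

  NumericVector beta_mean(p), a_mean(n_animals);
  for (int j = 0; j < p; ++j) beta_mean[j] = beta_sum[j] / std::max(kept, 1);
  for (int i = 0; i < n_animals; ++i) a_mean[i] = a_sum[i] / std::max(kept, 1);

  return List::create(_["samples"] = samples,
                      _["beta_mean"] = beta_mean,
                      _["a_mean"] = a_mean,
                      _["n_kept"] = kept);
}
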