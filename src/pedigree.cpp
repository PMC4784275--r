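#include <Rcpp.h>
using namespace Rcpp;

// Meuwissen & Luo (1992) style recursion: inbreeding coefficients without
// forming A. Pedigree must be topologically ordered, codes 1..n, 0 = unknown.
// For animal i the row of the gene-flow matrix L is accumulated backwards
// over its ancestors; a_ii = sum_k L_ik^2 d_k and F_i = a_ii - 1, where d_k
// is the Mendelian sampling variance of ancestor k.
// [[Rcpp::export(name = ".inbreeding_ml")]]
NumericVector inbreeding_ml(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> Fpad(n + 1, 0.0); // Fpad[0] unused guard for code 0
  std::vector<double> v(n + 1);

  for (int i = 1; i <= n; ++i) {
    int s = sire[i - 1], d = dam[i - 1];
    if (s < 0 || s > i - 1 || d < 0 || d > i - 1)
      stop("pedigree is not topologically ordered at animal %d", i);
    if (s == 0 && d == 0) { F[i - 1] = 0.0; Fpad[i] = 0.0; continue; }

    std::fill(v.begin(), v.begin() + i + 1, 0.0);
    v[i] = 1.0;
    double aii = 0.0;
    for (int k = i; k >= 1; --k) {
      double vk = v[k];
      if (vk == 0.0) continue;
      int ks = sire[k - 1], kd = dam[k - 1];
      double dk;
      if (ks && kd)      dk = 0.5  - 0.25 * (Fpad[ks] + Fpad[kd]);
      else if (ks)       dk = 0.75 - 0.25 * Fpad[ks];
      else if (kd)       dk = 0.75 - 0.25 * Fpad[kd];
      else               dk = 1.0;
      aii += vk * vk * dk;
      if (ks) v[ks] += 0.5 * vk;
      if (kd) v[kd] += 0.5 * vk;
    }
    Fpad[i] = aii - 1.0;
    F[i - 1] = Fpad[i];
  }
  return F;
}

// Full numerator relationship matrix by the tabular method.
// a_ij = 0.5 (a_{j,s(i)} + a_{j,d(i)}) for j < i; a_ii = 1 + 0.5 a_{s,d}.
// [[Rcpp::export(name = ".tabular_A")]]
NumericMatrix tabular_A(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i]; // 1-based codes, 0 unknown
    if (s > i || d > i)
      stop("pedigree is not topologically ordered at animal %d", i + 1);
    for (int j = 0; j < i; ++j) {
      double as = s ? A(j, s - 1) : 0.0;
      double ad = d ? A(j, d - 1) : 0.0;
      double v = 0.5 * (as + ad);
      A(j, i) = v;
      A(i, j) = v;
    }
    double asd = (s && d) ? A(s - 1, d - 1) : 0.0;
    A(i, i) = 1.0 + 0.5 * asd;
  }
  return A;
}
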