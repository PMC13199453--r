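#include <Rcpp.h>
using namespace Rcpp;

// Gamete formation over a panel of ordered loci.
//
// h1, h2: n_loci x n_parents 0/1 haplotype matrices (1 = freshwater
//         allele), one column per parent so a gamete walk is contiguous
//         in memory.
// parents: 1-based column indices, one per gamete to produce.
// rec: length n_loci-1 recombination fractions between consecutive loci
//      (0.5 across chromosome boundaries). Under a no-interference Poisson
//      crossover process the inheritance switch at each interval is an
//      independent Bernoulli(rec[i]) event, so this sampling is exact.
// Uses R's RNG: results are reproducible under set.seed().
//
// Switch positions are drawn by exponential skipping on the cumulative
// hazard C[i] = sum_{j<=i} -log(1 - rec[j]): an Exp(1) arrival landing in
// interval i's hazard chunk toggles the template there, and the next draw
// restarts from the following chunk boundary, which reproduces independent
// Bernoulli(rec[i]) switches exactly while drawing O(#switches) variates
// per gamete instead of O(#loci).
// [[Rcpp::export]]
IntegerMatrix cpp_make_gametes(const IntegerMatrix& h1,
                               const IntegerMatrix& h2,
                               const IntegerVector& parents,
                               const NumericVector& rec) {
  const int L = h1.nrow();
  const int m = parents.size();
  if (h2.nrow() != L || h2.ncol() != h1.ncol())
    stop("haplotype matrices must have identical dimensions");
  if (rec.size() != L - 1)
    stop("rec must have length n_loci - 1");
  // C[i] = cumulative hazard at the END of interval i, i = 0..L-2
  std::vector<double> C(L > 1 ? L - 1 : 0);
  double acc = 0.0;
  for (int i = 0; i < L - 1; ++i) {
    double r = rec[i];
    if (r < 0 || r > 0.5) stop("recombination fractions must be in [0, 0.5]");
    acc += (r >= 0.5) ? M_LN2 : -log1p(-r);
    C[i] = acc;
  }
  const double Ctot = acc;

  IntegerMatrix out(L, m);
  for (int g = 0; g < m; ++g) {
    int p = parents[g] - 1;
    if (p < 0 || p >= h1.ncol()) stop("parent index out of range");
    const int* c1 = &h1(0, p);
    const int* c2 = &h2(0, p);
    int* o = &out(0, g);
    bool cur = unif_rand() < 0.5;
    int l = 0;            // next locus to emit
    double base = 0.0;    // hazard consumed (start of interval l)
    while (l < L) {
      double arrival = base + exp_rand();
      if (L == 1 || arrival >= Ctot) {
        const int* src = cur ? c2 : c1;
        std::copy(src + l, src + L, o + l);
        break;
      }
      // first interval k >= l with C[k] > arrival holds the switch;
      // loci l..k keep the current template, locus k+1 starts the other
      int k = int(std::upper_bound(C.begin() + l, C.end(), arrival) -
                  C.begin());
      const int* src = cur ? c2 : c1;
      std::copy(src + l, src + k + 1, o + l);
      cur = !cur;
      l = k + 1;
      base = C[k];
    }
  }
  return out;
}

// Column sums of h1 + h2: per-individual freshwater allele counts.
// [[Rcpp::export]]
IntegerVector cpp_allele_counts(const IntegerMatrix& h1,
                                const IntegerMatrix& h2) {
  const int L = h1.nrow(), n = h1.ncol();
  IntegerVector out(n);
  for (int j = 0; j < n; ++j) {
    const int* c1 = &h1(0, j);
    const int* c2 = &h2(0, j);
    int s = 0;
    for (int l = 0; l < L; ++l) s += c1[l] + c2[l];
    out[j] = s;
  }
  return out;
}

// Per-individual heterozygous and homozygous-freshwater locus counts,
// for multiplicative fitness across loci.
// [[Rcpp::export]]
IntegerMatrix cpp_het_hom(const IntegerMatrix& h1, const IntegerMatrix& h2) {
  const int L = h1.nrow(), n = h1.ncol();
  IntegerMatrix out(n, 2);
  for (int j = 0; j < n; ++j) {
    const int* c1 = &h1(0, j);
    const int* c2 = &h2(0, j);
    int het = 0, hom = 0;
    for (int l = 0; l < L; ++l) {
      het += c1[l] != c2[l];
      hom += c1[l] & c2[l];
    }
    out(j, 0) = het;
    out(j, 1) = hom;
  }
  return out;
}
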