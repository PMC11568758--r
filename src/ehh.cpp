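#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Extended haplotype homozygosity outward from a core site.
//
// Carriers of the core allele are partitioned into identical extended
// haplotypes spanning core..x; EHH(x) = sum_h C(n_h,2) / C(n_c,2). The
// partition is refined one site at a time, so the whole curve costs
// O(n_carriers) per site.

static std::vector<double> ehh_direction(const IntegerMatrix& haps,
                                         const std::vector<int>& carriers,
                                         int core, int step, double trunc) {
  const int S = haps.ncol();
  const int n = (int)carriers.size();
  const double denom = (double)n * (n - 1) / 2.0;
  std::vector<int> grp(n, 0), lookup(2 * n, -1), cnt(n), touched(n);
  std::vector<double> out;
  for (int x = core + step; x >= 0 && x < S; x += step) {
    int next = 0, ntouch = 0;
    for (int i = 0; i < n; ++i) {
      int k = 2 * grp[i] + haps(carriers[i], x);
      int g = lookup[k];
      if (g < 0) { g = next++; lookup[k] = g; cnt[g] = 0; touched[ntouch++] = k; }
      grp[i] = g;
      cnt[g]++;
    }
    for (int t = 0; t < ntouch; ++t) lookup[touched[t]] = -1;
    double s = 0.0;
    for (int g = 0; g < next; ++g) s += (double)cnt[g] * (cnt[g] - 1) / 2.0;
    double e = s / denom;
    out.push_back(e);
    if (e < trunc) break;
    if (next == n) {            // fully partitioned: EHH stays 0 afterwards
      for (int y = x + step; y >= 0 && y < S; y += step) out.push_back(0.0);
      break;
    }
  }
  return out;
}

// trapezoidal integral of one direction's EHH over genetic distance,
// starting from (0, 1) at the core and truncated at the last site with
// EHH >= trunc (no interpolation past it)
static double ihh_direction(const IntegerMatrix& haps,
                            const std::vector<int>& carriers,
                            const NumericVector& gpos,
                            int core, int step, double trunc) {
  const int S = haps.ncol();
  const int n = (int)carriers.size();
  const double denom = (double)n * (n - 1) / 2.0;
  std::vector<int> grp(n, 0), lookup(2 * n, -1), cnt(n), touched(n);
  double ihh = 0.0, prev_e = 1.0, prev_d = 0.0;
  for (int x = core + step; x >= 0 && x < S; x += step) {
    int next = 0, ntouch = 0;
    for (int i = 0; i < n; ++i) {
      int k = 2 * grp[i] + haps(carriers[i], x);
      int g = lookup[k];
      if (g < 0) { g = next++; lookup[k] = g; cnt[g] = 0; touched[ntouch++] = k; }
      grp[i] = g;
      cnt[g]++;
    }
    for (int t = 0; t < ntouch; ++t) lookup[touched[t]] = -1;
    double s = 0.0;
    for (int g = 0; g < next; ++g) s += (double)cnt[g] * (cnt[g] - 1) / 2.0;
    double e = s / denom;
    double d = std::abs(gpos[x] - gpos[core]);
    if (e < trunc) break;
    ihh += (prev_e + e) / 2.0 * (d - prev_d);
    prev_e = e;
    prev_d = d;
  }
  return ihh;
}

static std::vector<int> carriers_of(const IntegerMatrix& haps, int core, int allele) {
  std::vector<int> idx;
  for (int i = 0; i < haps.nrow(); ++i)
    if (haps(i, core) == allele) idx.push_back(i);
  return idx;
}

// [[Rcpp::export(name = ".ehh_curve_cpp")]]
List ehh_curve_cpp(IntegerMatrix haps, int core1, int allele, double trunc) {
  int core = core1 - 1;
  std::vector<int> carr = carriers_of(haps, core, allele);
  if (carr.size() < 2)
    stop("EHH undefined: %d carrier(s) of allele %d at the core site",
         (int)carr.size(), allele);
  return List::create(
    _["left"]  = wrap(ehh_direction(haps, carr, core, -1, trunc)),
    _["right"] = wrap(ehh_direction(haps, carr, core, +1, trunc)),
    _["n_carriers"] = (int)carr.size());
}

// [[Rcpp::export(name = ".ihh_cpp")]]
NumericVector ihh_cpp(IntegerMatrix haps, NumericVector gpos, int core1,
                      int allele, double trunc) {
  int core = core1 - 1;
  std::vector<int> carr = carriers_of(haps, core, allele);
  if (carr.size() < 2)
    stop("iHH undefined: fewer than 2 carriers of allele %d", allele);
  double left = ihh_direction(haps, carr, gpos, core, -1, trunc);
  double right = ihh_direction(haps, carr, gpos, core, +1, trunc);
  return NumericVector::create(_["left"] = left, _["right"] = right);
}

// [[Rcpp::export(name = ".ihs_scan_cpp")]]
DataFrame ihs_scan_cpp(IntegerMatrix haps, NumericVector gpos,
                       double min_maf, double trunc) {
  const int S = haps.ncol();
  const int H = haps.nrow();
  NumericVector freq(S), ihh_a(S), ihh_d(S), ihs(S);
  for (int x = 0; x < S; ++x) {
    int cd = 0;
    for (int i = 0; i < H; ++i) cd += haps(i, x);
    double f = (double)cd / H;
    freq[x] = f;
    double maf = f < 0.5 ? f : 1.0 - f;
    if (maf < min_maf || cd < 2 || H - cd < 2) {
      ihh_a[x] = NA_REAL; ihh_d[x] = NA_REAL; ihs[x] = NA_REAL;
      continue;
    }
    std::vector<int> anc = carriers_of(haps, x, 0);
    std::vector<int> der = carriers_of(haps, x, 1);
    double ia = ihh_direction(haps, anc, gpos, x, -1, trunc) +
                ihh_direction(haps, anc, gpos, x, +1, trunc);
    double id = ihh_direction(haps, der, gpos, x, -1, trunc) +
                ihh_direction(haps, der, gpos, x, +1, trunc);
    ihh_a[x] = ia;
    ihh_d[x] = id;
    ihs[x] = (ia > 0.0 && id > 0.0) ? std::log(ia / id) : NA_REAL;
  }
  return DataFrame::create(_["site_index"] = seq(1, S), _["freq_derived"] = freq,
                           _["ihh_ancestral"] = ihh_a, _["ihh_derived"] = ihh_d,
                           _["ihs_unstd"] = ihs);
}
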