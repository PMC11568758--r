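#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// One Wright-Fisher generation: 2N gametes, each from a parent diploid
// sampled with probability proportional to fitness (additive selection at
// the focal site), recombining between that parent's two haplotypes with
// per-interval crossover probabilities. Uses R's RNG, so runs are
// reproducible under set.seed().

// [[Rcpp::export(name = ".wf_generation_cpp")]]
IntegerMatrix wf_generation_cpp(IntegerMatrix haps, NumericVector r_interval,
                                int focal1, double s) {
  const int n2 = haps.nrow();
  const int n = n2 / 2;
  const int S = haps.ncol();
  const int focal = focal1 - 1;
  IntegerMatrix out(n2, S);

  std::vector<double> cumw;
  double totw = 0.0;
  if (s != 0.0) {
    cumw.resize(n);
    for (int i = 0; i < n; ++i) {
      int dosage = haps(2 * i, focal) + haps(2 * i + 1, focal);
      totw += 1.0 + s * dosage;
      cumw[i] = totw;
    }
  }

  for (int g = 0; g < n2; ++g) {
    int parent;
    if (s != 0.0) {
      double u = unif_rand() * totw;
      parent = (int)(std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
      if (parent >= n) parent = n - 1;
    } else {
      parent = (int)(unif_rand() * n);
      if (parent >= n) parent = n - 1;
    }
    int cur = unif_rand() < 0.5 ? 0 : 1;
    out(g, 0) = haps(2 * parent + cur, 0);
    for (int j = 1; j < S; ++j) {
      if (r_interval[j - 1] > 0.0 && unif_rand() < r_interval[j - 1]) cur = 1 - cur;
      out(g, j) = haps(2 * parent + cur, j);
    }
  }
  return out;
}
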