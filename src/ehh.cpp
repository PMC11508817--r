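// Extended haplotype homozygosity by incremental group refinement.
// At each successive site away from the core, carrier haplotypes are split
// into groups identical over [core..site]; EHH = sum C(n_g,2) / C(n,2).

#include <Rcpp.h>

using namespace Rcpp;

// [[Rcpp::export]]
List ehh_kernel(IntegerMatrix al, IntegerVector pos, int core0,
                IntegerVector carriers0, IntegerVector check_rows0,
                int direction, double cutoff, double max_gap,
                int lo0, int hi0) {
  int n = carriers0.size();
  if (n < 2) {
    return List::create(_["site"] = IntegerVector(0),
                        _["ehh"] = NumericVector(0),
                        _["truncation"] = "no_carriers");
  }
  double denom = n * (n - 1) / 2.0;
  int nrow = al.nrow();
  const int *alp = INTEGER(al);
  int ncheck = check_rows0.size();
  std::vector<int> grp(n, 0), newgrp(n), gsize(n), remap(2 * n, -1),
      touched;
  touched.reserve(2 * n);
  std::vector<int> out_site;
  std::vector<double> out_ehh;
  std::string trunc = "chrom_end";
  int j = core0;
  double last_used = pos[core0];
  while (true) {
    j += direction;
    if (j < lo0 || j > hi0) { trunc = "chrom_end"; break; }
    const int *col = alp + (size_t) j * nrow;
    // exclude sites with any missing allele in the scanned population
    bool missing = false;
    for (int r = 0; r < ncheck; ++r) {
      if (col[check_rows0[r]] == NA_INTEGER) { missing = true; break; }
    }
    if (missing) continue;
    if (std::abs((double) pos[j] - last_used) > max_gap) {
      trunc = "max_gap";
      break;
    }
    // refine groups by the allele at site j
    int ngroups = 0;
    touched.clear();
    for (int i = 0; i < n; ++i) {
      int key = 2 * grp[i] + col[carriers0[i]];
      if (remap[key] < 0) {
        remap[key] = ngroups;
        gsize[ngroups] = 0;
        touched.push_back(key);
        ++ngroups;
      }
      newgrp[i] = remap[key];
      gsize[remap[key]]++;
    }
    for (size_t t = 0; t < touched.size(); ++t) remap[touched[t]] = -1;
    grp.swap(newgrp);
    double pairs = 0.0;
    for (int g = 0; g < ngroups; ++g)
      pairs += gsize[g] * (gsize[g] - 1) / 2.0;
    double e = pairs / denom;
    out_site.push_back(j + 1); // back to 1-based
    out_ehh.push_back(e);
    last_used = pos[j];
    if (e < cutoff || e == 0.0) { trunc = "cutoff"; break; }
  }
  return List::create(
    _["site"] = IntegerVector(out_site.begin(), out_site.end()),
    _["ehh"] = NumericVector(out_ehh.begin(), out_ehh.end()),
    _["truncation"] = trunc);
}
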