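#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Iterative greedy nucleosome calling on one chromosome.
//
// Repeats: take the leftmost global maximum of the smoothed dyad density;
// set the protected length from the mean length of fragments covering the
// center base; compute member-center statistics (fuzziness) within the
// protected region and occupancy within +/- occ_halfwin; zero the density
// on center +/- floor(protected/2); stop when the maximum falls below
// min_density (or max_calls is reached).
//
// A block-maximum index over the density vector keeps each iteration
// O(n_blocks + window) instead of O(n).
//
// dens:       smoothed per-base density (copied, then consumed)
// cnt:        per-base read-center counts
// cov_cnt:    per-base count of fragments covering the base
// cov_sumlen: per-base sum of lengths of covering fragments
// [[Rcpp::export]]
List greedy_call_chrom(NumericVector dens_in, IntegerVector cnt,
                       NumericVector cov_cnt, NumericVector cov_sumlen,
                       double min_density, int max_calls, int fallback_len,
                       int occ_halfwin) {
  const int n = dens_in.size();
  std::vector<double> dens(dens_in.begin(), dens_in.end());

  // prefix sums of center counts (integers: exact in double)
  std::vector<double> P(n + 1, 0.0);
  for (int i = 0; i < n; ++i) P[i + 1] = P[i] + cnt[i];
  auto count_range = [&](int lo, int hi) -> double {
    if (lo < 0) lo = 0;
    if (hi > n - 1) hi = n - 1;
    if (lo > hi) return 0.0;
    return P[hi + 1] - P[lo];
  };

  const int B = 1024;
  const int nb = (n + B - 1) / B;
  std::vector<double> bmax(nb, 0.0);
  auto update_block = [&](int b) {
    int lo = b * B, hi = std::min(n, lo + B);
    double m = 0.0;
    for (int i = lo; i < hi; ++i) if (dens[i] > m) m = dens[i];
    bmax[b] = m;
  };
  for (int b = 0; b < nb; ++b) update_block(b);

  std::vector<int> out_center, out_pl, out_occ, out_nmem;
  std::vector<double> out_fuzz, out_mean, out_peak;

  int ncalls = 0;
  while (max_calls <= 0 || ncalls < max_calls) {
    // leftmost global argmax: first block holding the max, first index in it
    int best_b = -1;
    double best = 0.0;
    for (int b = 0; b < nb; ++b) {
      if (bmax[b] > best) { best = bmax[b]; best_b = b; }
    }
    if (best_b < 0 || best < min_density || best <= 0.0) break;
    int c = -1;
    {
      int lo = best_b * B, hi = std::min(n, lo + B);
      for (int i = lo; i < hi; ++i) {
        if (dens[i] == best) { c = i; break; }
      }
    }
    if (c < 0) break;  // defensive; cannot happen

    // protected length: mean length of fragments covering the center base
    int pl;
    if (cov_cnt[c] > 0.0) {
      pl = (int)std::nearbyint(cov_sumlen[c] / cov_cnt[c]);
      if (pl < 1) pl = 1;
    } else {
      pl = fallback_len;
    }

    // member centers within center +/- pl/2 (inclusive, half may be x.5)
    double half = pl / 2.0;
    int mlo = (int)std::ceil(c - half), mhi = (int)std::floor(c + half);
    if (mlo < 0) mlo = 0;
    if (mhi > n - 1) mhi = n - 1;
    double n_mem = count_range(mlo, mhi);
    double s1 = 0.0, s2 = 0.0;  // moments of (x - c) over member centers
    for (int i = mlo; i <= mhi; ++i) {
      if (cnt[i] > 0) {
        double d = (double)(i - c);
        s1 += cnt[i] * d;
        s2 += cnt[i] * d * d;
      }
    }
    double mean = (n_mem > 0) ? c + s1 / n_mem : (double)c;
    double fuzz = 0.0, mvar = 0.0;
    if (n_mem >= 2) {
      mvar = (s2 - s1 * s1 / n_mem) / (n_mem - 1.0);
      if (mvar < 0) mvar = 0;
      fuzz = std::sqrt(mvar);
    }

    // occupancy: read centers within +/- occ_halfwin of the center
    int occ = (int)count_range(c - occ_halfwin, c + occ_halfwin);

    // zero the density over center +/- floor(pl/2)
    int zlo = c - pl / 2, zhi = c + pl / 2;
    if (zlo < 0) zlo = 0;
    if (zhi > n - 1) zhi = n - 1;
    for (int i = zlo; i <= zhi; ++i) dens[i] = 0.0;
    for (int b = zlo / B; b <= zhi / B; ++b) update_block(b);

    out_center.push_back(c);
    out_pl.push_back(pl);
    out_occ.push_back(occ);
    out_nmem.push_back((int)n_mem);
    out_fuzz.push_back(fuzz);
    out_mean.push_back(mean);
    out_peak.push_back(best);
    ++ncalls;
  }

  return List::create(
    _["center"] = wrap(out_center),
    _["protected_length"] = wrap(out_pl),
    _["fuzziness"] = wrap(out_fuzz),
    _["occupancy"] = wrap(out_occ),
    _["n_members"] = wrap(out_nmem),
    _["member_mean"] = wrap(out_mean),
    _["peak_density"] = wrap(out_peak));
}
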