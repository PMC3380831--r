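#include <Rcpp.h>
using namespace Rcpp;

// Greedy cross-replicate dyad linking within one chromosome.
//
// `centers` holds the 0 h call centers of every replicate, concatenated in
// replicate processing order with each replicate's block sorted ascending;
// `rep_sizes` gives the block lengths.  Clusters are seeded from the first
// block; each later row joins the nearest cluster (running mean dyad) not
// yet taken by its own replicate and within `link_radius`, ties to the
// earliest-seeded cluster, else seeds a new cluster.
//
// Returns the 1-based cluster id per input row.
// [[Rcpp::export]]
IntegerVector link_clusters_chrom(NumericVector centers,
                                  IntegerVector rep_sizes,
                                  double link_radius) {
    const int n = centers.size();
    IntegerVector out(n);
    std::vector<double> cl_dyad;
    std::vector<int> cl_n;
    std::vector<char> taken;
    int pos = 0;
    for (int ri = 0; ri < rep_sizes.size(); ++ri) {
        std::fill(taken.begin(), taken.end(), 0);
        for (int k = 0; k < rep_sizes[ri]; ++k, ++pos) {
            const double d = centers[pos];
            int j = -1;
            double best = R_PosInf;
            for (size_t c = 0; c < cl_dyad.size(); ++c) {
            if (taken[c]) continue;
            const double dist = std::fabs(cl_dyad[c] - d);
            if (dist < best) { best = dist; j = static_cast<int>(c); }
            }
            if (j >= 0 && best <= link_radius) {
                cl_dyad[j] = (cl_dyad[j] * cl_n[j] + d) / (cl_n[j] + 1);
                cl_n[j] += 1;
                taken[j] = 1;
                out[pos] = j + 1;
            } else {
                cl_dyad.push_back(d);
                cl_n.push_back(1);
                taken.push_back(1);
                out[pos] = static_cast<int>(cl_dyad.size());
            }
        }
    }
    return out;
}
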