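#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact Gillespie dynamics: point mutations at per-bp (possibly region-wise)
// rates plus random segmental duplications at rate lambda per bp. All
// randomness is drawn from R's RNG so runs are reproducible via set.seed().

static inline int other_base(int b) {
    int k = (int) (unif_rand() * 3.0);
    if (k > 2) k = 2;                       // guard unif_rand() == 1
    return (b + 1 + k) % 4;
}

// seq0: bases coded 0..3; region_rate: one mutation rate per M-bp region
// (last region may be shorter). Duplication copies a K-bp segment from a
// uniform source locus c over a uniform target locus v; length is conserved.
// [[Rcpp::export(name = ".evolve_seq")]]
List evolve_seq(IntegerVector seq0, double lambda, int K,
                NumericVector region_rate, int M, double duration) {
    const int L = seq0.size();
    if (K > L) stop("duplication length K exceeds sequence length L");
    const int nreg = region_rate.size();
    if ((int) std::ceil((double) L / M) != nreg)
        stop("region_rate length does not match ceiling(L / M)");

    std::vector<int> seq(seq0.begin(), seq0.end());
    // cumulative mutation weight per region
    std::vector<double> cumw(nreg);
    double R_mut = 0.0;
    for (int i = 0; i < nreg; ++i) {
        int len = std::min(M, L - i * M);
        R_mut += region_rate[i] * len;
        cumw[i] = R_mut;
    }
    const double R_dup = (lambda > 0.0) ? lambda * L : 0.0;
    const double R_tot = R_mut + R_dup;

    long n_mut = 0, n_dup = 0;
    std::vector<int> buf(K);
    RNGScope scope;
    if (R_tot > 0.0) {
        double t = 0.0;
        for (;;) {
            t += exp_rand() / R_tot;
            if (t > duration) break;
            if (unif_rand() * R_tot < R_mut) {
                // choose region proportional to rate * length, site uniform
                double u = unif_rand() * R_mut;
                int reg = (int) (std::lower_bound(cumw.begin(), cumw.end(), u)
                                 - cumw.begin());
                if (reg >= nreg) reg = nreg - 1;
                int len = std::min(M, L - reg * M);
                int site = reg * M + (int) (unif_rand() * len);
                if (site >= reg * M + len) site = reg * M + len - 1;
                seq[site] = other_base(seq[site]);
                ++n_mut;
            } else {
                int span = L - K + 1;
                int c = (int) (unif_rand() * span); if (c >= span) c = span - 1;
                int v = (int) (unif_rand() * span); if (v >= span) v = span - 1;
                std::copy(seq.begin() + c, seq.begin() + c + K, buf.begin());
                std::copy(buf.begin(), buf.end(), seq.begin() + v);
                ++n_dup;
            }
        }
    }
    return List::create(_["seq"] = IntegerVector(seq.begin(), seq.end()),
                        _["n_mut"] = (double) n_mut,
                        _["n_dup"] = (double) n_dup);
}

// Growing segment family (Yule or retro mode). The family starts from one
// source segment of length K; duplicates are appended at position n*K.
// yule mode: every segment duplicates at rate lamK and mutates at rate mu.
// retro mode: only the source (segment 0) duplicates, at rate lamK; copies
// mutate at rate mu per bp while the source mutates at a*mu per bp.
// [[Rcpp::export(name = ".evolve_family")]]
List evolve_family(IntegerVector source0, double lamK, double mu, double a,
                   double duration, bool yule, int max_segments = 200000) {
    const int K = source0.size();
    std::vector<int> seq(source0.begin(), source0.end());
    int n = 1;
    std::vector<double> times;  // duplication event times

    RNGScope scope;
    double t = 0.0;
    for (;;) {
        double R_dup = yule ? lamK * n : lamK;
        double R_src = (yule ? mu : a * mu) * K;
        double R_cop = mu * (double) (n - 1) * K;
        double R_tot = R_dup + R_src + R_cop;
        if (R_tot <= 0.0) break;
        t += exp_rand() / R_tot;
        if (t > duration) break;
        double u = unif_rand() * R_tot;
        if (u < R_dup) {
            if (n >= max_segments) stop("segment family exceeded max_segments");
            int src = 0;
            if (yule) {
                src = (int) (unif_rand() * n);
                if (src >= n) src = n - 1;
            }
            seq.insert(seq.end(), seq.begin() + (size_t) src * K,
                       seq.begin() + (size_t) (src + 1) * K);
            ++n;
            times.push_back(t);
        } else if (u < R_dup + R_src) {
            int site = (int) (unif_rand() * K);
            if (site >= K) site = K - 1;
            seq[site] = other_base(seq[site]);
        } else {
            long span = (long) (n - 1) * K;
            long site = (long) (unif_rand() * span);
            if (site >= span) site = span - 1;
            seq[K + site] = other_base(seq[K + site]);
        }
    }
    return List::create(_["seq"] = IntegerVector(seq.begin(), seq.end()),
                        _["n_segments"] = n,
                        _["times"] = NumericVector(times.begin(), times.end()));
}
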