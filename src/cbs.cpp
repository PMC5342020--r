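#include <Rcpp.h>
using namespace Rcpp;

// Circular binary-segmentation scan statistic for a window x[0..n-1]:
// over change-point pairs 0 <= i < j <= n (middle arc = x[i..j-1], m = j-i),
//   Z(i,j) = |S_j - S_i - (m/n) S_n| / sqrt(m (n-m) / n),
// the two-sample mean contrast of the arc against the rest of the window.
// j = n (or i = 0) reduces to the ordinary binary split statistic. The
// residual SD is constant under within-window permutation and cancels from
// the permutation p-value, so it is omitted.
//
// For speed, interior arcs are scanned only up to width `w` (min(m, n-m)
// <= w); all binary splits are always scanned. Short arcs are exactly the
// case where the plain binary statistic loses power, so the cap costs
// little: wide interior segments are found edge-by-edge by recursion.
struct ScanHit { double stat; int i; int j; };

static ScanHit scan_window(const double *x, int n, int w) {
    std::vector<double> S(n + 1);
    S[0] = 0.0;
    for (int k = 0; k < n; ++k) S[k + 1] = S[k] + x[k];
    const double Sn = S[n];
    ScanHit best = {-1.0, 0, n};
    for (int m = 1; m < n; ++m) {
        double denom = std::sqrt((double)m * (double)(n - m) / (double)n);
        double frac = (double)m / (double)n * Sn;
        bool full = (m <= w) || (n - m <= w);
        if (full) {
            for (int i = 0; i + m <= n; ++i) {
                double z = std::fabs(S[i + m] - S[i] - frac) / denom;
                if (z > best.stat) { best.stat = z; best.i = i; best.j = i + m; }
            }
        } else {  // binary splits only: arcs anchored at either window end
            double z0 = std::fabs(S[m] - frac) / denom;
            if (z0 > best.stat) { best.stat = z0; best.i = 0; best.j = m; }
            double z1 = std::fabs(S[n] - S[n - m] - frac) / denom;
            if (z1 > best.stat) { best.stat = z1; best.i = n - m; best.j = n; }
        }
    }
    return best;
}

// [[Rcpp::export(name = ".cbs_scan")]]
List cbs_scan(NumericVector x, int w) {
    int n = x.size();
    if (n < 2)
        return List::create(_["stat"] = 0.0, _["i"] = 0, _["j"] = n);
    ScanHit h = scan_window(REAL(x), n, w);
    return List::create(_["stat"] = h.stat, _["i"] = h.i, _["j"] = h.j);
}

// Permutation p-value for the max scan statistic of one window, with early
// stopping: once `early_exceed` permuted statistics reach the observed one
// the p-value can no longer fall below alpha, so the loop aborts. Uses R's
// RNG, so results are governed by set.seed().
// [[Rcpp::export(name = ".cbs_perm")]]
List cbs_perm(NumericVector x, int w, int n_perm, int early_exceed) {
    int n = x.size();
    if (n < 2)
        return List::create(_["stat"] = 0.0, _["i"] = 0, _["j"] = n,
                            _["p"] = 1.0);
    ScanHit obs = scan_window(REAL(x), n, w);
    std::vector<double> work(REAL(x), REAL(x) + n);
    RNGScope scope;
    int exceed = 0, done = 0;
    for (int b = 0; b < n_perm; ++b) {
        for (int k = n - 1; k > 0; --k) {  // Fisher-Yates via R RNG
            int j = (int)(unif_rand() * (k + 1));
            if (j > k) j = k;
            std::swap(work[k], work[j]);
        }
        ScanHit h = scan_window(work.data(), n, w);
        if (h.stat >= obs.stat) ++exceed;
        ++done;
        if (early_exceed > 0 && exceed >= early_exceed) break;
    }
    double p = (1.0 + exceed) / (1.0 + done);
    return List::create(_["stat"] = obs.stat, _["i"] = obs.i,
                        _["j"] = obs.j, _["p"] = p);
}
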