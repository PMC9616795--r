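#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Empirical excess mass E_{n,m}(lambda): the largest value of
// sum_j [ P_n(I_j) - lambda * |I_j| ] over at most m disjoint closed
// intervals with endpoints at data points.  Computed for one lambda by
// dynamic programming over the sorted sample: each point contributes
// mass 1/n, each gap inside an interval costs lambda * gap.
//
// The multimodality statistic is
//   Delta_{n,k+1} = max_lambda [ E_{n,k+1}(lambda) - E_{n,k}(lambda) ],
// maximised over the finite candidate set of slopes
// lambda = (j - i) / (n * (x_j - x_i)), i < j, plus lambda = 0, which
// contains the breakpoints where the optimal interval systems change.

static void excess_levels(const std::vector<double>& x, double lambda,
                          int mmax, std::vector<double>& E) {
    const int n = (int)x.size();
    const double w = 1.0 / n;
    // f[i]: best score with current number of intervals, last one ending at i
    // bestPrev[i]: best score with (m-1) intervals using points 1..i only
    std::vector<double> f(n), bestPrev(n, 0.0), bestCur(n);
    for (int m = 1; m <= mmax; ++m) {
        for (int i = 0; i < n; ++i) {
            // start a new interval at point i (earlier intervals end before i)
            double start = (i > 0 ? bestPrev[i - 1] : 0.0) + w;
            // or extend the interval ending at point i-1 across the gap
            double extend = -1e300;
            if (i > 0)
                extend = f[i - 1] + w - lambda * (x[i] - x[i - 1]);
            f[i] = std::max(start, extend);
            bestCur[i] = std::max(i > 0 ? bestCur[i - 1] : 0.0, f[i]);
        }
        // allow fewer than m intervals (degenerate/empty): E_m >= E_{m-1}
        E[m - 1] = std::max(bestCur[n - 1], m >= 2 ? E[m - 2] : 0.0);
        std::swap(bestPrev, bestCur);
        std::fill(bestCur.begin(), bestCur.end(), 0.0);
    }
}

// [[Rcpp::export(name = ".excess_mass_cpp")]]
double excess_mass_cpp(NumericVector xs, int k) {
    std::vector<double> x(xs.begin(), xs.end());
    std::sort(x.begin(), x.end());
    const int n = (int)x.size();
    if (n == 0) return NA_REAL;
    std::vector<double> lambdas;
    lambdas.push_back(0.0);
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
            if (x[j] > x[i])
                lambdas.push_back((double)(j - i) / (n * (x[j] - x[i])));
    std::sort(lambdas.begin(), lambdas.end());
    lambdas.erase(std::unique(lambdas.begin(), lambdas.end()), lambdas.end());
    std::vector<double> E(k + 1);
    double best = 0.0;
    for (double lam : lambdas) {
        excess_levels(x, lam, k + 1, E);
        double d = E[k] - E[k - 1];
        if (d > best) best = d;
    }
    return best;
}

// ---------------------------------------------------------------------------
// Dip statistic: the minimal sup-norm distance from the empirical CDF to the
// class of unimodal CDFs (convex up to the mode, concave after, with an atom
// allowed at the mode only).  Computed by bisection on the distance t with an
// exact feasibility certificate.
//
// For distance t the candidate CDF G must satisfy, at each distinct data
// value z_i with cumulative counts c_i (c_0 = 0):
//     G(z_i)  in [c_i/n - t,  c_i/n + t]      (value at the jump)
//     G(z_i-) in [c_{i-1}/n - t, c_{i-1}/n + t]  (left limit)
// For a continuity point both collapse to the two-sided band
//     l_i = c_i/n - t <= G(z_i) <= c_{i-1}/n + t = u_i.
// A convex nondecreasing sequence within bands [l, u] exists iff the forced
// lower envelope g* (max over support lines through (z_i, u_i)-(z_j, l_j)
// and horizontals) stays below u; g* is also the minimal feasible sequence,
// which gives the achievable endpoint interval directly.  The concave side is
// the mirror image.  The mode may sit at a data point (allowing a jump there,
// which relaxes the band at that single index) or inside a gap.

struct SweepResult {
    std::vector<char> feas;       // feas[m]: convex sequence exists on 1..m
    std::vector<double> lmin;     // minimal achievable value at index m
    std::vector<double> lmin_pt;  // minimal left-limit value at z_m (jump at m)
    std::vector<char> feas_pt;    // prefix 1..m-1 feasible and left-limit band reachable
};

// one-sided sweep on the convex side; z strictly increasing
static void convex_sweep(const std::vector<double>& z,
                         const std::vector<double>& l,
                         const std::vector<double>& u,
                         const std::vector<double>& l_left,   // left-limit band lower
                         const std::vector<double>& u_left,   // left-limit band upper
                         SweepResult& out) {
    const int p = (int)z.size();
    out.feas.assign(p + 1, 1);
    out.lmin.assign(p + 1, 0.0);
    out.lmin_pt.assign(p + 1, 0.0);
    out.feas_pt.assign(p + 1, 1);
    // support line per index: passes through (z_m, l_m), slope s_m >= 0
    std::vector<double> slope(p, 0.0);
    bool ok = true;
    for (int m = 0; m < p; ++m) {
        // forced bound at z_m from earlier support lines
        double q = 0.0;                      // CDF >= 0
        for (int j = 0; j < m; ++j) {
            double v = l[j] + slope[j] * (z[m] - z[j]);
            if (v > q) q = v;
        }
        // mode with an atom at z_m: left limit only needs the left band
        out.lmin_pt[m + 1] = std::max(q, std::max(l_left[m], 0.0));
        out.feas_pt[m + 1] = (out.feas[m] && out.lmin_pt[m + 1] <= u_left[m] + 1e-14) ? 1 : 0;
        double g = std::max(q, l[m]);
        out.lmin[m + 1] = g;
        ok = ok && (g <= u[m] + 1e-14);
        out.feas[m + 1] = ok ? 1 : 0;
        // steepest support line through (z_m, l_m) over earlier upper bounds
        double s = 0.0;
        for (int i = 0; i < m; ++i) {
            if (l[m] > u[i]) {
                double si = (l[m] - u[i]) / (z[m] - z[i]);
                if (si > s) s = si;
            }
        }
        slope[m] = s;
    }
}

static bool dip_feasible(const std::vector<double>& z,
                         const std::vector<double>& cum, int n, double t) {
    const int p = (int)z.size();
    std::vector<double> l(p), u(p), ll(p), ul(p);
    for (int i = 0; i < p; ++i) {
        double prev = (i > 0 ? cum[i - 1] : 0.0) / n;
        double cur = cum[i] / n;
        l[i] = std::max(cur - t, 0.0);
        u[i] = std::min(prev + t, 1.0);
        ll[i] = std::max(prev - t, 0.0);   // left-limit band at z_i
        ul[i] = std::min(prev + t, 1.0);
    }
    SweepResult left;
    convex_sweep(z, l, u, ll, ul, left);

    // mirrored problem for the concave side: x -> -x reversed, g -> 1-g
    std::vector<double> zr(p), lr(p), ur(p), llr(p), ulr(p);
    for (int i = 0; i < p; ++i) {
        int j = p - 1 - i;
        zr[i] = -z[j];
        lr[i] = 1.0 - u[j];
        ur[i] = 1.0 - l[j];
        // value-at-jump band of z_j becomes the custom start band on the right
        double cur = cum[j] / n;
        llr[i] = std::max(1.0 - std::min(cur + t, 1.0), 0.0);
        ulr[i] = std::min(1.0 - std::max(cur - t, 0.0), 1.0);
    }
    SweepResult right;
    convex_sweep(zr, lr, ur, llr, ulr, right);
    // translate mirrored results: suffix m..p corresponds to mirrored prefix
    // of length p-m+1; achievable start value w at z_m has maximal value
    // 1 - lmin_mirrored.
    auto suffix_feas = [&](int m) {            // concave feasible on m..p (1-based)
        return m > p ? true : (bool)right.feas[p - m + 1];
    };
    auto rmax_std = [&](int m) {               // max achievable G(z_m), standard band
        return 1.0 - right.lmin[p - m + 1];
    };

    // continuous mode at data point z_m: convex on 1..m and concave on
    // m..p share the value G(z_m); the achievable intervals must intersect
    for (int m = 1; m <= p; ++m) {
        if (left.feas[m] && suffix_feas(m) &&
            left.lmin[m] <= rmax_std(m) + 1e-14)
            return true;
    }
    // mode with an atom at data point z_m: the left part ends at the left
    // limit, the right part starts at the post-jump value.
    for (int m = 1; m <= p; ++m) {
        if (!left.feas_pt[m]) continue;
        if (!suffix_feas(m + 1)) continue;
        // maximal post-jump value at z_m honouring the value band and the
        // concave constraints coming from the right
        double rmax_pt = 1.0 - right.lmin_pt[p - m + 1];
        double rfeas = right.feas_pt[p - m + 1];
        if (!rfeas) continue;
        if (left.lmin_pt[m] <= rmax_pt + 1e-14) return true;
    }
    return false;
}

// [[Rcpp::export(name = ".dip_cpp")]]
double dip_cpp(NumericVector xs) {
    std::vector<double> x(xs.begin(), xs.end());
    std::sort(x.begin(), x.end());
    const int n = (int)x.size();
    if (n <= 1) return 0.0;
    std::vector<double> z, cum;
    for (int i = 0; i < n; ++i) {
        if (z.empty() || x[i] > z.back()) {
            z.push_back(x[i]);
            cum.push_back(i + 1.0);
        } else {
            cum.back() = i + 1.0;
        }
    }
    if (z.size() == 1) return 0.0;   // point mass is unimodal
    double lo = 0.0, hi = 0.5;
    for (int it = 0; it < 60; ++it) {
        double mid = 0.5 * (lo + hi);
        if (dip_feasible(z, cum, n, mid)) hi = mid; else lo = mid;
    }
    return hi;
}
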