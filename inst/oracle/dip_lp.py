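"""Brute-force dip computation by linear programming.

The dip of an empirical CDF is the smallest sup-norm distance to a unimodal
CDF (convex up to the mode, concave after it, atom allowed at the mode only).
For each candidate mode placement -- inside a gap between adjacent distinct
data values, or at a data value with a jump -- the minimal distance is the
optimum of a small LP in the CDF values at the data points.  The dip is the
minimum over placements.  Reads {"samples": [[...], ...]} as JSON on stdin,
writes {"dip": [...]} on stdout.  Used only as an independent test oracle.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def dip_lp(x):
    x = np.sort(np.asarray(x, dtype=float))
    n = len(x)
    if n <= 1:
        return 0.0
    z, counts = np.unique(x, return_counts=True)
    cum = np.cumsum(counts)
    p = len(z)
    if p == 1:
        return 0.0
    best = np.inf

    def solve(A_ub, b_ub, nvar):
        c = np.zeros(nvar)
        c[-1] = 1.0  # minimise t
        bounds = [(0.0, 1.0)] * (nvar - 1) + [(0.0, None)]
        res = linprog(c, A_ub=A_ub, b_ub=b_ub, bounds=bounds, method="highs")
        return res.fun if res.status == 0 else np.inf

    def band_rows(rows, rhs, idx, lo_target, hi_target, nvar):
        # g_idx >= lo_target - t ; g_idx <= hi_target + t
        r = np.zeros(nvar); r[idx] = -1.0; r[-1] = -1.0
        rows.append(r); rhs.append(-lo_target)
        r = np.zeros(nvar); r[idx] = 1.0; r[-1] = -1.0
        rows.append(r); rhs.append(hi_target)

    def mono_rows(rows, rhs, i, j, nvar):
        # g_i <= g_j
        r = np.zeros(nvar); r[i] = 1.0; r[j] = -1.0
        rows.append(r); rhs.append(0.0)

    def convex_row(rows, rhs, a, b, c_, xa, xb, xc, nvar, sense):
        # sense=+1 convex: slope(b,c) >= slope(a,b);  -1 concave
        r = np.zeros(nvar)
        r[a] = sense * (1.0 / (xb - xa))
        r[b] = sense * (-1.0 / (xb - xa) - 1.0 / (xc - xb))
        r[c_] = sense * (1.0 / (xc - xb))
        rows.append(-r); rhs.append(0.0)   # want r . g >= 0

    F = cum / n
    Fprev = np.concatenate([[0.0], F[:-1]])

    # continuous mode at data value z_m: convex on 0..m, concave on m..p-1
    for m in range(0, p):
        nvar = p + 1
        rows, rhs = [], []
        for i in range(p):
            band_rows(rows, rhs, i, F[i], Fprev[i], nvar)
            if i + 1 < p:
                mono_rows(rows, rhs, i, i + 1, nvar)
        for i in range(1, p - 1):
            if i + 1 <= m:
                convex_row(rows, rhs, i - 1, i, i + 1, z[i - 1], z[i], z[i + 1], nvar, +1)
            if i - 1 >= m:
                convex_row(rows, rhs, i - 1, i, i + 1, z[i - 1], z[i], z[i + 1], nvar, -1)
        best = min(best, solve(np.array(rows), np.array(rhs), nvar))

    # mode at data value z_m with a jump: extra variable v = G(z_m-)
    for m in range(p):
        nvar = p + 2          # g_0..g_{p-1}, v, t
        vi = p
        rows, rhs = [], []
        for i in range(p):
            if i == m:
                band_rows(rows, rhs, i, F[i], F[i], nvar)       # value at jump
            else:
                band_rows(rows, rhs, i, F[i], Fprev[i], nvar)
            if i + 1 < p:
                mono_rows(rows, rhs, i, i + 1, nvar)
        band_rows(rows, rhs, vi, Fprev[m], Fprev[m], nvar)
        if m >= 1:
            mono_rows(rows, rhs, m - 1, vi, nvar)
        mono_rows(rows, rhs, vi, m, nvar)
        # convex on (g_0..g_{m-1}, v at z_m)
        for i in range(1, m):
            xc_ = z[m] if i + 1 == m else z[i + 1]
            ci = vi if i + 1 == m else i + 1
            convex_row(rows, rhs, i - 1, i, ci, z[i - 1], z[i], xc_, nvar, +1)
        # concave on (g_m..g_{p-1})
        for i in range(m + 1, p - 1):
            convex_row(rows, rhs, i - 1, i, i + 1, z[i - 1], z[i], z[i + 1], nvar, -1)
        best = min(best, solve(np.array(rows), np.array(rhs), nvar))

    return float(best)


def main():
    data = json.load(sys.stdin)
    out = [dip_lp(s) for s in data["samples"]]
    json.dump({"dip": out}, sys.stdout)


if __name__ == "__main__":
    main()
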