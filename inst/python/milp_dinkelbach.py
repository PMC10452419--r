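"""Dinkelbach solver for one FDR-bounded minimum-conductance subnetwork.

Reads an instance JSON (written by the R front end) and writes a result
JSON. The fractional objective cut(x)/volume(x) is minimized by Dinkelbach
iteration: each round solves the parametric MILP

    min  sum_k c_k * y_k + sum_i (b_i - lam * d_i) * x_i
    s.t. sum_i (lfdr_i - B) * x_i <= 0            (FDR)
         y_k >= |x_i - x_j| for adjacent genes     (cut linearization)
         single-commodity flow from the seed       (connectivity)
         x_seed = 1, x binary

and updates lam to the achieved ratio until no further improvement. The
y upper-bound constraints are omitted: with c_k >= 0 and minimization the
lower bounds are tight at the optimum. Flow arcs carry capacity (n - 1),
gated by both endpoints' x variables; every selected non-seed gene consumes
one unit of flow, which forces the selection to be connected to the seed in
the physical local-graph adjacency.

Backend: scipy.optimize.milp (HiGHS branch-and-bound).
"""
import json
import sys
import time

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def build_constraints(n, pi, pj, seed, lfdr, B, forbid_all=False):
    m = len(pi)
    nx, ny, nf = n, m, 2 * m
    nv = nx + ny + nf

    rows, cols, vals, lo, hi = [], [], [], [], []
    r = 0

    def add_row(cidx, cval, lb, ub):
        nonlocal r
        rows.extend([r] * len(cidx))
        cols.extend(cidx)
        vals.extend(cval)
        lo.append(lb)
        hi.append(ub)
        r += 1

    # FDR: sum (lfdr_i - B) x_i <= 0
    add_row(list(range(n)), [w - B for w in lfdr], -np.inf, 0.0)

    if forbid_all and n > 1:
        # selecting every gene would cover the whole state space, where the
        # conductance ratio is undefined
        add_row(list(range(n)), [1.0] * n, -np.inf, float(n - 1))

    big = float(n - 1) if n > 1 else 1.0
    for k in range(m):
        i, j = pi[k], pj[k]
        yk = nx + k
        # y_k >= x_i - x_j  and  y_k >= x_j - x_i
        add_row([i, j, yk], [1.0, -1.0, -1.0], -np.inf, 0.0)
        add_row([j, i, yk], [1.0, -1.0, -1.0], -np.inf, 0.0)
        # arcs 2k (i -> j) and 2k+1 (j -> i), capacity gated by both ends
        for a, (t, h) in ((2 * k, (i, j)), (2 * k + 1, (j, i))):
            fa = nx + ny + a
            add_row([fa, t], [1.0, -big], -np.inf, 0.0)
            add_row([fa, h], [1.0, -big], -np.inf, 0.0)

    # flow conservation: for u != seed, inflow - outflow = x_u;
    # for the seed, outflow - inflow = sum_{u != seed} x_u
    inc = {u: ([], []) for u in range(n)}  # (in-arcs, out-arcs)
    for k in range(m):
        i, j = pi[k], pj[k]
        inc[j][0].append(2 * k)
        inc[i][1].append(2 * k)
        inc[i][0].append(2 * k + 1)
        inc[j][1].append(2 * k + 1)
    for u in range(n):
        cin = [nx + ny + a for a in inc[u][0]]
        cout = [nx + ny + a for a in inc[u][1]]
        if u == seed:
            cidx = cout + cin + [v for v in range(n) if v != seed]
            cval = [1.0] * len(cout) + [-1.0] * len(cin) + [-1.0] * (n - 1)
        else:
            cidx = cin + cout + [u]
            cval = [1.0] * len(cin) + [-1.0] * len(cout) + [-1.0]
        add_row(cidx, cval, 0.0, 0.0)

    A = sparse.csr_matrix((vals, (rows, cols)), shape=(r, nv))
    con = LinearConstraint(A, np.array(lo), np.array(hi))

    lb = np.zeros(nv)
    ub = np.concatenate([np.ones(nx + ny), np.full(nf, big)])
    lb[seed] = 1.0
    integrality = np.concatenate([np.ones(nx), np.zeros(ny + nf)])
    return con, Bounds(lb, ub), integrality, nv


def main(inst_path, out_path):
    with open(inst_path) as fh:
        inst = json.load(fh)
    n = int(inst["n"])
    seed = int(inst["seed"]) - 1
    pi = [int(v) - 1 for v in inst.get("pair_i", [])]
    pj = [int(v) - 1 for v in inst.get("pair_j", [])]
    pc = [float(v) for v in inst.get("pair_c", [])]
    b = np.asarray(inst["b"], dtype=float)
    d = np.asarray(inst["d"], dtype=float)
    lfdr = [float(v) for v in inst["lfdr"]]
    B = float(inst["B"])
    time_limit = float(inst.get("time_limit", 600.0))
    gap = float(inst.get("mip_rel_gap", 1e-6))
    tol = float(inst.get("dinkelbach_tol", 1e-9))
    max_iter = int(inst.get("max_iter", 50))

    con, bounds, integrality, nv = build_constraints(
        n, pi, pj, seed, lfdr, B, forbid_all=bool(inst.get("forbid_all", False)))
    m = len(pi)

    def N_of(sel):
        x = np.zeros(n)
        x[sel] = 1.0
        cut = sum(pc[k] * abs(x[pi[k]] - x[pj[k]]) for k in range(m))
        return cut + float(b @ x)

    def D_of(sel):
        return float(d[sel].sum())

    best = [seed]
    lam = N_of(best) / D_of(best)
    lambdas = [lam]
    status = "optimal"
    certificate = None
    it = 0
    t0 = time.monotonic()

    while it < max_iter:
        it += 1
        obj = np.concatenate([b - lam * d, np.asarray(pc, dtype=float),
                              np.zeros(2 * m)])
        remaining = time_limit - (time.monotonic() - t0)
        if remaining <= 0:
            status = "incumbent"
            break
        res = milp(obj, constraints=con, bounds=bounds,
                   integrality=integrality,
                   options={"time_limit": max(1.0, remaining),
                            "mip_rel_gap": gap, "presolve": True})
        if res.status != 0 or res.x is None:
            status = "incumbent" if res.status == 1 else "solver_failed"
            break
        sel = [i for i in range(n) if res.x[i] > 0.5]
        val = N_of(sel) - lam * D_of(sel)  # recomputed exactly from integers
        certificate = val
        new_lam = N_of(sel) / D_of(sel)
        if val >= -tol:
            if new_lam < lam:  # keep a marginally better incumbent
                best, lam = sel, new_lam
                lambdas.append(lam)
            break
        best = sel
        if lam - new_lam < tol:
            lam = new_lam
            lambdas.append(lam)
            break
        lam = new_lam
        lambdas.append(lam)

    out = {
        "selected": [i + 1 for i in best],
        "conductance": lam,
        "lambdas": lambdas,
        "iterations": it,
        "status": status,
        "certificate": certificate,
    }
    with open(out_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
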