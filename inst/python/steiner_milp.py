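"""Network-flow Steiner arborescence MILP, solved with scipy/HiGHS.

Reads a JSON problem {n, edges: [[from,to,weight],...] (1-based),
root, targets, time_limit, gap} and writes a JSON solution
{status, success, objective, gap, b, d}.

Formulation (per edge (u,v)): integer flow d_uv in {0..|S|}, binary
selection b_uv >= d_uv/|S|; minimize sum b_uv * w(u,v) subject to flow
conservation at non-root non-target nodes, |S| units leaving the root, and
one unit absorbed at each target.
"""
import json
import sys

import numpy as np
from scipy.optimize import milp, LinearConstraint, Bounds
from scipy.sparse import lil_matrix


def main(inp, outp):
    with open(inp) as fh:
        prob = json.load(fh)
    edges = np.asarray(prob["edges"], dtype=float)
    if edges.ndim == 1:
        edges = edges.reshape(1, -1)
    n = int(prob["n"])
    root = int(prob["root"]) - 1
    t_raw = prob["targets"]
    if isinstance(t_raw, (int, float)):
        t_raw = [t_raw]
    targets = set(int(t) - 1 for t in t_raw)
    ne = edges.shape[0]
    src = edges[:, 0].astype(int) - 1
    dst = edges[:, 1].astype(int) - 1
    w = edges[:, 2]
    ns = len(targets)

    nvar = 2 * ne  # [d flows | b selections]
    c = np.concatenate([np.zeros(ne), w])

    rows = []
    lo = []
    hi = []
    A = lil_matrix((n + ne, nvar))
    r = 0
    for v in range(n):
        if v == root:
            for e in np.where(src == v)[0]:
                A[r, e] = 1.0
            lo.append(ns)
            hi.append(ns)
        elif v in targets:
            for e in np.where(dst == v)[0]:
                A[r, e] = 1.0
            lo.append(1.0)
            hi.append(1.0)
        else:
            for e in np.where(dst == v)[0]:
                A[r, e] = 1.0
            for e in np.where(src == v)[0]:
                A[r, e] = -1.0
            lo.append(0.0)
            hi.append(0.0)
        r += 1
    # coupling: d_e - |S| * b_e <= 0
    for e in range(ne):
        A[r, e] = 1.0
        A[r, ne + e] = -float(ns)
        lo.append(-np.inf)
        hi.append(0.0)
        r += 1

    cons = LinearConstraint(A.tocsc(), np.array(lo), np.array(hi))
    lb = np.zeros(nvar)
    ub = np.concatenate([np.full(ne, float(ns)), np.ones(ne)])
    integrality = np.ones(nvar)
    opts = {"time_limit": float(prob.get("time_limit", 12600)),
            "mip_rel_gap": float(prob.get("gap", 0.0))}
    res = milp(c=c, constraints=cons, bounds=Bounds(lb, ub),
               integrality=integrality, options=opts)
    out = {
        "success": bool(res.success),
        "status": int(res.status),
        "message": str(res.message),
        "objective": float(res.fun) if res.fun is not None else None,
        "gap": float(getattr(res, "mip_gap", 0.0) or 0.0),
        "d": res.x[:ne].tolist() if res.x is not None else None,
        "b": res.x[ne:].tolist() if res.x is not None else None,
    }
    with open(outp, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
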