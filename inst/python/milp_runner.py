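"""Solve one or more MILP models described in a JSON file with HiGHS.

Usage: python milp_runner.py models.json solutions.json

Each model: nvar, obj, lb, ub, integer (0/1 per variable), sparse
constraint triplets (ai, aj, av; 1-based), row ranges rlb/rub, maximize,
relax, time_limit (seconds, -1 for none), mip_gap.  Bounds with absolute
value >= 1e30 are infinities.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

INF = 1e30


def _inf(a):
    a = np.asarray(a, dtype=float)
    a[a >= INF] = np.inf
    a[a <= -INF] = -np.inf
    return a


def solve_one(m):
    n = int(m["nvar"])
    c = np.asarray(m["obj"], dtype=float)
    if m.get("maximize", True):
        c = -c
    lb = _inf(m["lb"])
    ub = _inf(m["ub"])
    integrality = np.asarray(m["integer"], dtype=int)
    if m.get("relax", False):
        integrality = np.zeros(n, dtype=int)
    ai = np.asarray(m["ai"], dtype=int) - 1
    aj = np.asarray(m["aj"], dtype=int) - 1
    av = np.asarray(m["av"], dtype=float)
    nrow = len(m["rlb"])
    A = sparse.csc_matrix((av, (ai, aj)), shape=(nrow, n))
    cons = LinearConstraint(A, _inf(m["rlb"]), _inf(m["rub"]))
    options = {"mip_rel_gap": float(m.get("mip_gap", 1e-9))}
    tl = float(m.get("time_limit", -1))
    if tl > 0:
        options["time_limit"] = tl
    res = milp(c=c, constraints=cons, integrality=integrality,
               bounds=Bounds(lb, ub), options=options)
    status = {0: "optimal", 1: "limit", 2: "infeasible",
              3: "unbounded"}.get(res.status, "failed")
    out = {"status": status}
    if res.x is not None:
        obj = float(np.dot(np.asarray(m["obj"], dtype=float), res.x))
        out["objective"] = obj
        out["values"] = [float(v) for v in res.x]
    return out


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    if isinstance(payload, dict):
        payload = [payload]
    results = [solve_one(m) for m in payload]
    with open(sys.argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
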