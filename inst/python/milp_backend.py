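#!/usr/bin/env python
"""Batch LP/MILP backend: reads a JSON problem list, solves each with
scipy.optimize (HiGHS), writes a JSON result list.

Usage: python milp_backend.py <in.json> <out.json>

Problem schema (all arrays plain lists; constraint matrices in triplet form):
  sense        "min" | "max"
  c            objective coefficients, length n
  n            number of variables
  A            {"i": [...], "j": [...], "x": [...], "m": nrow} row/col 0-based
  cl, cu       per-row lower/upper constraint bounds (-1e30/1e30 = infinite)
  lb, ub       variable bounds
  integrality  list of 0/1 (1 = integer variable); omitted => all continuous
  mip_gap      optional relative MIP gap
  time_limit   optional seconds
"""
import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import csr_matrix

INF = 1e30


def _solve(p):
    n = int(p["n"])
    c = np.asarray(p["c"], dtype=float)
    sense = p.get("sense", "min")
    if sense == "max":
        c = -c
    A = p["A"]
    m = int(A["m"])
    constraints = []
    if m > 0:
        mat = csr_matrix(
            (np.asarray(A["x"], dtype=float),
             (np.asarray(A["i"], dtype=int), np.asarray(A["j"], dtype=int))),
            shape=(m, n),
        )
        cl = np.asarray(p["cl"], dtype=float)
        cu = np.asarray(p["cu"], dtype=float)
        cl[cl <= -INF] = -np.inf
        cu[cu >= INF] = np.inf
        constraints.append(LinearConstraint(mat, cl, cu))
    lb = np.asarray(p["lb"], dtype=float)
    ub = np.asarray(p["ub"], dtype=float)
    lb[lb <= -INF] = -np.inf
    ub[ub >= INF] = np.inf
    integrality = np.asarray(p.get("integrality", [0] * n), dtype=int)
    options = {}
    if "mip_gap" in p:
        options["mip_rel_gap"] = float(p["mip_gap"])
    if "time_limit" in p:
        options["time_limit"] = float(p["time_limit"])
    res = milp(
        c=c,
        constraints=constraints,
        integrality=integrality,
        bounds=Bounds(lb, ub),
        options=options,
    )
    status_map = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
                  3: "unbounded", 4: "error"}
    out = {"status": status_map.get(res.status, "error")}
    if res.x is not None:
        obj = float(res.fun)
        out["objective"] = -obj if sense == "max" else obj
        out["x"] = [float(v) for v in res.x]
    return out


def main(argv):
    with open(argv[1]) as fh:
        payload = json.load(fh)
    results = [_solve(p) for p in payload["problems"]]
    with open(argv[2], "w") as fh:
        json.dump({"results": results}, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
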