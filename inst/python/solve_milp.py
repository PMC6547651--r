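"""HiGHS backend for colonet MIP instances.

Reads a sparse-triplet MILP from binary files in the directory given as
argv[1] (written by colonet::solve_mip) and writes the solution back as
x.bin + result.json. Exit code 0 covers optimal, infeasible and timeout
outcomes; a non-zero exit signals a backend failure.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def main(d):
    with open(f"{d}/header.json") as fh:
        hdr = json.load(fh)
    n_var, n_con, nnz = hdr["n_var"], hdr["n_con"], hdr["nnz"]
    ai = np.fromfile(f"{d}/ai.bin", dtype=np.int32, count=nnz)
    aj = np.fromfile(f"{d}/aj.bin", dtype=np.int32, count=nnz)
    av = np.fromfile(f"{d}/av.bin", dtype=np.float64, count=nnz)
    bl = np.fromfile(f"{d}/bl.bin", dtype=np.float64, count=n_con)
    bu = np.fromfile(f"{d}/bu.bin", dtype=np.float64, count=n_con)
    c = np.fromfile(f"{d}/c.bin", dtype=np.float64, count=n_var)
    lb = np.fromfile(f"{d}/lb.bin", dtype=np.float64, count=n_var)
    ub = np.fromfile(f"{d}/ub.bin", dtype=np.float64, count=n_var)
    integ = np.fromfile(f"{d}/int.bin", dtype=np.int32, count=n_var)
    A = sparse.csc_matrix((av, (ai, aj)), shape=(n_con, n_var))
    options = {"mip_rel_gap": hdr.get("mip_rel_gap", 0) or 0}
    if hdr.get("time_limit"):
        options["time_limit"] = float(hdr["time_limit"])
    res = milp(c=c, constraints=LinearConstraint(A, bl, bu),
               integrality=integ, bounds=Bounds(lb, ub), options=options)
    # scipy status codes: 0 optimal, 1 iteration/time limit, 2 infeasible,
    # 3 unbounded, 4 other
    status_class = {0: "optimal", 1: "timeout", 2: "infeasible",
                    3: "unbounded"}.get(res.status, "error")
    out = {"status": int(res.status), "status_class": status_class,
           "success": bool(res.success), "message": str(res.message),
           "fun": None if res.x is None else float(res.fun)}
    if res.x is not None:
        np.asarray(res.x, dtype=np.float64).tofile(f"{d}/x.bin")
    with open(f"{d}/result.json", "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1])
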