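"""Bounded LP solver backend: c'v optimized over S v = 0, lb <= v <= ub.

Called by the R package with two arguments: an input JSON holding the
problem (obj, row-major S, m, n, lb, ub, maximize) and an output path.
Writes status ("optimal" / "infeasible" / "unbounded"), objective and the
solution vector as JSON. Solved with scipy's HiGHS interface.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def main(fin, fout):
    spec = json.load(open(fin))
    n = int(spec["n"])
    m = int(spec["m"])
    c = np.asarray(spec["obj"], float)
    S = np.asarray(spec["S"], float).reshape(m, n) if m else np.zeros((0, n))
    sign = -1.0 if spec["maximize"] else 1.0
    res = linprog(sign * c, A_eq=S, b_eq=np.zeros(m),
                  bounds=list(zip(spec["lb"], spec["ub"])), method="highs")
    if res.status == 0:
        out = {"status": "optimal",
               "objective": float(c @ res.x),
               "solution": [float(v) for v in res.x]}
    elif res.status == 2:
        out = {"status": "infeasible", "objective": None, "solution": None}
    else:
        out = {"status": "unbounded", "objective": None, "solution": None}
    json.dump(out, open(fout, "w"))


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
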