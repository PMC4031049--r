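"""Independent brute-force oracle for the synthetic-lethality pipeline.

Reads tsv-triplet fixture directories straight from disk, rebuilds every
linear program by hand and solves it with scipy's HiGHS solver -- a separate
language, parser and solver from the R package under test. For each fixture
it reports wild-type growth, the essential-reaction set, the candidate set,
all synthetic lethal pairs found by exhaustive double-deletion enumeration,
their subtype, and the single-knockout growths of every pair member.

Subtypes are called through forced activity at the fixed optimum: with
biomass pinned at its maximum, a redundancy member cannot avoid carrying
flux (minimal flux > 0) while a plasticity backup can rest at zero.

Usage: python pyoracle.py <dir-with-fixture-subdirs> <out.json>
"""
import csv
import itertools
import json
import os
import sys

import numpy as np
from scipy.optimize import linprog


def truthy(x):
    return str(x).strip().lower() in ("true", "t", "1", "yes")


def read_fixture(d):
    with open(os.path.join(d, "reactions.tsv")) as fh:
        rxns = list(csv.DictReader(fh, delimiter="\t"))
    with open(os.path.join(d, "metabolites.tsv")) as fh:
        mets = list(csv.DictReader(fh, delimiter="\t"))
    internal = [m["id"] for m in mets if not truthy(m.get("is_external", "false"))]
    idx = {m: i for i, m in enumerate(internal)}
    ids = [r["id"] for r in rxns]
    S = np.zeros((len(internal), len(ids)))
    for j, r in enumerate(rxns):
        for kv in r["stoichiometry"].split(";"):
            met, coef = kv.split(":")
            if met in idx:
                S[idx[met], j] = float(coef)
    return {
        "ids": ids,
        "S": S,
        "lb": np.array([float(r["lower_bound"]) for r in rxns]),
        "ub": np.array([float(r["upper_bound"]) for r in rxns]),
        "gpr": [r.get("gpr", "") for r in rxns],
        "is_ex": np.array([truthy(r.get("is_exchange", "f")) for r in rxns]),
        "is_bm": np.array([truthy(r.get("is_biomass", "f")) for r in rxns]),
    }


def solve(c, S, lb, ub, maximize):
    sign = -1.0 if maximize else 1.0
    res = linprog(sign * np.asarray(c, float), A_eq=S, b_eq=np.zeros(S.shape[0]),
                  bounds=list(zip(lb, ub)), method="highs")
    if res.status != 0:
        return None
    return float(np.asarray(c, float) @ res.x), res.x


def growth(om, deleted=()):
    lb, ub = om["lb"].copy(), om["ub"].copy()
    for r in deleted:
        j = om["ids"].index(r)
        lb[j] = ub[j] = 0.0
    out = solve(om["is_bm"].astype(float), om["S"], lb, ub, True)
    return 0.0 if out is None else out[0]


def flux_extreme(om, rxn, maximize, bm_lb=None, bm_ub=None):
    lb, ub = om["lb"].copy(), om["ub"].copy()
    bm = int(np.flatnonzero(om["is_bm"])[0])
    if bm_lb is not None:
        lb[bm] = max(lb[bm], bm_lb)
    if bm_ub is not None:
        ub[bm] = min(ub[bm], bm_ub) if bm_ub < ub[bm] else ub[bm]
    c = np.zeros(len(om["ids"]))
    c[om["ids"].index(rxn)] = 1.0
    out = solve(c, om["S"], lb, ub, maximize)
    assert out is not None, f"FVA LP infeasible for {rxn}"
    return out[0]


def analyse(d):
    om = read_fixture(d)
    wt = growth(om)
    eps = 1e-6 * wt
    essential = sorted(r for r in om["ids"] if growth(om, (r,)) <= eps)
    active = {
        r: abs(flux_extreme(om, r, True, bm_lb=0.0)) > 1e-9
        or abs(flux_extreme(om, r, False, bm_lb=0.0)) > 1e-9
        for r in om["ids"]
    }
    candidates = sorted(
        r for j, r in enumerate(om["ids"])
        if om["gpr"][j].strip() and not om["is_ex"][j] and not om["is_bm"][j]
        and active[r] and r not in essential
    )
    pairs = []
    for a, b in itertools.combinations(candidates, 2):
        if growth(om, (a, b)) <= eps:
            # forced-activity subtype at biomass fixed to its optimum
            min_a = flux_extreme(om, a, False, bm_lb=wt)
            min_b = flux_extreme(om, b, False, bm_lb=wt)
            za, zb = abs(min_a) <= 1e-9, abs(min_b) <= 1e-9
            subtype = "PSL" if (za != zb) else ("RSL" if not (za or zb) else "degenerate")
            pairs.append({
                "rxn_a": a, "rxn_b": b, "subtype": subtype,
                "active": (a if zb else b) if subtype == "PSL" else None,
                "growth_ko_a": growth(om, (a,)),
                "growth_ko_b": growth(om, (b,)),
            })
    return {"wild_type_growth": wt, "essential": essential,
            "candidates": candidates, "pairs": pairs}


def main(parent, out):
    results = {}
    for name in sorted(os.listdir(parent)):
        d = os.path.join(parent, name)
        if os.path.isdir(d) and os.path.exists(os.path.join(d, "reactions.tsv")):
            results[name] = analyse(d)
    with open(out, "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
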