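#!/usr/bin/env python
"""Transportation-LP oracle for tree earth-mover's distances.

Reads a JSON file {"instances": [{"cost": [[...]], "a": [...], "b": [...]}]}
and writes a JSON list of optimal transport costs. Solved as a dense LP
(min <c, x> with exact row/column marginal constraints) with scipy; kept
independent of any tree-traversal shortcut.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve(cost, a, b):
    cost = np.asarray(cost, dtype=float)
    a = np.asarray(a, dtype=float)
    b = np.asarray(b, dtype=float)
    b = b * (a.sum() / b.sum())  # guard against last-ulp imbalance
    n, m = cost.shape
    A_eq = []
    b_eq = []
    for i in range(n):
        row = np.zeros((n, m))
        row[i, :] = 1.0
        A_eq.append(row.ravel())
        b_eq.append(a[i])
    for j in range(m):
        col = np.zeros((n, m))
        col[:, j] = 1.0
        A_eq.append(col.ravel())
        b_eq.append(b[j])
    res = linprog(cost.ravel(), A_eq=np.array(A_eq), b_eq=np.array(b_eq),
                  bounds=(0, None), method="highs")
    if not res.success:
        raise RuntimeError("LP failed: " + res.message)
    return float(res.fun)


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    values = [solve(inst["cost"], inst["a"], inst["b"])
              for inst in payload["instances"]]
    with open(sys.argv[2], "w") as fh:
        json.dump(values, fh)


if __name__ == "__main__":
    main()
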