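"""Independent reference route for the trace test.

Reads a long CSV (columns: dataset, y1, y2), runs statsmodels'
coint_johansen with an unrestricted constant (det_order = 0) and one
lagged difference on each dataset, and writes one CSV row per dataset:
dataset, lambda1, lambda2, trace_r0, trace_r1, beta0 (leading eigenvector
normalized to its first component).
"""
import sys

import numpy as np
import pandas as pd
from statsmodels.tsa.vector_ar.vecm import coint_johansen

def main(inp, outp):
    df = pd.read_csv(inp)
    rows = []
    for key, g in df.groupby("dataset", sort=True):
        x = g[["y1", "y2"]].to_numpy(float)
        res = coint_johansen(x, det_order=0, k_ar_diff=1)
        beta0 = res.evec[1, 0] / res.evec[0, 0]
        rows.append((key, res.eig[0], res.eig[1], res.lr1[0], res.lr1[1], beta0))
    out = pd.DataFrame(rows, columns=["dataset", "lambda1", "lambda2",
                                      "trace_r0", "trace_r1", "beta0"])
    out.to_csv(outp, index=False, float_format="%.12g")

if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
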