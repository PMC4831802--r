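# Independent oracle for the circular EMD: solves each instance as a full
# transportation linear program (scipy linprog / HiGHS) on the circular
# cost matrix d(i, j) = min(|i - j|, B - |i - j|).

emd_lp_oracle_script <- '
import json, sys
import numpy as np
from scipy.optimize import linprog

instances = json.load(sys.stdin)
out = []
for inst in instances:
    p = np.array(inst["p"], dtype=float); p = p / p.sum()
    q = np.array(inst["q"], dtype=float); q = q / q.sum()
    B = len(p)
    idx = np.arange(B)
    d = np.abs(idx[:, None] - idx[None, :])
    cost = np.minimum(d, B - d).astype(float).ravel()
    A_eq = []
    b_eq = []
    for i in range(B):
        row = np.zeros((B, B)); row[i, :] = 1
        A_eq.append(row.ravel()); b_eq.append(p[i])
    for j in range(B - 1):  # drop one redundant constraint
        col = np.zeros((B, B)); col[:, j] = 1
        A_eq.append(col.ravel()); b_eq.append(q[j])
    res = linprog(cost, A_eq=np.array(A_eq), b_eq=np.array(b_eq),
                  bounds=(0, None), method="highs")
    assert res.status == 0, res.message
    out.append(res.fun)
json.dump(out, sys.stdout)
'

emd_lp_oracle <- function(pairs) {
  # pairs: list of list(p = ..., q = ...); returns LP distances
  instances <- lapply(pairs, function(x) list(p = as.numeric(x$p),
                                              q = as.numeric(x$q)))
  json_in <- vapply(instances, function(x) {
    sprintf('{"p":[%s],"q":[%s]}',
            paste(format(x$p, digits = 17), collapse = ","),
            paste(format(x$q, digits = 17), collapse = ","))
  }, character(1))
  infile <- tempfile(fileext = ".json")
  writeLines(sprintf("[%s]", paste(json_in, collapse = ",")), infile)
  scr <- tempfile(fileext = ".py")
  writeLines(emd_lp_oracle_script, scr)
  out <- system2("python", scr, stdout = TRUE, stdin = infile)
  as.numeric(jsonlite_min_parse(paste(out, collapse = "")))
}

# minimal parser for a flat JSON array of numbers (avoids extra deps)
jsonlite_min_parse <- function(txt) {
  txt <- gsub("\\[|\\]|\\s", "", txt)
  as.numeric(strsplit(txt, ",")[[1]])
}
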