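"""ViennaRNA worker: executes a batch of folding operations described by a
JSON request file and writes a JSON response to stdout.

Request: {"params": "turner1999"|"turner2004", "temperature": 37.0,
          "dangles": 2, "ops": [ ... ]}
Ops:
  {"op": "mfe",    "seq": s}                    -> {structure, energy}
  {"op": "eval",   "seq": s, "structure": db}   -> {energy}
  {"op": "pf",     "seq": s}                    -> {ensemble_energy, kT,
                                                    pairs: [[i, j, p], ...],
                                                    unpaired: [p1..pn]}
  {"op": "sample", "seq": s, "n": N, "seed": k} -> {structures: [...]}

Probabilities below 1e-12 are omitted from `pairs`.
"""
import json
import sys

import RNA


def load_params(name):
    if name == "turner1999":
        RNA.params_load_RNA_Turner1999()
    elif name == "turner2004":
        RNA.params_load_RNA_Turner2004()
    else:
        raise ValueError("unknown parameter set: %s" % name)


def model(req):
    md = RNA.md()
    md.temperature = float(req.get("temperature", 37.0))
    md.dangles = int(req.get("dangles", 2))
    md.uniq_ML = 1
    return md


def with_pf(seq, md):
    fc = RNA.fold_compound(seq, md)
    _, mfe = fc.mfe()
    fc.exp_params_rescale(mfe)
    _, g = fc.pf()
    return fc, g


def run_op(op, md):
    kind = op["op"]
    seq = op["seq"]
    if kind == "mfe":
        fc = RNA.fold_compound(seq, md)
        ss, e = fc.mfe()
        return {"structure": ss, "energy": e}
    if kind == "eval":
        fc = RNA.fold_compound(seq, md)
        return {"energy": fc.eval_structure(op["structure"])}
    if kind == "pf":
        fc, g = with_pf(seq, md)
        n = len(seq)
        bpp = fc.bpp()
        pairs = []
        row = [0.0] * (n + 1)
        for i in range(1, n + 1):
            for j in range(i + 1, n + 1):
                p = bpp[i][j]
                if p > 1e-12:
                    pairs.append([i, j, p])
                    row[i] += p
                    row[j] += p
        unpaired = [1.0 - row[i] for i in range(1, n + 1)]
        return {
            "ensemble_energy": g,
            "kT": fc.exp_params.kT / 1000.0,
            "pairs": pairs,
            "unpaired": unpaired,
        }
    if kind == "sample":
        fc, _ = with_pf(seq, md)
        RNA.init_rand(int(op["seed"]))
        return {"structures": list(fc.pbacktrack(int(op["n"])))}
    raise ValueError("unknown op: %s" % kind)


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    load_params(req.get("params", "turner1999"))
    md = model(req)
    out = [run_op(op, md) for op in req["ops"]]
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
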