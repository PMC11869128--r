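"""Batched RDKit helper for the mfbo R package.

Reads one JSON request object from the file given as argv[1] and writes a
JSON reply to the file given as argv[2].  Every request carries an "op"
and a payload; all operations are batched so the R side pays the
interpreter start-up cost once per batch, not once per molecule.

Request ops
-----------
process:   {"op": "process", "smiles": [...], "radius": 2, "nbits": 1024,
            "want": ["fp", "mw", "qed"]}
           -> per molecule {ok, canonical, bits, mw, qed}; bits are 0-based
           Morgan fingerprint on-bit indices.
match:     {"op": "match", "smiles": [...], "smarts": [...]}
           -> {ok: [...], hits: row-major n_smiles x n_smarts 0/1 matrix}
react:     {"op": "react", "jobs": [{"smarts": rxn, "reactants": [...]}]}
           -> per job {status: "ok"|"nomatch"|"error", products: [...]}
           products are canonical SMILES of all distinct outcomes, sorted.
validate_smarts: {"op": "validate_smarts", "smarts": [...]} -> {ok: [...]}
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, QED

RDLogger.DisableLog("rdApp.*")


def _mol(smi):
    if not isinstance(smi, str) or smi == "":
        return None
    return Chem.MolFromSmiles(smi)


def op_process(req):
    radius = int(req.get("radius", 2))
    nbits = int(req.get("nbits", 1024))
    want = set(req.get("want", ["fp"]))
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append({"ok": False})
            continue
        rec = {"ok": True, "canonical": Chem.MolToSmiles(m)}
        if "fp" in want:
            fp = AllChem.GetMorganFingerprintAsBitVect(m, radius, nBits=nbits)
            rec["bits"] = sorted(fp.GetOnBits())
        if "mw" in want:
            rec["mw"] = Descriptors.MolWt(m)
        if "qed" in want:
            try:
                rec["qed"] = QED.qed(m)
            except Exception:
                rec["qed"] = None
        out.append(rec)
    return {"records": out}


def op_match(req):
    pats, ok_p = [], []
    for s in req["smarts"]:
        p = Chem.MolFromSmarts(s)
        pats.append(p)
        ok_p.append(p is not None)
    ok_m, hits = [], []
    for smi in req["smiles"]:
        m = _mol(smi)
        ok_m.append(m is not None)
        if m is None:
            hits.append([0] * len(pats))
        else:
            hits.append([1 if (p is not None and m.HasSubstructMatch(p)) else 0
                         for p in pats])
    return {"ok_smiles": ok_m, "ok_smarts": ok_p, "hits": hits}


def op_react(req):
    out = []
    for job in req["jobs"]:
        try:
            rxn = AllChem.ReactionFromSmarts(job["smarts"])
        except Exception:
            out.append({"status": "error", "message": "bad reaction SMARTS"})
            continue
        mols = [_mol(s) for s in job["reactants"]]
        if any(m is None for m in mols):
            out.append({"status": "error", "message": "unparsable reactant"})
            continue
        if rxn.GetNumReactantTemplates() != len(mols):
            out.append({"status": "error", "message": "arity mismatch"})
            continue
        try:
            prod_sets = rxn.RunReactants(tuple(mols))
        except Exception:
            out.append({"status": "error", "message": "reaction failed"})
            continue
        prods = set()
        for ps in prod_sets:
            for p in ps:
                try:
                    Chem.SanitizeMol(p)
                    prods.add(Chem.MolToSmiles(p))
                except Exception:
                    pass
        if not prods:
            out.append({"status": "nomatch", "products": []})
        else:
            out.append({"status": "ok", "products": sorted(prods)})
    return {"results": out}


def op_validate_smarts(req):
    return {"ok": [Chem.MolFromSmarts(s) is not None for s in req["smarts"]]}


OPS = {
    "process": op_process,
    "match": op_match,
    "react": op_react,
    "validate_smarts": op_validate_smarts,
}


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    op = req.get("op")
    if op not in OPS:
        reply = {"error": "unknown op: %r" % op}
    else:
        try:
            reply = OPS[op](req)
        except Exception as exc:  # surface as a structured error, not a crash
            reply = {"error": "%s: %s" % (type(exc).__name__, exc)}
    with open(sys.argv[2], "w") as fh:
        json.dump(reply, fh)


if __name__ == "__main__":
    main()
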