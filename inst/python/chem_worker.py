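"""RDKit chemistry worker.

Serves SMILES sanitization/canonicalization, QED descriptor properties,
synthetic-accessibility scores and Morgan fingerprints to the R package over
a pair of FIFOs using a JSON-lines protocol.  One request object per line on
the request FIFO; one JSON reply per line on the response FIFO.

Usage: python chem_worker.py REQUEST_FIFO RESPONSE_FIFO
"""
import json
import os
import sys


def main() -> int:
    req_path, resp_path = sys.argv[1], sys.argv[2]
    # Signal liveness before the (blocking) FIFO open so the client can poll
    # a plain file with a timeout instead of blocking on the FIFO itself.
    with open(resp_path + ".alive", "w") as fh:
        fh.write(str(os.getpid()))
    fin = open(req_path, "r")

    from rdkit import Chem, RDLogger
    from rdkit.Chem import QED, AllChem, Descriptors
    RDLogger.DisableLog("rdApp.*")

    sa_scorer = None

    def get_sa_scorer():
        nonlocal sa_scorer
        if sa_scorer is None:
            from rdkit.Chem import RDConfig
            sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
            import sascorer
            sa_scorer = sascorer
        return sa_scorer

    def mols(smiles):
        return [Chem.MolFromSmiles(s) for s in smiles]

    def handle(msg):
        op = msg["op"]
        if op == "ping":
            return {"ok": True}
        smiles = msg.get("smiles", [])
        if op == "canon":
            out = []
            for m in mols(smiles):
                out.append(Chem.MolToSmiles(m) if m is not None else None)
            return {"canonical": out}
        if op == "qed_props":
            out = []
            for m in mols(smiles):
                if m is None:
                    out.append(None)
                else:
                    p = QED.properties(m)
                    out.append({"MW": p.MW, "ALOGP": p.ALOGP, "HBA": p.HBA,
                                "HBD": p.HBD, "PSA": p.PSA, "ROTB": p.ROTB,
                                "AROM": p.AROM, "ALERTS": p.ALERTS})
            return {"properties": out}
        if op == "qed":
            out = []
            for m in mols(smiles):
                out.append(QED.qed(m) if m is not None else None)
            return {"qed": out}
        if op == "sa_score":
            sc = get_sa_scorer()
            out = []
            for m in mols(smiles):
                out.append(sc.calculateScore(m) if m is not None else None)
            return {"sa_score": out}
        if op == "morgan_fp":
            radius = int(msg.get("radius", 2))
            nbits = int(msg.get("nbits", 2048))
            gen = AllChem.GetMorganGenerator(radius=radius, fpSize=nbits)
            out = []
            for m in mols(smiles):
                if m is None:
                    out.append(None)
                else:
                    # 1-based bit positions for the R side
                    out.append([b + 1 for b in gen.GetFingerprint(m).GetOnBits()])
            return {"bits": out}
        if op == "descriptors":
            out = []
            for m in mols(smiles):
                if m is None:
                    out.append(None)
                else:
                    out.append({
                        "heavy_atoms": m.GetNumHeavyAtoms(),
                        "rings": m.GetRingInfo().NumRings(),
                        "mw": Descriptors.MolWt(m),
                        "tpsa": Descriptors.TPSA(m),
                        "logp": Descriptors.MolLogP(m),
                    })
            return {"descriptors": out}
        return {"error": f"unknown op: {op}"}

    with open(resp_path, "w") as fout:
        for line in fin:
            line = line.strip()
            if not line:
                continue
            try:
                msg = json.loads(line)
            except json.JSONDecodeError as exc:
                fout.write(json.dumps({"error": str(exc)}) + "\n")
                fout.flush()
                continue
            if msg.get("op") == "quit":
                break
            try:
                reply = handle(msg)
            except Exception as exc:  # noqa: BLE001 - reported to the client
                reply = {"error": f"{type(exc).__name__}: {exc}"}
            fout.write(json.dumps(reply) + "\n")
            fout.flush()
    return 0


if __name__ == "__main__":
    sys.exit(main())
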