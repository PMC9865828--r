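"""Batched RDKit helper for the ligandgen R package.

Usage: python chem_backend.py <op> <infile> <outfile> [args...]

  canon    <in> <out>                 canonical SMILES per line ("" = invalid)
  scaffold <in> <out>                 Bemis-Murcko scaffold SMILES per line
                                      ("" = acyclic, "!" = invalid input)
  props    <in> <out>                 JSON records: MW, LogP, QED, SA
  morgan   <in> <out> <radius> <nbits>  JSON: list of on-bit index lists

Input files contain one SMILES per line. Output is JSON (an array).
"""
import json
import sys

from rdkit import Chem, RDLogger

RDLogger.DisableLog("rdApp.*")


def read_lines(path):
    with open(path) as fh:
        return [ln.rstrip("\n") for ln in fh]


def op_canon(smiles):
    out = []
    for s in smiles:
        mol = Chem.MolFromSmiles(s)
        out.append(Chem.MolToSmiles(mol) if mol is not None else "")
    return out


def op_scaffold(smiles):
    from rdkit.Chem.Scaffolds import MurckoScaffold

    out = []
    for s in smiles:
        mol = Chem.MolFromSmiles(s)
        if mol is None:
            out.append("!")
            continue
        scaf = MurckoScaffold.GetScaffoldForMol(mol)
        out.append(Chem.MolToSmiles(scaf) if scaf.GetNumAtoms() else "")
    return out


def op_props(smiles):
    import os

    from rdkit.Chem import Descriptors, QED, RDConfig

    sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
    import sascorer

    out = []
    for s in smiles:
        mol = Chem.MolFromSmiles(s)
        if mol is None:
            out.append(None)
            continue
        out.append(
            {
                "MW": Descriptors.MolWt(mol),
                "LogP": Descriptors.MolLogP(mol),
                "QED": QED.qed(mol),
                "SA": sascorer.calculateScore(mol),
            }
        )
    return out


def op_morgan(smiles, radius, nbits):
    from rdkit.Chem import rdFingerprintGenerator

    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=nbits)
    out = []
    for s in smiles:
        mol = Chem.MolFromSmiles(s)
        if mol is None:
            out.append(None)
            continue
        out.append(sorted(gen.GetFingerprint(mol).GetOnBits()))
    return out


def main(argv):
    op, infile, outfile = argv[1], argv[2], argv[3]
    smiles = read_lines(infile)
    if op == "canon":
        res = op_canon(smiles)
    elif op == "scaffold":
        res = op_scaffold(smiles)
    elif op == "props":
        res = op_props(smiles)
    elif op == "morgan":
        res = op_morgan(smiles, int(argv[4]), int(argv[5]))
    else:
        raise SystemExit("unknown op: " + op)
    with open(outfile, "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main(sys.argv)
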