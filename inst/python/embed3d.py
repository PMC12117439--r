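"""Deterministic single-conformer 3D embedding service.

Reads SMILES (one per line) on stdin, writes one JSON object per molecule:
{"ok": true, "elements": [...], "coords": [[x,y,z], ...],
 "bonds": [[a1,a2], ...]} with 1-based atom indices, heavy atoms first in
input order, hydrogens appended.  Embedding uses the ETKDG distance-geometry
method with a fixed random seed, followed by an MMFF (fallback UFF) cleanup,
so a given (SMILES, seed) pair always yields the same conformer.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def embed(smiles: str, seed: int):
    mol = Chem.MolFromSmiles(smiles, sanitize=True)
    if mol is None:
        return {"ok": False, "error": "parse failure"}
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    if AllChem.EmbedMolecule(mol, params) != 0:
        params.useRandomCoords = True
        if AllChem.EmbedMolecule(mol, params) != 0:
            return {"ok": False, "error": "embedding failure"}
    try:
        if AllChem.MMFFHasAllMoleculeParams(mol):
            AllChem.MMFFOptimizeMolecule(mol, maxIters=500)
        else:
            AllChem.UFFOptimizeMolecule(mol, maxIters=500)
    except Exception:
        pass  # raw ETKDG geometry is still usable
    conf = mol.GetConformer()
    coords = [[conf.GetAtomPosition(i).x, conf.GetAtomPosition(i).y,
               conf.GetAtomPosition(i).z] for i in range(mol.GetNumAtoms())]
    elements = [a.GetSymbol() for a in mol.GetAtoms()]
    bonds = [[b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1]
             for b in mol.GetBonds()]
    return {"ok": True, "elements": elements, "coords": coords, "bonds": bonds}


def main():
    seed = int(sys.argv[1]) if len(sys.argv) > 1 else 1
    for line in sys.stdin:
        smi = line.strip()
        if not smi:
            continue
        try:
            out = embed(smi, seed)
        except Exception as exc:  # noqa: BLE001 - reported per record
            out = {"ok": False, "error": str(exc)}
        sys.stdout.write(json.dumps(out) + "\n")


if __name__ == "__main__":
    main()
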