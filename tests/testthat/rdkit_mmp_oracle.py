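"""Independent single-cut MMP oracle built on RDKit.

Reads a TSV of (compound_id, smiles) on stdin, enumerates every
single-cut decomposition of each molecule (acyclic single bonds between
heavy atoms; core at least twice the substituent in heavy atoms;
substituent at most 13 heavy atoms), and prints every unordered compound
pair that shares a core (same canonical fragment with a marked
attachment site) with distinct substituents differing by at most 8
heavy atoms.
"""
import sys
from itertools import combinations

from rdkit import Chem
from rdkit.Chem import rdmolops

RATIO = 2.0
MAX_SUB = 13
MAX_DIFF = 8


def decompositions(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        raise ValueError(f"bad smiles: {smiles}")
    out = set()
    for bond in mol.GetBonds():
        if bond.IsInRing() or bond.GetBondType() != Chem.BondType.SINGLE:
            continue
        frag = Chem.FragmentOnBonds(mol, [bond.GetIdx()], addDummies=True)
        pieces = rdmolops.GetMolFrags(frag, asMols=True, sanitizeFrags=True)
        if len(pieces) != 2:
            continue
        sizes = [sum(1 for a in p.GetAtoms() if a.GetAtomicNum() > 1 and a.GetAtomicNum() != 0)
                 for p in pieces]
        for core_i, sub_i in ((0, 1), (1, 0)):
            ch, sh = sizes[core_i], sizes[sub_i]
            if sh < 1 or sh > MAX_SUB or ch < RATIO * sh:
                continue
            core = Chem.MolToSmiles(strip_dummy_labels(pieces[core_i]))
            sub = Chem.MolToSmiles(strip_dummy_labels(pieces[sub_i]))
            out.add((core, sub, sh))
    return out


def strip_dummy_labels(mol):
    m = Chem.Mol(mol)
    for atom in m.GetAtoms():
        if atom.GetAtomicNum() == 0:
            atom.SetIsotope(0)
    return m


def main():
    mols = {}
    for line in sys.stdin:
        line = line.rstrip("\n")
        if not line or line.startswith("compound_id"):
            continue
        cid, smi = line.split("\t")[:2]
        mols[cid] = decompositions(smi)
    for a, b in combinations(sorted(mols), 2):
        hit = False
        for core_a, sub_a, sh_a in mols[a]:
            for core_b, sub_b, sh_b in mols[b]:
                if core_a == core_b and sub_a != sub_b and abs(sh_a - sh_b) <= MAX_DIFF:
                    hit = True
                    break
            if hit:
                break
        if hit:
            print(f"{a}\t{b}")


if __name__ == "__main__":
    main()
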