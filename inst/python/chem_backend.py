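"""Batch chemistry worker for the molfrag R package.

Reads a JSON request from argv[1], writes a JSON response to argv[2].
All molecular perception (SMILES parsing, SMARTS matching, fragment
assembly, descriptors) happens here through RDKit; the fragmentation
algorithm itself lives on the R side.

Conventions: atom and bond indices are 0-based (RDKit order for the
parsed SMILES); stereochemistry is stripped on input so fragment
identity is constitution-level; dummy atoms are plain '*' (isotope 0).
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors

RDLogger.DisableLog("rdApp.*")

BOND_ORDER = {
    Chem.BondType.SINGLE: "S",
    Chem.BondType.DOUBLE: "D",
    Chem.BondType.TRIPLE: "T",
    Chem.BondType.AROMATIC: "A",
}


def aslist(x):
    if x is None:
        return []
    if isinstance(x, list):
        return x
    return [x]


def parse_mol(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None
    Chem.RemoveStereochemistry(mol)
    return mol


def mol_summary(mol):
    bonds = [
        {
            "index": b.GetIdx(),
            "a": b.GetBeginAtomIdx(),
            "b": b.GetEndAtomIdx(),
            "order": BOND_ORDER.get(b.GetBondType(), "?"),
            "ring": b.IsInRing(),
        }
        for b in mol.GetBonds()
    ]
    return {
        "ok": True,
        "canonical": Chem.MolToSmiles(mol),
        "heavy_atoms": sum(1 for a in mol.GetAtoms() if a.GetAtomicNum() > 1),
        "mol_weight": Descriptors.MolWt(mol),
        "n_components": len(Chem.GetMolFrags(mol)),
        "bonds": bonds,
    }


def op_analyze(req):
    """Parse molecules and match every SMARTS against every molecule.

    matches[i][j] is the list of [a, b] atom-index pairs where SMARTS j
    matched molecule i (first two atoms of the SMARTS, i.e. the two atoms
    of the candidate cleavable bond)."""
    patterns = []
    for p in aslist(req.get("smarts")):
        q = Chem.MolFromSmarts(p)
        patterns.append(q)
    mols, matches = [], []
    for smi in aslist(req.get("smiles")):
        mol = parse_mol(smi)
        if mol is None:
            mols.append({"ok": False, "error": "SMILES failed to parse"})
            matches.append([[] for _ in patterns])
            continue
        mols.append(mol_summary(mol))
        row = []
        for q in patterns:
            if q is None:
                row.append([])
                continue
            hits = mol.GetSubstructMatches(q, uniquify=True)
            row.append([[int(h[0]), int(h[1])] for h in hits if len(h) >= 2])
        matches.append(row)
    return {"mols": mols, "matches": matches}


def op_check_rules(req):
    out = []
    for p in aslist(req.get("smarts")):
        q = Chem.MolFromSmarts(p)
        if q is None:
            out.append({"ok": False, "error": "invalid SMARTS"})
            continue
        n_at, n_bd = q.GetNumAtoms(), q.GetNumBonds()
        if n_at != 2 or n_bd != 1:
            out.append(
                {
                    "ok": False,
                    "error": "pattern must match exactly two atoms joined by "
                    "one bond (got %d atoms, %d bonds)" % (n_at, n_bd),
                }
            )
        else:
            out.append({"ok": True, "n_atoms": n_at, "n_bonds": n_bd})
    return out


def fragment_info(mol, n_dummies):
    return {
        "ok": True,
        "smiles": Chem.MolToSmiles(mol),
        "heavy_atoms": sum(1 for a in mol.GetAtoms() if a.GetAtomicNum() > 1),
        "mol_weight": Descriptors.MolWt(mol),
        "n_dummies": n_dummies,
    }


def hydrogen_cap(frag):
    """Turn every dummy atom into an (implicit) hydrogen cap."""
    rw = Chem.RWMol(frag)
    for a in rw.GetAtoms():
        if a.GetAtomicNum() == 0:
            a.SetAtomicNum(1)
    return Chem.RemoveHs(rw.GetMol())


def op_assemble(req):
    """Excise connected atom subsets from parents, capping boundary cuts.

    Each job: parent (0-based index into parents), atoms (atom indices of
    the member base fragments), cuts (list of [a,b] boundary bond atom
    pairs), x (dummy-atom caps if true, hydrogen caps otherwise)."""
    parents = [parse_mol(s) for s in aslist(req.get("parents"))]
    out = []
    for job in aslist(req.get("jobs")):
        mol = parents[int(job["parent"])]
        if mol is None:
            out.append({"ok": False, "error": "parent failed to parse"})
            continue
        atoms = [int(a) for a in aslist(job.get("atoms"))]
        cuts = [c for c in aslist(job.get("cuts"))]
        use_x = bool(job.get("x", False))
        if not cuts:
            # no boundary: the fragment is the full parent
            out.append(fragment_info(mol, 0))
            continue
        bond_ids = []
        for pair in cuts:
            a, b = int(pair[0]), int(pair[1])
            bond = mol.GetBondBetweenAtoms(a, b)
            bond_ids.append(bond.GetIdx())
        broken = Chem.FragmentOnBonds(
            mol, bond_ids, addDummies=True, dummyLabels=[(0, 0)] * len(bond_ids)
        )
        comp_atoms = Chem.GetMolFrags(broken)
        comp_mols = Chem.GetMolFrags(broken, asMols=True, sanitizeFrags=True)
        seed = atoms[0]
        frag = None
        for idx_set, cmol in zip(comp_atoms, comp_mols):
            if seed in idx_set:
                frag = cmol
                break
        n_dummies = sum(1 for a in frag.GetAtoms() if a.GetAtomicNum() == 0)
        if not use_x:
            frag = hydrogen_cap(frag)
            n_dummies = 0
        out.append(fragment_info(frag, n_dummies))
    return out


def is_amide_cn(bond):
    for first, second in ((bond.GetBeginAtom(), bond.GetEndAtom()),
                          (bond.GetEndAtom(), bond.GetBeginAtom())):
        if first.GetAtomicNum() == 6 and second.GetAtomicNum() == 7:
            for nb in first.GetBonds():
                if (
                    nb.GetBondType() == Chem.BondType.DOUBLE
                    and nb.GetOtherAtom(first).GetAtomicNum() == 8
                ):
                    return True
    return False


def count_hbd(mol):
    return sum(
        1
        for a in mol.GetAtoms()
        if a.GetAtomicNum() in (7, 8) and a.GetTotalNumHs() > 0
    )


def count_hba(mol):
    """N/O acceptors: pyrrole-type aromatic N (three sigma bonds) and amide
    N are excluded; dummy atoms are not N/O so they never count."""
    n = 0
    for a in mol.GetAtoms():
        z = a.GetAtomicNum()
        if z == 8:
            n += 1
        elif z == 7:
            if a.GetIsAromatic() and a.GetTotalDegree() == 3:
                continue
            amide = any(
                nbr.GetAtomicNum() == 6
                and any(
                    b.GetBondType() == Chem.BondType.DOUBLE
                    and b.GetOtherAtom(nbr).GetAtomicNum() == 8
                    for b in nbr.GetBonds()
                )
                for nbr in a.GetNeighbors()
            )
            if not amide:
                n += 1
    return n


def heavy_degree(atom):
    """Connections to real heavy atoms (dummies and hydrogens excluded)."""
    return sum(1 for nb in atom.GetNeighbors() if nb.GetAtomicNum() > 1)


def count_rotb_nt(mol):
    """Acyclic single bonds between two non-terminal real heavy atoms;
    amide C-N and any bond touching a dummy atom are excluded."""
    n = 0
    for bond in mol.GetBonds():
        if bond.IsInRing() or bond.GetBondType() != Chem.BondType.SINGLE:
            continue
        a, b = bond.GetBeginAtom(), bond.GetEndAtom()
        if a.GetAtomicNum() <= 1 or b.GetAtomicNum() <= 1:
            continue
        if heavy_degree(a) < 2 or heavy_degree(b) < 2:
            continue
        if is_amide_cn(bond):
            continue
        n += 1
    return n


def op_props(req):
    out = []
    for smi in aslist(req.get("smiles")):
        mol = parse_mol(smi)
        if mol is None:
            out.append({"ok": False, "error": "SMILES failed to parse"})
            continue
        out.append(
            {
                "ok": True,
                "mol_weight": Descriptors.MolWt(mol),
                "xlogp": Crippen.MolLogP(mol),
                "hbd": count_hbd(mol),
                "hba": count_hba(mol),
                "rotb_nt": count_rotb_nt(mol),
            }
        )
    return out


def op_canonical(req):
    out = []
    for smi in aslist(req.get("smiles")):
        mol = parse_mol(smi)
        if mol is None:
            out.append({"ok": False, "error": "SMILES failed to parse"})
        else:
            out.append(
                {
                    "ok": True,
                    "canonical": Chem.MolToSmiles(mol),
                    "n_components": len(Chem.GetMolFrags(mol)),
                }
            )
    return out


def strip_dummies(mol):
    rw = Chem.RWMol(mol)
    for idx in sorted(
        (a.GetIdx() for a in rw.GetAtoms() if a.GetAtomicNum() == 0),
        reverse=True,
    ):
        rw.RemoveAtom(idx)
    out = rw.GetMol()
    Chem.SanitizeMol(out)
    return out


def op_substructure(req):
    """Is each fragment (dummies removed) a substructure of its parent?"""
    out = []
    for pair in aslist(req.get("pairs")):
        parent = parse_mol(pair["parent"])
        frag = parse_mol(pair["frag"])
        if parent is None or frag is None:
            out.append({"ok": False, "error": "SMILES failed to parse"})
            continue
        query = strip_dummies(frag)
        out.append({"ok": True, "is_sub": parent.HasSubstructMatch(query)})
    return out


OPS = {
    "analyze": op_analyze,
    "check_rules": op_check_rules,
    "assemble": op_assemble,
    "props": op_props,
    "canonical": op_canonical,
    "substructure": op_substructure,
}


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    handler = OPS.get(req.get("op"))
    if handler is None:
        raise SystemExit("unknown op: %r" % req.get("op"))
    resp = handler(req)
    with open(sys.argv[2], "w") as fh:
        json.dump(resp, fh)


if __name__ == "__main__":
    main()
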