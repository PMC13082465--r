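"""Cheminformatics helper: small JSON-in/JSON-out operations on SMILES.

Invoked as: python rdkit_ops.py <op> <in.json> <out.json>
All randomness is driven by an explicit seed in the payload.
"""
import json
import random
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import BRICS, Crippen, Descriptors, Lipinski, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def mol_or_none(smi):
    return Chem.MolFromSmiles(smi)


def op_canonical(payload):
    out = []
    for smi in payload["smiles"]:
        m = mol_or_none(smi)
        out.append(Chem.MolToSmiles(m) if m is not None else None)
    return {"canonical": out}


def op_descriptors(payload):
    keys = ["logp", "mass", "no_count", "nhoh_count", "tpsa",
            "rotatable_bonds", "aromatic_carbocycles",
            "aromatic_heterocycles", "aromatic_rings", "fraction_csp3"]
    cols = {k: [] for k in keys}
    for smi in payload["smiles"]:
        m = mol_or_none(smi)
        if m is None:
            for k in keys:
                cols[k].append(None)
            continue
        cols["logp"].append(Crippen.MolLogP(m))
        cols["mass"].append(Descriptors.MolWt(m))
        cols["no_count"].append(Lipinski.NOCount(m))
        cols["nhoh_count"].append(Lipinski.NHOHCount(m))
        cols["tpsa"].append(rdMolDescriptors.CalcTPSA(m))
        cols["rotatable_bonds"].append(Lipinski.NumRotatableBonds(m))
        cols["aromatic_carbocycles"].append(Lipinski.NumAromaticCarbocycles(m))
        cols["aromatic_heterocycles"].append(Lipinski.NumAromaticHeterocycles(m))
        cols["aromatic_rings"].append(Lipinski.NumAromaticRings(m))
        cols["fraction_csp3"].append(Lipinski.FractionCSP3(m))
    return cols


def morgan_environments(mol, max_radius, min_atoms):
    frags = set()
    for atom in mol.GetAtoms():
        for r in range(1, max_radius + 1):
            env = Chem.FindAtomEnvironmentOfRadiusN(mol, r, atom.GetIdx())
            if not env:
                continue
            amap = {}
            sub = Chem.PathToSubmol(mol, env, atomMap=amap)
            if sub.GetNumAtoms() >= min_atoms:
                smi = Chem.MolToSmiles(sub)
                if smi:
                    frags.add(smi)
    return sorted(frags)


def op_morgan_fragments(payload):
    out = []
    for smi in payload["smiles"]:
        m = mol_or_none(smi)
        if m is None:
            out.append(None)
        else:
            out.append(morgan_environments(m, int(payload.get("max_radius", 5)),
                                           int(payload.get("min_atoms", 3))))
    return {"fragments": out}


def query_mol(frag):
    q = Chem.MolFromSmiles(frag)
    if q is None:
        q = Chem.MolFromSmarts(frag)
    return q


def op_substruct_matrix(payload):
    mols = [mol_or_none(s) for s in payload["smiles"]]
    matrix = []
    for frag in payload["fragments"]:
        q = query_mol(frag)
        if q is None:
            matrix.append([False] * len(mols))
            continue
        matrix.append([bool(m is not None and m.HasSubstructMatch(q))
                       for m in mols])
    return {"matrix": matrix}


def op_brics_decompose(payload):
    out = []
    for smi in payload["smiles"]:
        m = mol_or_none(smi)
        if m is None:
            out.append(None)
        else:
            out.append(sorted(BRICS.BRICSDecompose(m)))
    return {"fragments": out}


def cap_dummies(mol):
    """Replace remaining BRICS attachment points with hydrogens."""
    em = Chem.RWMol(mol)
    for atom in em.GetAtoms():
        if atom.GetAtomicNum() == 0:
            atom.SetAtomicNum(1)
            atom.SetIsotope(0)
            atom.SetNoImplicit(False)
    m = em.GetMol()
    try:
        Chem.SanitizeMol(m)
        m = Chem.RemoveHs(m)
        return Chem.MolToSmiles(m)
    except Exception:
        return None


def join_pairs(left, right, cap, rng, limit):
    """All BRICS-compatible joins of one mol from `left` with one from
    `right`; intermediate sets beyond `cap` are down-sampled with `rng`."""
    seen = set()
    prods = []
    for m1 in left:
        for m2 in right:
            for rxn in BRICS.reverseReactions:
                for pair in ((m1, m2), (m2, m1)):
                    for ps in rxn.RunReactants(pair):
                        p = ps[0]
                        try:
                            Chem.SanitizeMol(p)
                        except Exception:
                            continue
                        smi = Chem.MolToSmiles(p)
                        if smi not in seen:
                            seen.add(smi)
                            prods.append(p)
    if len(prods) > cap:
        order = sorted(range(len(prods)),
                       key=lambda i: Chem.MolToSmiles(prods[i]))
        pick = rng.sample(order, cap)
        prods = [prods[i] for i in sorted(pick)]
    return prods


def op_brics_recombine(payload):
    k = int(payload.get("k", 3))
    limit = int(payload.get("limit", 100000))
    rng = random.Random(int(payload.get("seed", 0)))
    frags = []
    for smi in sorted(set(payload["fragments"])):
        m = mol_or_none(smi)
        if m is not None and any(a.GetAtomicNum() == 0 for a in m.GetAtoms()):
            frags.append(m)
    if not frags or k < 2:
        return {"products": [], "note": "no usable fragments"}
    level = frags
    for _ in range(k - 1):
        level = join_pairs(level, frags, cap=max(limit, 1), rng=rng, limit=limit)
        if not level:
            return {"products": []}
    out = set()
    for m in level:
        smi = cap_dummies(m)
        if smi:
            out.add(smi)
    out = sorted(out)
    if len(out) > limit:
        out = sorted(rng.sample(out, limit))
    return {"products": out}


OPS = {
    "canonical": op_canonical,
    "descriptors": op_descriptors,
    "morgan_fragments": op_morgan_fragments,
    "substruct_matrix": op_substruct_matrix,
    "brics_decompose": op_brics_decompose,
    "brics_recombine": op_brics_recombine,
}


def main():
    op, fin, fout = sys.argv[1], sys.argv[2], sys.argv[3]
    with open(fin) as fh:
        payload = json.load(fh)
    result = OPS[op](payload)
    with open(fout, "w") as fh:
        json.dump(result, fh)


if __name__ == "__main__":
    main()
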