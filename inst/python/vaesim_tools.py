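"""Command-line bridge to RDKit and umap-learn used by the vaesim R package.

All communication is line-oriented over stdin/stdout so that a single process
spawn handles an arbitrarily large batch.  Subcommands:

  canon             stdin: one SMILES per line
                    stdout: canonical SMILES, or an empty line if unparsable
  fp --method M [--radius R] [--nbits N]
                    stdin: one SMILES per line
                    stdout: per line "L:i1,i2,..." where L is the bit-vector
                    length and i* the 0-based indices of set bits; "!" for an
                    unparsable SMILES
  umap --seed S [--n-neighbors K] [--min-dist D]
                    stdin: CSV matrix (no header), one row per observation
                    stdout: CSV with two columns, the 2-d embedding
  version           stdout: rdkit version string
"""

import sys


def _read_lines():
    return [ln.rstrip("\n") for ln in sys.stdin]


def _rdkit():
    from rdkit import Chem, RDLogger
    RDLogger.DisableLog("rdApp.*")
    return Chem


def cmd_canon(_args):
    Chem = _rdkit()
    out = []
    for smi in _read_lines():
        mol = Chem.MolFromSmiles(smi) if smi else None
        out.append(Chem.MolToSmiles(mol) if mol is not None else "")
    sys.stdout.write("\n".join(out) + "\n")


FP_METHODS = (
    "atompair", "avalon", "featmorgan", "layered", "maccs",
    "morgan", "pattern", "rdkit", "torsion",
)


def _fingerprint(mol, method, radius, nbits):
    from rdkit.Chem import AllChem, MACCSkeys, rdMolDescriptors
    from rdkit import Chem
    if method == "maccs":
        return MACCSkeys.GenMACCSKeys(mol)
    if method == "morgan":
        return AllChem.GetMorganFingerprintAsBitVect(mol, radius, nBits=nbits)
    if method == "featmorgan":
        return AllChem.GetMorganFingerprintAsBitVect(
            mol, radius, nBits=nbits, useFeatures=True)
    if method == "atompair":
        return rdMolDescriptors.GetHashedAtomPairFingerprintAsBitVect(
            mol, nBits=nbits)
    if method == "torsion":
        return rdMolDescriptors.GetHashedTopologicalTorsionFingerprintAsBitVect(
            mol, nBits=nbits)
    if method == "rdkit":
        return Chem.RDKFingerprint(mol)
    if method == "layered":
        return Chem.LayeredFingerprint(mol)
    if method == "pattern":
        return Chem.PatternFingerprint(mol)
    if method == "avalon":
        from rdkit.Avalon import pyAvalonTools
        return pyAvalonTools.GetAvalonFP(mol)
    raise SystemExit("unknown fingerprint method: %s" % method)


def cmd_fp(args):
    Chem = _rdkit()
    method = args["--method"]
    radius = int(args.get("--radius", 2))
    nbits = int(args.get("--nbits", 1024))
    out = []
    for smi in _read_lines():
        mol = Chem.MolFromSmiles(smi) if smi else None
        if mol is None:
            out.append("!")
            continue
        bv = _fingerprint(mol, method, radius, nbits)
        out.append("%d:%s" % (bv.GetNumBits(),
                              ",".join(str(i) for i in bv.GetOnBits())))
    sys.stdout.write("\n".join(out) + "\n")


def cmd_umap(args):
    import numpy as np
    import warnings
    X = np.loadtxt(sys.stdin, delimiter=",", ndmin=2)
    seed = int(args["--seed"])
    n_neighbors = int(args.get("--n-neighbors", 15))
    min_dist = float(args.get("--min-dist", 0.1))
    with warnings.catch_warnings():
        warnings.simplefilter("ignore")
        import umap
        emb = umap.UMAP(n_components=2, n_neighbors=n_neighbors,
                        min_dist=min_dist, random_state=seed).fit_transform(X)
    np.savetxt(sys.stdout, emb, delimiter=",", fmt="%.10g")


def cmd_version(_args):
    import rdkit
    sys.stdout.write(rdkit.__version__ + "\n")


def main(argv):
    if not argv:
        raise SystemExit(__doc__)
    cmd, rest = argv[0], argv[1:]
    args = dict(zip(rest[::2], rest[1::2]))
    fn = {"canon": cmd_canon, "fp": cmd_fp,
          "umap": cmd_umap, "version": cmd_version}.get(cmd)
    if fn is None:
        raise SystemExit("unknown subcommand: %s" % cmd)
    fn(args)


if __name__ == "__main__":
    main(sys.argv[1:])
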