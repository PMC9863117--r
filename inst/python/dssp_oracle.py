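"""Independent secondary-structure oracle for the test suite.

Reads a multi-model PDB trajectory, runs mdtraj's Kabsch-Sander (DSSP)
implementation, and writes one line per frame of per-residue labels
(mdtraj's blank 'loop' code is rewritten to '-').

Usage: python dssp_oracle.py input.pdb output.txt
"""
import sys

import mdtraj as md


def main(pdb_path, out_path):
    traj = md.load(pdb_path)
    labels = md.compute_dssp(traj, simplified=False)
    with open(out_path, "w") as fh:
        for row in labels:
            fh.write("".join("-" if c in (" ", "") else c for c in row))
            fh.write("\n")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
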