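"""Independent solvent-accessible surface-area oracle for the test suite.

Reads atom coordinates and van der Waals radii from a CSV (columns
x, y, z, radius), computes total SASA with biotite's Shrake-Rupley
implementation using exactly those radii, and prints the total area.

Usage: python sasa_oracle.py atoms.csv [probe_radius] [n_points]
"""
import sys

import numpy as np
import biotite.structure as struc


def main(csv_path, probe=1.4, n_points=1000):
    data = np.loadtxt(csv_path, delimiter=",", skiprows=1)
    arr = struc.AtomArray(len(data))
    arr.coord = data[:, :3].astype(np.float32)
    arr.element = np.array(["C"] * len(data))
    areas = struc.sasa(arr, probe_radius=probe, point_number=int(n_points),
                       vdw_radii=data[:, 3])
    print(repr(float(np.sum(areas))))


if __name__ == "__main__":
    probe = float(sys.argv[2]) if len(sys.argv) > 2 else 1.4
    npts = int(sys.argv[3]) if len(sys.argv) > 3 else 1000
    main(sys.argv[1], probe, npts)
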