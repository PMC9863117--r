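# Internal-coordinate templates for peptide construction (heavy atoms + polar
# hydrogens only). Each atom is placed by the natural-extension-reference-frame
# rule from three previously placed reference atoms:
#   position = NeRF(ref1, ref2, ref3; bond, angle, torsion)
# where `bond` is the ref3-atom distance in Angstrom, `angle` the
# ref2-ref3-atom angle in degrees, and the torsion is the ref1-ref2-ref3-atom
# dihedral in degrees, evaluated as value(torsion_type) + offset.
# torsion_type: fixed | phi | psi | psi_prev | chi1 | chi2 | chi3
#   (phi/psi are the residue's backbone dihedrals, psi_prev the preceding
#    residue's psi; chi values come from the caller or chi_defaults.tsv).
# A reference name prefixed with "-" lives on the preceding residue.
# Rows with residue "*" are backbone atoms common to every residue type; the
# first residue's N/CA/C seed the chain and its ammonium hydrogens (H1-H3),
# the backbone amide hydrogen, and the C-terminal carboxylate (O at 1.25 A
# plus OXT) are handled by the builder itself.
# Backbone lengths/angles follow standard protein-geometry values; side-chain
# geometry follows ideal residue templates (CB improper N-C-CA-CB = +120 deg
# for L-amino acids). Carboxylates of D, E and the C-terminus are deprotonated:
# both oxygens at 1.25 A, no hydrogen.
residue	atom	element	ref1	ref2	ref3	bond	angle	torsion_type	offset
*	N	N	-N	-CA	-C	1.329	116.2	psi_prev	0
*	CA	C	-CA	-C	N	1.458	121.7	fixed	180
*	C	C	-C	N	CA	1.525	111.2	phi	0
*	O	O	N	CA	C	1.231	120.8	psi	180
ALA	CB	C	N	C	CA	1.530	110.5	fixed	120
VAL	CB	C	N	C	CA	1.530	110.5	fixed	120
VAL	CG1	C	N	CA	CB	1.530	110.5	chi1	0
VAL	CG2	C	N	CA	CB	1.530	110.5	chi1	120
LEU	CB	C	N	C	CA	1.530	110.5	fixed	120
LEU	CG	C	N	CA	CB	1.530	116.3	chi1	0
LEU	CD1	C	CA	CB	CG	1.530	110.7	chi2	0
LEU	CD2	C	CA	CB	CG	1.530	110.7	chi2	120
ASP	CB	C	N	C	CA	1.530	110.5	fixed	120
ASP	CG	C	N	CA	CB	1.520	112.6	chi1	0
ASP	OD1	O	CA	CB	CG	1.250	118.4	chi2	0
ASP	OD2	O	CA	CB	CG	1.250	118.4	chi2	180
GLU	CB	C	N	C	CA	1.530	110.5	fixed	120
GLU	CG	C	N	CA	CB	1.520	114.1	chi1	0
GLU	CD	C	CA	CB	CG	1.520	112.6	chi2	0
GLU	OE1	O	CB	CG	CD	1.250	118.4	chi3	0
GLU	OE2	O	CB	CG	CD	1.250	118.4	chi3	180
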