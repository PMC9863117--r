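# Default side-chain torsions (degrees) used when the caller supplies none.
# Common rotamer-library states chosen so that default fixtures are clash-free
# in both helical and extended backbones.
residue	chi1	chi2	chi3
GLY	NA	NA	NA
ALA	NA	NA	NA
VAL	180	NA	NA
LEU	180	60	NA
ASP	180	-30	NA
GLU	180	180	-30
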