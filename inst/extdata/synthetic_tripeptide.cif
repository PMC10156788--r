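data_synthetic_tripeptide
#
loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.label_entity_id
_atom_site.label_seq_id
_atom_site.pdbx_PDB_ins_code
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.B_iso_or_equiv
_atom_site.pdbx_formal_charge
_atom_site.auth_seq_id
_atom_site.auth_comp_id
_atom_site.auth_asym_id
_atom_site.auth_atom_id
_atom_site.pdbx_PDB_model_num
ATOM 1  N N  . ALA A 1 1 ? 11.104 6.134 -6.504 1.00 10.00 ? 1 ALA A N  1
ATOM 2  C CA . ALA A 1 1 ? 12.560 6.351 -6.510 1.00 10.00 ? 1 ALA A CA 1
ATOM 3  C C  . ALA A 1 1 ? 13.250 5.266 -5.690 1.00 10.00 ? 1 ALA A C  1
ATOM 4  O O  . ALA A 1 1 ? 12.631 4.568 -4.880 1.00 10.00 ? 1 ALA A O  1
ATOM 5  N N  . GLY A 1 2 ? 14.570 5.120 -5.860 1.00 11.00 ? 2 GLY A N  1
ATOM 6  C CA . GLY A 1 2 ? 15.340 4.100 -5.140 1.00 11.00 ? 2 GLY A CA 1
ATOM 7  C C  . GLY A 1 2 ? 16.120 4.720 -3.980 1.00 11.00 ? 2 GLY A C  1
ATOM 8  O O  . GLY A 1 2 ? 16.110 5.950 -3.800 1.00 11.00 ? 2 GLY A O  1
ATOM 9  N N  . SER B 2 1 ? 16.800 3.880 -3.190 1.00 12.00 ? 1 SER B N  1
ATOM 10 C CA . SER B 2 1 ? 17.600 4.320 -2.040 1.00 12.00 ? 1 SER B CA 1
ATOM 11 C CB . SER B 2 1 ? 16.720 4.640 -0.830 1.00 12.00 ? 1 SER B CB 1
ATOM 12 O OG . SER B 2 1 ? 15.960 3.500 -0.440 1.00 12.00 ? 1 SER B OG 1
#
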