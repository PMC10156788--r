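REMARK synthetic three-residue fixture for parser tests
ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N
ATOM      2  CA  ALA A   1      12.560   6.351  -6.510  1.00 10.00           C
ATOM      3  C   ALA A   1      13.250   5.266  -5.690  1.00 10.00           C
ATOM      4  O   ALA A   1      12.631   4.568  -4.880  1.00 10.00           O
ATOM      5  N   GLY A   2      14.570   5.120  -5.860  1.00 11.00           N
ATOM      6  CA  GLY A   2      15.340   4.100  -5.140  1.00 11.00           C
ATOM      7  C   GLY A   2      16.120   4.720  -3.980  1.00 11.00           C
ATOM      8  O   GLY A   2      16.110   5.950  -3.800  1.00 11.00           O
ATOM      9  N   SER B   1      16.800   3.880  -3.190  1.00 12.00           N
ATOM     10  CA  SER B   1      17.600   4.320  -2.040  1.00 12.00           C
ATOM     11  CB  SER B   1      16.720   4.640  -0.830  1.00 12.00           C
ATOM     12  OG  SER B   1      15.960   3.500  -0.440  1.00 12.00           O
END
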