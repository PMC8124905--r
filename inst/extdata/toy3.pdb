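ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C
ATOM      4  CA  GLY A   2       4.100   2.300   0.500  1.00  0.00           C
ATOM      5  CA  SER A   3       6.800   4.100   1.200  1.00  0.00           C
END
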