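toluene
     RDKit          3D

  7  7  0  0  0  0  0  0  0  0999 V2000
   -2.2198   -0.0813   -0.0076 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7212   -0.0266    0.0223 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0323   -1.2067   -0.0018 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4273   -1.1549   -0.0057 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.0803    0.0762    0.0039 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.3390    1.2562    0.0130 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0561    1.2057    0.0170 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  3  4  1  0
  4  5  2  0
  5  6  1  0
  6  7  2  0
  7  2  1  0
M  END
$$$$
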