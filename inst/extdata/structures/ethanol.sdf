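ethanol
     RDKit          3D

  3  2  0  0  0  0  0  0  0  0999 V2000
   -0.8632    0.2204    0.2027 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4063   -0.3750   -0.3700 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.5274    0.4036    0.0222 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
M  END
$$$$
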