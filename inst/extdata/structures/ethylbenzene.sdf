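ethylbenzene
     RDKit          3D

  8  8  0  0  0  0  0  0  0  0999 V2000
   -2.4199   -0.4997   -0.6103 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6543    0.1021    0.5580 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1699    0.1329    0.2991 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6371   -0.9550    0.6579 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.0093   -0.9324    0.4033 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5864    0.1747   -0.2160 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7918    1.2591   -0.5830 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4194    1.2382   -0.3291 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
  6  7  1  0
  7  8  2  0
  8  3  1  0
M  END
$$$$
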