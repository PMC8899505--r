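pyrrole
     RDKit          3D

  5  5  0  0  0  0  0  0  0  0999 V2000
    0.2807    1.1616   -0.0079 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1924    0.0789    0.0017 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4513   -1.0817    0.0087 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8752   -0.7370    0.0037 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9891    0.6288   -0.0064 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  3  4  1  0
  4  5  1  0
  5  1  2  0
M  END
$$$$
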