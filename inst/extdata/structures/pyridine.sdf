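pyridine
     RDKit          3D

  6  6  0  0  0  0  0  0  0  0999 V2000
   -0.3581    1.1278    0.0372 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2897    0.0952    0.0117 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8223   -1.2086   -0.0316 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4880   -1.5369   -0.0507 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.3689   -0.5131   -0.0252 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9986    0.8216    0.0185 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
  6  1  1  0
M  END
$$$$
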