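stereo_R
     RDKit          3D

  5  4  0  0  0  0  0  0  0  0999 V2000
   -0.0576   -0.1051   -0.0841 C   0  0  1  0  0  0  0  0  0  0  0  0
   -0.3388   -1.2118    0.6487 F   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2451    1.1540    0.2505 Cl  0  0  0  0  0  0  0  0  0  0  0  0
    1.7251    0.5278    0.3302 Br  0  0  0  0  0  0  0  0  0  0  0  0
   -0.0837   -0.3650   -1.1452 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  1  3  1  0
  1  4  1  0
  1  5  1  6
M  END
$$$$
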