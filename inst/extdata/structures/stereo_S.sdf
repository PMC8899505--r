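stereo_S
     RDKit          3D

  5  4  0  0  0  0  0  0  0  0999 V2000
   -0.0570   -0.1138    0.0724 C   0  0  2  0  0  0  0  0  0  0  0  0
   -0.3057   -1.1476   -0.7704 F   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2618    1.1521   -0.1590 Cl  0  0  0  0  0  0  0  0  0  0  0  0
    1.7204    0.5864   -0.2452 Br  0  0  0  0  0  0  0  0  0  0  0  0
   -0.0960   -0.4771    1.1022 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  1  3  1  0
  1  4  1  0
  1  5  1  1
M  END
$$$$
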