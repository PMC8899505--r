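cyclohexane
     RDKit          3D

  6  6  0  0  0  0  0  0  0  0999 V2000
   -0.7331    1.1007   -0.6541 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6871    1.2990   -0.1312 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4705   -0.0109   -0.1193 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7331   -1.1007    0.6541 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6871   -1.2990    0.1312 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4705    0.0109    0.1193 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  6  1  1  0
M  END
$$$$
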