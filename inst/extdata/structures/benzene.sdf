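benzene
     RDKit          3D

  6  6  0  0  0  0  0  0  0  0999 V2000
    1.0734    0.8905   -0.0210 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.3080   -0.4844   -0.0077 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2346   -1.3749    0.0133 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0734   -0.8905    0.0210 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3080    0.4844    0.0077 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2346    1.3749   -0.0133 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
  6  1  1  0
M  END
$$$$
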