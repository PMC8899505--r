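aniline
     RDKit          3D

  7  7  0  0  0  0  0  0  0  0999 V2000
    2.2620   -0.3796    0.3593 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.9109   -0.1311    0.0882 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3228    1.0729    0.4846 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0492    1.2841    0.3244 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8535    0.2732   -0.1964 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2876   -0.9527   -0.5380 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0850   -1.1584   -0.3756 C   0  0  0  0  0  0  0  0  0  0  0  0
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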