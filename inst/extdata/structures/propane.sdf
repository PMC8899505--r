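propane
     RDKit          3D

  3  2  0  0  0  0  0  0  0  0999 V2000
    1.1646    0.4787   -0.2221 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1269   -0.6063    0.0105 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2604   -0.0212    0.2141 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
M  END
$$$$
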