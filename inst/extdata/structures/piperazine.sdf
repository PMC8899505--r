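piperazine
     RDKit          3D

  6  6  0  0  0  0  0  0  0  0999 V2000
    1.4253    0.0751    0.0742 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6586   -1.2648    0.0959 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6347   -1.1986   -0.6072 N   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4253   -0.0751   -0.0742 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6586    1.2648   -0.0959 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6347    1.1986    0.6072 N   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  6  1  1  0
M  END
$$$$
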