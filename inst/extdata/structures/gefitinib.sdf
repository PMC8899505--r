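gefitinib
     RDKit          3D

 31 34  0  0  0  0  0  0  0  0999 V2000
    0.0498   -5.4707   -1.9149 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3377   -4.1905   -1.3699 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7184   -3.3501   -1.1203 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0518   -3.6397   -1.4310 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0823   -2.7496   -1.1571 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.3265   -3.0983   -1.4945 N   0  0  0  0  0  0  0  0  0  0  0  0
   -5.2944   -2.2174   -1.2234 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.1356   -1.0295   -0.6355 N   0  0  0  0  0  0  0  0  0  0  0  0
   -3.8830   -0.6896   -0.2835 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.6626    0.5428    0.3935 N   0  0  0  0  0  0  0  0  0  0  0  0
   -4.5437    1.6417    0.5132 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.4819    1.9670   -0.4776 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.2906    3.1018   -0.3631 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.1481    3.9389    0.7356 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.9301    5.0242    0.8280 F   0  0  0  0  0  0  0  0  0  0  0  0
   -5.1988    3.6583    1.7124 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.9952    4.7033    3.0664 Cl  0  0  0  0  0  0  0  0  0  0  0  0
   -4.3916    2.5228    1.5964 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7795   -1.5297   -0.5414 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4284   -1.2200   -0.2371 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4010   -2.1197   -0.5250 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9247   -1.8999   -0.2556 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.3176   -0.5977    0.1732 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.8398   -0.5833    0.2948 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.3469    0.7978    0.7196 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.7951    0.8258    0.9675 N   0  0  0  0  0  0  0  0  0  0  0  0
    5.2330    2.1208    1.5350 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.8541    3.0664    0.4952 C   0  0  0  0  0  0  0  0  0  0  0  0
    7.0075    2.5150   -0.1542 O   0  0  0  0  0  0  0  0  0  0  0  0
    7.0011    1.0810   -0.1881 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.5804    0.4991   -0.2450 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
  6  7  1  0
  7  8  2  0
  8  9  1  0
  9 10  1  0
 10 11  1  0
 11 12  2  0
 12 13  1  0
 13 14  2  0
 14 15  1  0
 14 16  1  0
 16 17  1  0
 16 18  2  0
  9 19  2  0
 19 20  1  0
 20 21  2  0
 21 22  1  0
 22 23  1  0
 23 24  1  0
 24 25  1  0
 25 26  1  0
 26 27  1  0
 27 28  1  0
 28 29  1  0
 29 30  1  0
 30 31  1  0
 21  3  1  0
 31 26  1  0
 19  5  1  0
 18 11  1  0
M  END
$$$$
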