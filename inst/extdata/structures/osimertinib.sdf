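osimertinib
     RDKit          3D

 37 40  0  0  0  0  0  0  0  0999 V2000
    0.1279   -3.7580    0.7287 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3738   -2.5385    0.1995 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.5487   -1.5972   -0.2064 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.9344   -1.7854   -0.1887 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.7938   -0.7618   -0.6112 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.2192   -0.9008   -0.6038 N   0  0  0  0  0  0  0  0  0  0  0  0
    4.6360   -1.7371   -1.7420 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.7398   -1.3500    0.7119 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.1553   -0.7712    0.9551 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.7988   -1.2253    2.2076 N   0  0  0  0  0  0  0  0  0  0  0  0
    6.0962   -0.7215    3.3911 C   0  0  0  0  0  0  0  0  0  0  0  0
    8.1946   -0.7764    2.2374 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.2419    0.4542   -1.0764 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.1830    1.4331   -1.4616 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.9603    2.6625   -2.0235 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.8934    3.1338   -2.3998 O   0  0  0  0  0  0  0  0  0  0  0  0
    4.1973    3.4672   -2.2435 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.3124    3.4012   -1.5013 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8573    0.6373   -1.0982 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0079   -0.3743   -0.6567 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4092   -0.2421   -0.6257 N   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2966    0.8060   -0.8329 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8790    2.0038   -1.2550 N   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8008    2.9648   -1.4139 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.1346    2.7792   -1.1621 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.4931    1.5209   -0.7290 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.8826    1.1763   -0.4052 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.9630    2.0137   -0.6341 C   0  0  0  0  0  0  0  0  0  0  0  0
   -8.1028    1.3863   -0.2063 N   0  0  0  0  0  0  0  0  0  0  0  0
   -9.4304    1.9571   -0.2759 C   0  0  0  0  0  0  0  0  0  0  0  0
   -7.8070    0.1396    0.2959 C   0  0  0  0  0  0  0  0  0  0  0  0
   -8.6420   -0.8552    0.8342 C   0  0  0  0  0  0  0  0  0  0  0  0
   -8.0547   -2.0443    1.2757 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.6812   -2.2354    1.1843 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.8605   -1.2379    0.6456 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.4205   -0.0227    0.1864 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.5839    0.5344   -0.5667 N   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  1  0
  6  7  1  0
  6  8  1  0
  8  9  1  0
  9 10  1  0
 10 11  1  0
 10 12  1  0
  5 13  2  0
 13 14  1  0
 14 15  1  0
 15 16  2  0
 15 17  1  0
 17 18  2  0
 13 19  1  0
 19 20  2  0
 20 21  1  0
 21 22  1  0
 22 23  2  0
 23 24  1  0
 24 25  2  0
 25 26  1  0
 26 27  1  0
 27 28  2  0
 28 29  1  0
 29 30  1  0
 29 31  1  0
 31 32  2  0
 32 33  1  0
 33 34  2  0
 34 35  1  0
 35 36  2  0
 26 37  2  0
 20  3  1  0
 37 22  1  0
 36 27  1  0
 36 31  1  0
M  END
$$$$
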