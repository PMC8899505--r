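afatinib
     RDKit          3D

 34 37  0  0  0  0  0  0  0  0999 V2000
    5.4258   -3.8303    0.3377 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.3912   -2.8394   -0.7449 N   0  0  0  0  0  0  0  0  0  0  0  0
    6.6402   -2.9127   -1.5070 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.1881   -1.4855   -0.2181 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.7583   -1.1247    0.0962 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.6653   -1.8500   -0.2093 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2729   -1.4442    0.1205 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4744   -2.3014    0.4791 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.0273   -0.1058   -0.0757 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1922    0.5912    0.0682 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3968   -0.0225    0.4039 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5921    0.7304    0.5228 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.8551    0.1979    0.8476 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.9529    0.9713    0.9170 N   0  0  0  0  0  0  0  0  0  0  0  0
   -4.7934    2.2745    0.6800 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.6449    2.8841    0.3771 N   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5596    2.1113    0.2946 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3527    2.7120   -0.0404 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1719    1.9752   -0.1680 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0545    2.4938   -0.5040 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.1159    3.8162   -1.0187 C   0  0  2  0  0  0  0  0  0  0  0  0
    2.3801    3.9920   -1.8367 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5360    5.4967   -1.8413 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.0201    5.9691   -0.5868 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.3434    4.8718    0.0533 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.9707   -1.1951    1.1022 N   0  0  0  0  0  0  0  0  0  0  0  0
   -5.1373   -1.9820    1.1682 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.1111   -3.1687    1.9188 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.2221   -4.0184    1.9594 C   0  0  0  0  0  0  0  0  0  0  0  0
   -7.3602   -3.6997    1.2245 C   0  0  0  0  0  0  0  0  0  0  0  0
   -8.4090   -4.5391    1.2563 F   0  0  0  0  0  0  0  0  0  0  0  0
   -7.3993   -2.5441    0.4543 C   0  0  0  0  0  0  0  0  0  0  0  0
   -8.7938   -2.1633   -0.4883 Cl  0  0  0  0  0  0  0  0  0  0  0  0
   -6.2892   -1.6920    0.4212 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  2  4  1  0
  4  5  1  0
  5  6  2  0
  6  7  1  0
  7  8  2  0
  7  9  1  0
  9 10  1  0
 10 11  2  0
 11 12  1  0
 12 13  2  0
 13 14  1  0
 14 15  2  0
 15 16  1  0
 16 17  2  0
 17 18  1  0
 18 19  2  0
 19 20  1  0
 21 20  1  1
 21 22  1  0
 22 23  1  0
 23 24  1  0
 24 25  1  0
 13 26  1  0
 26 27  1  0
 27 28  2  0
 28 29  1  0
 29 30  2  0
 30 31  1  0
 30 32  1  0
 32 33  1  0
 32 34  2  0
 19 10  1  0
 25 21  1  0
 34 27  1  0
 17 12  1  0
M  END
$$$$
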