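dasatinib
     RDKit          3D

 33 36  0  0  0  0  0  0  0  0999 V2000
    1.7137   -3.1876    0.5721 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7730   -1.9257   -0.2294 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7000   -1.1233   -0.2060 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.7575   -0.0010   -0.9312 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3382    0.8897   -1.0004 N   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5754    0.6114   -0.5248 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1744   -0.5586   -0.4942 N   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4238   -0.4509    0.0785 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.8192    0.8248    0.4242 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.0525    1.3059    1.0206 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.1689    2.4304    1.5003 O   0  0  0  0  0  0  0  0  0  0  0  0
   -6.1133    0.4100    0.9186 N   0  0  0  0  0  0  0  0  0  0  0  0
   -7.3929    0.6389    1.4895 C   0  0  0  0  0  0  0  0  0  0  0  0
   -8.5339    0.3817    0.6945 C   0  0  0  0  0  0  0  0  0  0  0  0
   -8.4323   -0.1004   -0.7284 C   0  0  0  0  0  0  0  0  0  0  0  0
   -9.8136    0.6248    1.2248 C   0  0  0  0  0  0  0  0  0  0  0  0
   -9.9730    1.0907    2.5273 C   0  0  0  0  0  0  0  0  0  0  0  0
   -8.8553    1.2951    3.3297 C   0  0  0  0  0  0  0  0  0  0  0  0
   -7.5716    1.0574    2.8263 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.2763    1.1214    3.9774 Cl  0  0  0  0  0  0  0  0  0  0  0  0
   -2.5483    1.9159    0.0604 S   0  0  0  0  0  0  0  0  0  0  0  0
    1.8983    0.3268   -1.6468 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.9923   -0.5206   -1.5827 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.1716   -0.1935   -2.2858 N   0  0  0  0  0  0  0  0  0  0  0  0
    5.1973   -1.2695   -2.3262 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.4589   -0.9571   -1.4686 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.1741   -0.1945   -0.2483 N   0  0  0  0  0  0  0  0  0  0  0  0
    7.2979   -0.0636    0.6771 C   0  0  0  0  0  0  0  0  0  0  0  0
    8.5504    0.6671    0.1570 C   0  0  0  0  0  0  0  0  0  0  0  0
    9.5401    0.7564    1.1817 O   0  0  0  0  0  0  0  0  0  0  0  0
    5.4476    1.0574   -0.5216 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.7440    1.1138   -1.9056 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.9137   -1.6623   -0.8837 N   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  6  7  2  0
  7  8  1  0
  8  9  2  0
  9 10  1  0
 10 11  2  0
 10 12  1  0
 12 13  1  0
 13 14  2  0
 14 15  1  0
 14 16  1  0
 16 17  2  0
 17 18  1  0
 18 19  2  0
 19 20  1  0
  9 21  1  0
  4 22  2  0
 22 23  1  0
 23 24  1  0
 24 25  1  0
 25 26  1  0
 26 27  1  0
 27 28  1  0
 28 29  1  0
 29 30  1  0
 27 31  1  0
 31 32  1  0
 23 33  2  0
 33  2  1  0
 21  6  1  0
 32 24  1  0
 19 13  1  0
M  END
$$$$
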