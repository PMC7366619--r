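strain stress
    0 0.0252156
    2 1.18882
    4 2.35458
    6 3.51543
    8 4.82103
   10  6.0828
   12 7.44097
   14 8.79858
   16 10.1777
   18 12.1408
   20 14.0356
   22 16.2749
   24 18.7412
   26 21.1477
   28 24.5953
   30  27.989
   32 33.0273
   34 37.4662
   36 44.3045
   38 50.7637
   40 60.5246
   42 70.6351
   44 83.8345
   46 101.282
   48 125.211
   50 149.726
   52 186.672
   54 243.317
   56 308.885
   58 394.634
   60 548.291
   62 750.134
   64 1036.12
   66 1531.01
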