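# SYNTHETIC sphere self S-values for Lu-177 (unit-density spheres).
# Derived from mean local (electron) energy per decay 0.1479 MeV and a
# surface-loss absorbed-fraction model phi = 1 - 0.75*xbar/r, xbar = 0.23 mm.
# Stand-in for published sphere-model values; version 1.
mass_g,svalue_gy_per_gbq_min
0.01,123.81298
0.014677993,85.853852
0.021544347,59.391405
0.031622777,41.002343
0.046415888,28.257962
0.068129207,19.445794
0.1,13.364486
0.14677993,9.174791
0.21544347,6.29248
0.31622777,4.3120557
0.46415888,2.9527799
0.68129207,2.0207041
1,1.3820842
1.4677993,0.94483689
2.1544347,0.64564856
3.1622777,0.44103745
4.6415888,0.30117204
6.8129207,0.2056038
10,0.14032663
14.677993,0.095753525
21.544347,0.065326103
31.622777,0.044560101
46.415888,0.030390782
68.129207,0.020724386
100,0.014130982
146.77993,0.0096342931
215.44347,0.0065679442
316.22777,0.0044771922
464.15888,0.0030517766
681.29207,0.0020800511
1000,0.0014176617
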