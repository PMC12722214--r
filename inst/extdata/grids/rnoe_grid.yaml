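# rNOE network dictionary grid (aliphatic protons at -3.5 ppm).
water_t1: [1.2, 1.6, 2.0, 2.4]
water_t2: [0.04, 0.065, 0.09, 0.115]
f_ss: [0.02, 0.06, 0.1, 0.14, 0.18, 0.22, 0.26, 0.3]
k_ssw: [5.0, 28.75, 52.5, 76.25, 100.0]
f_rnoe: [0.001, 0.00273, 0.00445, 0.00618, 0.00791, 0.00964, 0.01136,
         0.01309, 0.01482, 0.01655, 0.01827, 0.02]
k_rnoe: [5.0, 14.0, 23.0, 32.0, 41.0, 50.0]
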