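# Semisolid MT grid with a wide water-T2 range including CSF-like values.
water_t1: [1.2, 1.6, 2.0, 2.4, 3.0, 3.6, 4.2]
water_t2: [0.035, 0.062, 0.088, 0.115, 0.3, 0.6, 1.2, 2.0]
f_ss: [0.005, 0.02, 0.05, 0.08, 0.11, 0.14, 0.17, 0.2, 0.23, 0.26, 0.3]
k_ssw: [5.0, 15.0, 25.0, 35.0, 45.0, 55.0, 65.0, 75.0, 85.0, 100.0]
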